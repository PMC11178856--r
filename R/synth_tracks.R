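#' Configuration for synthetic single-molecule tracks
#'
#' Describes an ensemble of membrane-bound single-molecule trajectories with
#' photon emission and a single exponential on-time process. Track end is a
#' single dwell process (the experiment cannot distinguish unbinding from
#' photobleaching, so the two are not modelled separately).
#'
#' Units follow the track schema: positions in nm, times in ms. Note that
#' 1 um^2/s = 1000 nm^2/ms and 1 um/s = 1 nm/ms.
#'
#' @param n_tracks number of tracks.
#' @param D diffusion coefficient in um^2/s (Brownian and confined models).
#' @param motion_model `"brownian"`, `"ballistic"` or `"confined"`.
#' @param speed constant speed in um/s (ballistic model only).
#' @param dt localization interval in ms.
#' @param on_time_mean mean of the exponential on-time in ms (or the fixed
#'   duration when `duration_model = "fixed"`).
#' @param duration_model `"exponential"` draws each track's on-time from an
#'   exponential with mean `on_time_mean`; `"fixed"` gives every track
#'   exactly that duration (useful for controlled MSD studies).
#' @param photons_meanlog,photons_sdlog parameters (mu, sigma) of the
#'   log-normal photon count per localization.
#' @param loc_noise_sd localization noise SD in nm, added independently per
#'   axis.
#' @param confinement_radius radius in nm of the reflecting circular boundary
#'   (confined model only).
#' @param seed RNG seed.
#' @return An object of class `synth_track_config`.
#' @export
synth_track_config <- function(n_tracks = 100L, D = 1,
                               motion_model = c("brownian", "ballistic",
                                                "confined"),
                               speed = 1, dt = 1, on_time_mean = 500,
                               duration_model = c("exponential", "fixed"),
                               photons_meanlog = log(200),
                               photons_sdlog = 0.5,
                               loc_noise_sd = 0,
                               confinement_radius = 250,
                               seed = 1L) {
  motion_model <- match.arg(motion_model)
  duration_model <- match.arg(duration_model)
  if (D < 0) stop("D must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  if (speed < 0) stop("speed must be >= 0")
  if (on_time_mean <= 0) stop("on_time_mean must be > 0")
  if (loc_noise_sd < 0) stop("loc_noise_sd must be >= 0")
  if (photons_sdlog < 0) stop("photons_sdlog must be >= 0")
  if (motion_model == "confined" && confinement_radius <= 0)
    stop("confinement_radius must be > 0")
  structure(list(n_tracks = as.integer(n_tracks), D = D,
                 motion_model = motion_model, speed = speed, dt = dt,
                 on_time_mean = on_time_mean,
                 duration_model = duration_model,
                 photons_meanlog = photons_meanlog,
                 photons_sdlog = photons_sdlog,
                 loc_noise_sd = loc_noise_sd,
                 confinement_radius = confinement_radius,
                 seed = seed),
            class = "synth_track_config")
}

#' Simulate a single-molecule track ensemble
#'
#' Brownian steps have per-axis variance `2 * D * dt` (in nm^2 with D
#' converted to nm^2/ms); ballistic tracks move along a random fixed
#' direction at constant speed; confined tracks are Brownian with radial
#' reflection at the confinement boundary. Photon counts per localization are
#' drawn log-normally (rounded, floored at 1); localization noise is added
#' independently per axis after the motion model.
#'
#' @param config a [synth_track_config()].
#' @return A [track_ensemble()] whose `truth` attribute records the
#'   generating parameters and the expected MSD exponent (`alpha` 1 for
#'   diffusive, 2 for ballistic motion).
#' @export
simulate_tracks <- function(config) {
  stopifnot(inherits(config, "synth_track_config"))
  D_nm <- config$D * 1000          # um^2/s -> nm^2/ms
  v_nm <- config$speed             # um/s == nm/ms
  step_sd <- sqrt(2 * D_nm * config$dt)
  with_fixed_seed(config$seed, {
    durations <- if (config$duration_model == "exponential")
      stats::rexp(config$n_tracks, rate = 1 / config$on_time_mean)
    else rep(config$on_time_mean, config$n_tracks)
    parts <- vector("list", config$n_tracks)
    for (i in seq_len(config$n_tracks)) {
      n <- max(2L, floor(durations[i] / config$dt) + 1L)
      tt <- (seq_len(n) - 1) * config$dt
      if (config$motion_model == "ballistic") {
        th <- stats::runif(1, 0, 2 * pi)
        x <- v_nm * tt * cos(th)
        y <- v_nm * tt * sin(th)
      } else {
        dx <- stats::rnorm(n - 1L, 0, step_sd)
        dy <- stats::rnorm(n - 1L, 0, step_sd)
        x <- cumsum(c(0, dx))
        y <- cumsum(c(0, dy))
        if (config$motion_model == "confined") {
          R <- config$confinement_radius
          for (j in seq_len(n - 1L) + 1L) {
            r <- sqrt(x[j]^2 + y[j]^2)
            if (r > R) {          # radial reflection at the boundary
              f <- (2 * R - r) / r
              x[j] <- x[j] * f; y[j] <- y[j] * f
              if (j < n) {        # re-anchor the remaining increments
                x[(j + 1):n] <- x[(j + 1):n] + (x[j] - x[j] / f)
                y[(j + 1):n] <- y[(j + 1):n] + (y[j] - y[j] / f)
              }
            }
          }
        }
      }
      if (config$loc_noise_sd > 0) {
        x <- x + stats::rnorm(n, 0, config$loc_noise_sd)
        y <- y + stats::rnorm(n, 0, config$loc_noise_sd)
      }
      ph <- pmax(1, round(stats::rlnorm(n, config$photons_meanlog,
                                        config$photons_sdlog)))
      parts[[i]] <- data.frame(track_id = i, t_ms = tt, x_nm = x, y_nm = y,
                               photons = ph)
    }
  })
  truth <- list(D = config$D, speed = config$speed,
                model = config$motion_model,
                alpha = if (config$motion_model == "ballistic") 2 else 1,
                on_time_mean = config$on_time_mean,
                dt = config$dt, loc_noise_sd = config$loc_noise_sd)
  track_ensemble(do.call(rbind, parts), truth = truth)
}
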