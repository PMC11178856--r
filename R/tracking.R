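#' Track durations and their percentage histogram
#'
#' Duration of a track is last minus first localization time. The histogram
#' is normalized to the percentage of tracks so that the bin values sum
#' to 100.
#'
#' @param ensemble a [track_ensemble()].
#' @param breaks histogram breaks in ms, as accepted by [graphics::hist()]
#'   (default `"Sturges"`).
#' @return List with `durations` (named by track id) and `histogram`
#'   (data.frame: `mid_ms`, `count`, `percent`).
#' @export
track_durations <- function(ensemble, breaks = "Sturges") {
  stopifnot(inherits(ensemble, "track_ensemble"))
  if (nrow(ensemble) == 0L) stop("empty ensemble")
  durations <- vapply(split_tracks(ensemble),
                      function(tr) max(tr$t_ms) - min(tr$t_ms), numeric(1))
  h <- graphics::hist(durations, breaks = breaks, plot = FALSE)
  list(durations = durations,
       histogram = data.frame(mid_ms = h$mids, count = h$counts,
                              percent = 100 * h$counts / sum(h$counts)))
}

#' Rolling-window speed along a track
#'
#' For each localization, sums the lengths of the consecutive steps lying
#' within a centred time window (default 35 ms) and divides by the actual
#' time span covered, giving an accumulated-distance-over-time speed per
#' position. Positions whose window extends beyond the track (partial
#' windows at the edges) are dropped to avoid systematic edge
#' underestimation. A track shorter than the window yields an empty series.
#'
#' @param track data.frame with `t_ms`, `x_nm`, `y_nm` (one track), or a
#'   [track_ensemble()] containing a single track.
#' @param window window length in ms (> 0; default 35).
#' @return data.frame with `t_ms` and `speed_um_s` (1 nm/ms = 1 um/s) for
#'   each interior position.
#' @export
rolling_speed <- function(track, window = 35) {
  if (window <= 0) stop("window must be > 0")
  tr <- as.data.frame(track)
  tr <- tr[order(tr$t_ms), , drop = FALSE]
  n <- nrow(tr)
  if (n < 2L || (max(tr$t_ms) - min(tr$t_ms)) < window)
    return(data.frame(t_ms = numeric(), speed_um_s = numeric()))
  steps <- sqrt(diff(tr$x_nm)^2 + diff(tr$y_nm)^2)  # step i: i -> i+1
  cum <- c(0, cumsum(steps))
  out_t <- numeric(0); out_v <- numeric(0)
  for (i in seq_len(n)) {
    lo <- tr$t_ms[i] - window / 2
    hi <- tr$t_ms[i] + window / 2
    if (lo < tr$t_ms[1] || hi > tr$t_ms[n]) next   # partial window: drop
    first <- which(tr$t_ms >= lo)[1]
    last <- which(tr$t_ms <= hi); last <- last[length(last)]
    if (last <= first) next
    span <- tr$t_ms[last] - tr$t_ms[first]
    if (span <= 0) next
    out_t <- c(out_t, tr$t_ms[i])
    out_v <- c(out_v, (cum[last] - cum[first]) / span)  # nm/ms == um/s
  }
  data.frame(t_ms = out_t, speed_um_s = out_v)
}

#' Maximum-likelihood log-normal fit of photon counts
#'
#' Pools the per-localization photon counts of an ensemble (the fit is
#' invariant to track grouping) and fits a log-normal by maximum likelihood:
#' `meanlog = mean(log N)`, `sdlog = sqrt(mean((log N - meanlog)^2))`.
#' Constant counts give `sdlog = 0` and are flagged degenerate.
#'
#' @param ensemble a [track_ensemble()] (or anything with a `photons`
#'   column, all values >= 1).
#' @param breaks histogram breaks for the returned count histogram.
#' @return List with `meanlog`, `sdlog`, `degenerate`, `n` and `histogram`
#'   (data.frame: `mid`, `count`, `density`).
#' @export
photon_lognormal_fit <- function(ensemble, breaks = "Sturges") {
  ph <- as.data.frame(ensemble)$photons
  if (is.null(ph) || !length(ph)) stop("no photon counts")
  if (any(ph < 1)) stop("photon counts must be >= 1")
  lg <- log(ph)
  meanlog <- mean(lg)
  sdlog <- sqrt(mean((lg - meanlog)^2))
  h <- graphics::hist(ph, breaks = breaks, plot = FALSE)
  list(meanlog = meanlog, sdlog = sdlog, degenerate = sdlog == 0,
       n = length(ph),
       histogram = data.frame(mid = h$mids, count = h$counts,
                              density = h$density))
}

#' Localization precision from photon counts
#'
#' The localization precision of an iterative probing scheme with probing
#' range `L` and `N` collected photons is approximately
#' `L / (2 * sqrt(2 * N))`. The approximation requires the probing range to
#' be much smaller than `fwhm / sqrt(log(2))` of the excitation beam; a
#' warning is raised when `L` exceeds that bound.
#'
#' @param photons photon count(s) `N`, all >= 1.
#' @param model list with `L` (probing range, nm, > 0) and optionally `fwhm`
#'   (beam FWHM, nm) for the validity check.
#' @return Localization precision(s) in nm: `L / (2 * sqrt(2 * photons))`.
#' @export
localization_precision <- function(photons, model) {
  if (any(photons < 1)) stop("photon counts must be >= 1")
  if (is.null(model$L) || model$L <= 0) stop("model$L must be > 0")
  if (!is.null(model$fwhm) && is.finite(model$fwhm) &&
      model$L >= model$fwhm / sqrt(log(2)))
    warning("probing range L is not small compared to fwhm/sqrt(ln 2); ",
            "the precision approximation may not hold")
  model$L / (2 * sqrt(2 * photons))
}

gumbel_nll <- function(par, x) {
  mu <- par[1]; beta <- par[2]
  if (beta <= 0) return(Inf)
  z <- (x - mu) / beta
  length(x) * log(beta) + sum(z + exp(-z))
}

gev_nll <- function(par, x) {
  mu <- par[1]; beta <- par[2]; xi <- par[3]
  if (beta <= 0) return(Inf)
  z <- (x - mu) / beta
  if (abs(xi) < 1e-8) return(gumbel_nll(par[1:2], x))
  w <- 1 + xi * z
  if (any(w <= 0)) return(Inf)
  length(x) * log(beta) + (1 + 1 / xi) * sum(log(w)) + sum(w^(-1 / xi))
}

#' Extreme-value fit of localization precision distributions
#'
#' Maximum-likelihood fit of a Gumbel or generalized extreme-value (GEV)
#' distribution, the family conventionally used to summarize per-track
#' localization-precision histograms. Initial values come from the Gumbel
#' moment estimators (`scale = sd * sqrt(6) / pi`,
#' `location = mean - 0.5772 * scale`); the GEV adds a shape parameter
#' started at 0.1. Standard errors are taken from the inverse Hessian.
#'
#' @param precisions numeric vector (n >= 10) of precision values in nm.
#' @param family `"gumbel"` (default) or `"gev"`.
#' @return List with `family`, `location`, `scale`, `shape` (0 for Gumbel),
#'   `se` (named vector), `loglik`, `n`, `ks_statistic` (goodness summary)
#'   and `degenerate`.
#' @export
precision_evd_fit <- function(precisions, family = c("gumbel", "gev")) {
  family <- match.arg(family)
  x <- precisions[is.finite(precisions)]
  if (length(x) < 10L) stop("need at least 10 values")
  if (stats::sd(x) == 0)
    return(list(family = family, location = x[1], scale = 0, shape = 0,
                se = NULL, loglik = NA_real_, n = length(x),
                ks_statistic = NA_real_, degenerate = TRUE))
  beta0 <- stats::sd(x) * sqrt(6) / pi
  mu0 <- mean(x) - 0.57721566 * beta0
  if (family == "gumbel") {
    opt <- stats::optim(c(mu0, beta0), gumbel_nll, x = x, hessian = TRUE)
    par <- c(opt$par, 0)
  } else {
    opt <- stats::optim(c(mu0, beta0, 0.1), gev_nll, x = x, hessian = TRUE)
    par <- opt$par
  }
  se <- tryCatch(sqrt(diag(solve(opt$hessian))), error = function(e) NULL)
  cdf <- function(q) {
    z <- (q - par[1]) / par[2]
    if (abs(par[3]) < 1e-8) exp(-exp(-z))
    else exp(-pmax(1 + par[3] * z, 0)^(-1 / par[3]))
  }
  ks <- suppressWarnings(stats::ks.test(x, cdf)$statistic)
  list(family = family, location = par[1], scale = par[2], shape = par[3],
       se = se, loglik = -opt$value, n = length(x),
       ks_statistic = unname(ks), degenerate = FALSE)
}

# bin-average one track onto a regular grid of width time_bin (ms) starting
# at the track's first localization; returns x/y per bin index (NA = empty)
resample_track <- function(tr, time_bin) {
  b <- floor((tr$t_ms - tr$t_ms[1]) / time_bin)
  nb <- max(b) + 1L
  x <- rep(NA_real_, nb); y <- rep(NA_real_, nb)
  xs <- rowsum(tr$x_nm, b); ys <- rowsum(tr$y_nm, b)
  ns <- rowsum(rep(1, length(b)), b)
  idx <- as.integer(rownames(xs)) + 1L
  x[idx] <- xs / ns; y[idx] <- ys / ns
  list(x = x, y = y)
}

#' Time-averaged mean squared displacement
#'
#' Resamples each track onto a regular time grid by averaging localizations
#' per bin, forms all overlapping position pairs at each bin lag, and pools
#' the squared displacements across tracks (each pair contributing equally,
#' so lags are weighted by their pair counts). Lag 0 is included with MSD 0.
#'
#' @param ensemble a [track_ensemble()].
#' @param time_bin resampling bin width in ms; a bin equal to the
#'   localization interval is an identity resampling.
#' @param max_lag largest lag to evaluate in ms.
#' @return An `msd_curve`: data.frame with `lag_ms`, `msd_nm2`, `n_pairs`.
#'   Empty (zero rows beyond lag 0 absent) if no track spans any lag.
#' @export
msd <- function(ensemble, time_bin, max_lag) {
  stopifnot(inherits(ensemble, "track_ensemble"))
  if (time_bin <= 0 || max_lag <= 0) stop("time_bin and max_lag must be > 0")
  K <- floor(max_lag / time_bin)
  ss <- numeric(K + 1L); np <- numeric(K + 1L)
  for (tr in split_tracks(ensemble)) {
    rs <- resample_track(tr, time_bin)
    nb <- length(rs$x)
    np[1] <- np[1] + sum(!is.na(rs$x))
    for (k in seq_len(min(K, nb - 1L))) {
      dx <- rs$x[(k + 1):nb] - rs$x[1:(nb - k)]
      dy <- rs$y[(k + 1):nb] - rs$y[1:(nb - k)]
      v <- !is.na(dx)
      ss[k + 1L] <- ss[k + 1L] + sum(dx[v]^2 + dy[v]^2)
      np[k + 1L] <- np[k + 1L] + sum(v)
    }
  }
  keep <- np > 0
  out <- data.frame(lag_ms = (0:K)[keep] * time_bin,
                    msd_nm2 = ifelse((0:K)[keep] == 0, 0,
                                     ss[keep] / pmax(np[keep], 1)),
                    n_pairs = np[keep])
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit a diffusion model to an MSD curve
#'
#' Brownian model: least squares through the origin, `msd = 4 D lag`.
#' Anomalous model: `msd = 4 D lag^alpha` fitted as a line in log-log space;
#' non-positive MSD values cannot enter the log fit and are excluded (and
#' counted in `n_excluded`). The default fit range is the first quarter of
#' the available positive lags, never fewer than 3.
#'
#' @param curve an `msd_curve` from [msd()].
#' @param model `"brownian"` or `"anomalous"`.
#' @param fit_range optional `c(min_lag, max_lag)` in ms.
#' @return A `diffusion_fit`: list with `model`, `D` (um^2/s), `alpha`,
#'   `fit_range`, `n_lags`, `n_excluded`.
#' @export
fit_msd <- function(curve, model = c("brownian", "anomalous"),
                    fit_range = NULL) {
  model <- match.arg(model)
  cv <- as.data.frame(curve)
  cv <- cv[cv$lag_ms > 0, , drop = FALSE]
  if (is.null(fit_range)) {
    n_use <- max(3L, floor(nrow(cv) / 4))
    cv <- cv[seq_len(min(n_use, nrow(cv))), , drop = FALSE]
  } else {
    cv <- cv[cv$lag_ms >= fit_range[1] & cv$lag_ms <= fit_range[2], ,
             drop = FALSE]
  }
  if (nrow(cv) < 3L) stop("need at least 3 lags in the fit range")
  n_excluded <- 0L
  if (model == "brownian") {
    D_nm2_ms <- sum(cv$msd_nm2 * cv$lag_ms) / sum(cv$lag_ms^2) / 4
    alpha <- 1
  } else {
    pos <- cv$msd_nm2 > 0
    n_excluded <- sum(!pos)
    cv <- cv[pos, , drop = FALSE]
    if (nrow(cv) < 3L) stop("fewer than 3 positive MSD values in range")
    fit <- stats::lm(log(msd_nm2) ~ log(lag_ms), data = cv)
    alpha <- unname(stats::coef(fit)[2])
    D_nm2_ms <- exp(unname(stats::coef(fit)[1])) / 4
  }
  structure(list(model = model, D = D_nm2_ms / 1000,  # nm^2/ms -> um^2/s
                 alpha = alpha,
                 fit_range = range(cv$lag_ms), n_lags = nrow(cv),
                 n_excluded = n_excluded),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> %s: D = %.4g um^2/s, alpha = %.3f (%d lags)\n",
              x$model, x$D, x$alpha, x$n_lags))
  invisible(x)
}

#' Trajectory-truncation sensitivity of the anomalous exponent
#'
#' Clips every track to its first `length` ms for each tested length,
#' recomputes the pooled time-averaged MSD and refits the anomalous model.
#' Short trajectories push the log-log fit onto the first few analysis bins,
#' where bin-averaging (motion blur) depresses the MSD most, so apparent
#' superdiffusion emerges as trajectories are shortened.
#'
#' @param ensemble a [track_ensemble()].
#' @param lengths truncation lengths in ms.
#' @param time_bin MSD resampling bin in ms (default 10).
#' @return data.frame with `length_ms`, `alpha`, `D`, `n_tracks`.
#' @export
truncation_study <- function(ensemble, lengths, time_bin = 10) {
  stopifnot(inherits(ensemble, "track_ensemble"))
  rows <- lapply(lengths, function(len) {
    df <- as.data.frame(ensemble)
    t0 <- stats::ave(df$t_ms, df$track_id, FUN = min)
    df <- df[df$t_ms - t0 <= len, , drop = FALSE]
    nloc <- table(df$track_id)
    df <- df[df$track_id %in% names(nloc)[nloc >= 2], , drop = FALSE]
    clipped <- track_ensemble(df)
    fit <- fit_msd(msd(clipped, time_bin = time_bin, max_lag = len),
                   model = "anomalous")
    data.frame(length_ms = len, alpha = fit$alpha, D = fit$D,
               n_tracks = length(unique(df$track_id)))
  })
  do.call(rbind, rows)
}

#' Time-binning sensitivity of the MSD curve
#'
#' Clips every track to its first `interval` ms, then recomputes the MSD and
#' the anomalous-model fit at each tested resampling bin. Binning alone
#' barely changes the shape of a well-sampled MSD curve; the fitted exponent
#' summarizes the curvature per binning.
#'
#' @param ensemble a [track_ensemble()].
#' @param bins resampling bin widths in ms.
#' @param interval analysis interval in ms (default 1000).
#' @return List with `curves` (one `msd_curve` per bin) and `summary`
#'   (data.frame: `bin_ms`, `alpha`, `D`).
#' @export
binning_study <- function(ensemble, bins, interval = 1000) {
  stopifnot(inherits(ensemble, "track_ensemble"))
  df <- as.data.frame(ensemble)
  t0 <- stats::ave(df$t_ms, df$track_id, FUN = min)
  df <- df[df$t_ms - t0 <= interval, , drop = FALSE]
  clipped <- track_ensemble(df)
  curves <- list(); rows <- list()
  for (b in bins) {
    cv <- msd(clipped, time_bin = b, max_lag = interval)
    fit <- fit_msd(cv, model = "anomalous")
    curves[[as.character(b)]] <- cv
    rows[[length(rows) + 1L]] <- data.frame(bin_ms = b, alpha = fit$alpha,
                                            D = fit$D)
  }
  list(curves = curves, summary = do.call(rbind, rows))
}
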