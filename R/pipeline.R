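#' Run one pipeline stage from a configuration
#'
#' Thin orchestration layer tying the simulation and analysis stages
#' together. A configuration is a named list (or a YAML file path) with
#' elements `stage`, `params` (stage parameters, including any `seed`),
#' optional `inputs` (named file paths) and `out_dir`. Every stage writes its
#' artifacts into `out_dir` plus a machine-readable `report.json` recording
#' the stage, parameters, MD5 hashes of the inputs and the summary
#' statistics, so a run is fully reproducible from its config: the same
#' config always produces an identical report.
#'
#' Stages:
#' * `"simulate-scene"`: [generate_ratiometric_scene()]; writes detector and
#'   green TIFFs, masks and a ground-truth CSV.
#' * `"simulate-flim"`: [simulate_flim_stack()]; writes the stack TIFF.
#' * `"simulate-tracks"`: [simulate_tracks()]; writes the track CSV.
#' * `"ratio"`: [ratio_map()] + [compartment_stats()] from `inputs$det1`,
#'   `inputs$det2` and optional `inputs$masks`; writes the ratio TIFF and a
#'   per-compartment CSV.
#' * `"flim-fit"`: both lifetime fits on `inputs$stack`; writes tau maps and
#'   reports the per-method lifetime table.
#' * `"track-stats"`: durations, rolling speeds and MSD fit on
#'   `inputs$tracks`.
#'
#' @param config named list or path to a YAML file.
#' @return The report (a list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$stage)) stop("config needs a 'stage'")
  if (is.null(config$out_dir)) stop("config needs an 'out_dir'")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- if (is.null(config$params)) list() else config$params
  inputs <- if (is.null(config$inputs)) list() else config$inputs
  op <- function(p) file.path(config$out_dir, p)

  artifacts <- character(0)
  summary <- switch(config$stage,
    "simulate-scene" = {
      cfg <- do.call(synth_image_config, params)
      sc <- generate_ratiometric_scene(cfg)
      write_image(sc$pair$det1, op("det1.tif"))
      write_image(sc$pair$det2, op("det2.tif"))
      write_image(sc$green, op("green.tif"))
      write_masks(sc$masks, op("masks.tif"))
      utils::write.csv(sc$truth, op("truth.csv"), row.names = FALSE)
      artifacts <- op(c("det1.tif", "det2.tif", "green.tif", "masks.tif",
                        "truth.csv"))
      list(n_compartments = nrow(sc$truth),
           image_shape = cfg$image_shape)
    },
    "simulate-flim" = {
      amp <- params$amplitude
      params$amplitude <- NULL
      cfg <- do.call(flim_sim_config, params)
      st <- if (is.null(amp)) simulate_flim_stack(cfg)
            else simulate_flim_stack(cfg, amplitude = amp)
      write_flim_stack(st, op("flim_stack.tif"))
      artifacts <- op("flim_stack.tif")
      list(n_bins = dim(st)[3], n_patches = length(flim_i0_grid(cfg)),
           tau_true = cfg$tau)
    },
    "simulate-tracks" = {
      cfg <- do.call(synth_track_config, params)
      ens <- simulate_tracks(cfg)
      write_tracks(ens, op("tracks.csv"))
      artifacts <- op("tracks.csv")
      list(n_tracks = cfg$n_tracks, n_localizations = nrow(ens))
    },
    "ratio" = {
      pair <- channel_pair(read_image(inputs$det1), read_image(inputs$det2))
      sigma <- if (is.null(params$sigma)) 1.5 else params$sigma
      bg <- if (is.null(params$background)) {
        # percentile rule: 60th percentile of nonzero pixels, per detector
        c(stats::quantile(pair$det1$values[pair$det1$values > 0], 0.6),
          stats::quantile(pair$det2$values[pair$det2$values > 0], 0.6))
      } else params$background
      rm_ <- ratio_map(pair, sigma = sigma, background = bg)
      write_image(image2d(ifelse(rm_$valid_mask, rm_$ratio, 0),
                          rm_$pixel_size), op("ratio.tif"))
      artifacts <- op("ratio.tif")
      s <- list(n_valid = sum(rm_$valid_mask),
                median_ratio = stats::median(rm_$ratio[rm_$valid_mask]))
      if (!is.null(inputs$masks)) {
        cs <- compartment_stats(rm_, read_masks(inputs$masks))
        utils::write.csv(cs$summary, op("compartments.csv"),
                         row.names = FALSE)
        artifacts <- c(artifacts, op("compartments.csv"))
        s$compartments <- cs$summary
      }
      s
    },
    "flim-fit" = {
      st <- read_flim_stack(inputs$stack)
      bg <- if (is.null(params$background)) 0 else params$background
      tab <- list()
      for (m in c("linearized", "nonlinear")) {
        fit <- if (m == "linearized") linearized_lifetime_fit(st, bg)
               else nonlinear_lifetime_fit(st, bg)
        write_image(image2d(ifelse(fit$fit_ok, fit$tau, 0), st$pixel_size),
                    op(paste0("tau_", m, ".tif")))
        artifacts <- c(artifacts, op(paste0("tau_", m, ".tif")))
        tv <- fit$tau[fit$fit_ok]
        tab[[m]] <- list(mean_tau_ns = mean(tv), sd_tau_ns = stats::sd(tv),
                         n_fit = sum(fit$fit_ok))
      }
      list(tau_table = tab)
    },
    "track-stats" = {
      ens <- read_tracks(inputs$tracks)
      window <- if (is.null(params$window)) 35 else params$window
      time_bin <- if (is.null(params$time_bin)) 10 else params$time_bin
      dur <- track_durations(ens)
      speeds <- unlist(lapply(split_tracks(ens), function(tr)
        rolling_speed(tr, window = window)$speed_um_s))
      max_lag <- if (is.null(params$max_lag)) max(dur$durations)
                 else params$max_lag
      fit <- fit_msd(msd(ens, time_bin = time_bin, max_lag = max_lag),
                     model = "anomalous")
      utils::write.csv(data.frame(track_id = names(dur$durations),
                                  duration_ms = dur$durations),
                       op("durations.csv"), row.names = FALSE)
      artifacts <- op("durations.csv")
      list(n_tracks = length(dur$durations),
           mean_duration_ms = mean(dur$durations),
           median_speed_um_s = if (length(speeds)) stats::median(speeds)
                               else NA_real_,
           alpha = fit$alpha, D_um2_s = fit$D)
    },
    stop("unknown stage '", config$stage, "'; valid stages: simulate-scene, ",
         "simulate-flim, simulate-tracks, ratio, flim-fit, track-stats")
  )

  input_md5 <- if (length(inputs))
    as.list(tools::md5sum(unlist(inputs))) else list()
  report <- list(stage = config$stage, params = params,
                 inputs = input_md5, artifacts = as.character(artifacts),
                 summary = summary)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
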