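ballistic_ens <- function(n = 3, speed = 1, dur = 200, seed = 2) {
  simulate_tracks(synth_track_config(
    n_tracks = n, motion_model = "ballistic", speed = speed, dt = 1,
    on_time_mean = dur, duration_model = "fixed", loc_noise_sd = 0,
    seed = seed))
}

test_that("track durations normalize to percentages summing to 100", {
  one <- track_ensemble(data.frame(track_id = 1, t_ms = c(0, 50, 100),
                                   x_nm = 0, y_nm = 0, photons = 10))
  td <- track_durations(one)
  expect_equal(unname(td$durations), 100)
  expect_equal(sum(td$histogram$percent), 100)
  ens <- simulate_tracks(synth_track_config(n_tracks = 400, seed = 3))
  td2 <- track_durations(ens, breaks = seq(0, 10000, by = 100))
  expect_equal(sum(td2$histogram$percent), 100, tolerance = 1e-9)
})

test_that("rolling speed is exact on ballistic and immobile tracks", {
  tr <- as.data.frame(ballistic_ens(1))
  sp <- rolling_speed(tr, window = 35)
  expect_gt(nrow(sp), 0)
  expect_equal(sp$speed_um_s, rep(1, nrow(sp)), tolerance = 1e-12)
  still <- data.frame(t_ms = 0:100, x_nm = 5, y_nm = -3)
  sps <- rolling_speed(still, 35)
  expect_gt(nrow(sps), 0)
  expect_equal(sps$speed_um_s, rep(0, nrow(sps)))
  # shorter than the window: empty series, not an error
  short <- data.frame(t_ms = 0:10, x_nm = 0:10, y_nm = 0)
  expect_equal(nrow(rolling_speed(short, 35)), 0L)
})

test_that("rolling speed equals a brute-force windowed oracle", {
  ens <- simulate_tracks(synth_track_config(n_tracks = 1, D = 0.5, dt = 1,
                                            on_time_mean = 120,
                                            duration_model = "fixed",
                                            seed = 11))
  tr <- as.data.frame(ens)
  sp <- rolling_speed(tr, window = 35)
  steps <- sqrt(diff(tr$x_nm)^2 + diff(tr$y_nm)^2)
  for (r in seq_len(nrow(sp))) {
    ti <- sp$t_ms[r]
    inwin <- which(tr$t_ms >= ti - 17.5 & tr$t_ms <= ti + 17.5)
    dist <- sum(steps[inwin[-length(inwin)]])
    span <- tr$t_ms[max(inwin)] - tr$t_ms[min(inwin)]
    expect_equal(sp$speed_um_s[r], dist / span)
  }
})

test_that("photon statistics follow the configured log-normal", {
  const <- track_ensemble(data.frame(track_id = 1, t_ms = 0:9, x_nm = 0,
                                     y_nm = 0, photons = 100))
  f0 <- photon_lognormal_fit(const)
  expect_equal(f0$meanlog, log(100))
  expect_equal(f0$sdlog, 0)
  expect_true(f0$degenerate)
  set.seed(5)
  big <- track_ensemble(data.frame(track_id = rep(1:100, each = 1000),
                                   t_ms = rep(0:999, 100),
                                   x_nm = 0, y_nm = 0,
                                   photons = pmax(1, round(rlnorm(1e5, 5, 0.5)))))
  fit <- photon_lognormal_fit(big)
  expect_lt(abs(fit$meanlog - 5), 3 * 0.5 / sqrt(1e5))
  expect_lt(abs(fit$sdlog - 0.5), 3 * 0.5 / sqrt(2e5))
  # closed-form ML agrees with the MASS reference fit
  skip_if_not_installed("MASS")
  ref <- MASS::fitdistr(big$photons, "lognormal")
  expect_equal(fit$meanlog, unname(ref$estimate["meanlog"]), tolerance = 1e-8)
  expect_equal(fit$sdlog, unname(ref$estimate["sdlog"]), tolerance = 1e-8)
})

test_that("localization precision follows L / (2 sqrt(2 N))", {
  model <- list(L = 50, fwhm = 800)
  expect_equal(localization_precision(200, model), 1.25)
  expect_equal(localization_precision(50, list(L = 40)), 2)
  # exact algebraic scaling in L and N
  set.seed(6)
  for (i in 1:20) {
    L <- runif(1, 10, 100); N <- sample(1:5000, 1); c_ <- runif(1, 0.5, 4)
    expect_equal(localization_precision(N, list(L = c_ * L)),
                 c_ * localization_precision(N, list(L = L)))
    expect_equal(localization_precision(4 * N, list(L = L)),
                 localization_precision(N, list(L = L)) / 2)
  }
  expect_true(all(diff(localization_precision(1:100, model)) < 0))
  expect_error(localization_precision(0, model), ">= 1")
  expect_warning(localization_precision(10, list(L = 900, fwhm = 600)),
                 "probing range")
})

test_that("the extreme-value fit recovers Gumbel parameters", {
  set.seed(8)
  x <- 5 - 2 * log(-log(runif(1e4)))    # Gumbel(location 5, scale 2)
  fit <- precision_evd_fit(x)
  expect_lt(abs(fit$location - 5), 3 * fit$se[1])
  expect_lt(abs(fit$scale - 2), 3 * fit$se[2])
  # shift and scale equivariance
  sh <- precision_evd_fit(x + 10)
  expect_equal(sh$location, fit$location + 10, tolerance = 0.02)
  expect_equal(sh$scale, fit$scale, tolerance = 0.02)
  sc <- precision_evd_fit(3 * x)
  expect_equal(sc$location, 3 * fit$location, tolerance = 0.05)
  expect_equal(sc$scale, 3 * fit$scale, tolerance = 0.05)
  gev <- precision_evd_fit(x, family = "gev")
  expect_lt(abs(gev$shape), 0.05)        # Gumbel is GEV with shape 0
  expect_true(precision_evd_fit(rep(2, 20))$degenerate)
})

test_that("MSD is exact for ballistic and immobile motion", {
  ens <- ballistic_ens(1, speed = 1, dur = 100)
  cv <- msd(ens, time_bin = 1, max_lag = 50)
  expect_equal(cv$msd_nm2[cv$lag_ms == 0], 0)
  pos <- cv[cv$lag_ms > 0, ]
  expect_equal(pos$msd_nm2, (1 * pos$lag_ms)^2, tolerance = 1e-9)
  expect_true(all(diff(cv$n_pairs) <= 0))
  still <- track_ensemble(data.frame(track_id = 1, t_ms = 0:99, x_nm = 1,
                                     y_nm = 2, photons = 5))
  expect_equal(msd(still, 1, 20)$msd_nm2, rep(0, 21))
})

test_that("MSD and rolling speed are invariant under rigid motions", {
  ens <- simulate_tracks(synth_track_config(n_tracks = 5, D = 1, dt = 1,
                                            on_time_mean = 200,
                                            duration_model = "fixed",
                                            seed = 14))
  df <- as.data.frame(ens)
  th <- 0.7
  rot <- data.frame(track_id = df$track_id, t_ms = df$t_ms,
                    x_nm = cos(th) * df$x_nm - sin(th) * df$y_nm + 500,
                    y_nm = sin(th) * df$x_nm + cos(th) * df$y_nm - 200,
                    photons = df$photons)
  e2 <- track_ensemble(rot)
  expect_equal(msd(e2, 5, 100)$msd_nm2, msd(ens, 5, 100)$msd_nm2,
               tolerance = 1e-9)
  tr1 <- df[df$track_id == 1, ]; tr2 <- rot[rot$track_id == 1, ]
  expect_equal(rolling_speed(tr2, 35)$speed_um_s,
               rolling_speed(tr1, 35)$speed_um_s, tolerance = 1e-9)
})

test_that("diffusion fits recover exact inputs to machine precision", {
  lag <- 1:40
  bro <- data.frame(lag_ms = lag, msd_nm2 = 4 * 2000 * lag, n_pairs = 100)
  class(bro) <- c("msd_curve", "data.frame")
  f1 <- fit_msd(bro, "brownian")
  expect_equal(f1$D, 2, tolerance = 1e-12)      # 2000 nm^2/ms = 2 um^2/s
  f2 <- fit_msd(bro, "anomalous")
  expect_equal(f2$alpha, 1, tolerance = 1e-10)
  expect_equal(f2$D, 2, tolerance = 1e-10)
  bal <- data.frame(lag_ms = lag, msd_nm2 = (3 * lag)^2, n_pairs = 100)
  class(bal) <- c("msd_curve", "data.frame")
  expect_equal(fit_msd(bal, "anomalous")$alpha, 2, tolerance = 1e-10)
})

test_that("pooled MSD of a Brownian ensemble recovers 4 D lag", {
  ens <- simulate_tracks(synth_track_config(n_tracks = 200, D = 1, dt = 1,
                                            on_time_mean = 500,
                                            duration_model = "fixed",
                                            seed = 15))
  cv <- msd(ens, time_bin = 1, max_lag = 100)
  fit <- fit_msd(cv, "brownian")
  expect_lt(abs(fit$D - 1), 0.1)
  af <- fit_msd(cv, "anomalous")
  expect_gt(af$alpha, 0.9); expect_lt(af$alpha, 1.1)
})

test_that("a single long Brownian track converges to 4 D lag", {
  ens <- simulate_tracks(synth_track_config(n_tracks = 1, D = 1, dt = 1,
                                            on_time_mean = 1e5,
                                            duration_model = "fixed",
                                            seed = 16))
  cv <- msd(ens, time_bin = 1, max_lag = 20)
  pos <- cv[cv$lag_ms > 0, ]
  expect_true(all(abs(pos$msd_nm2 - 4000 * pos$lag_ms) /
                    (4000 * pos$lag_ms) < 0.05))
})

test_that("truncation and binning studies behave on reference motions", {
  bal <- ballistic_ens(5, dur = 1000, seed = 21)
  ts <- truncation_study(bal, lengths = c(200, 1000), time_bin = 10)
  expect_equal(ts$alpha, c(2, 2), tolerance = 0.02)
  bro <- simulate_tracks(synth_track_config(n_tracks = 150, D = 1, dt = 1,
                                            on_time_mean = 1000,
                                            duration_model = "fixed",
                                            seed = 22))
  tsb <- truncation_study(bro, lengths = 1000, time_bin = 10)
  expect_lt(abs(tsb$alpha - 1), 0.12)
  bs <- binning_study(bro, bins = c(5, 10, 20), interval = 1000)
  expect_lt(max(bs$summary$alpha) - min(bs$summary$alpha), 0.15)
  # noiseless ballistic: identical normalized curves at all binnings
  bb <- binning_study(bal, bins = c(5, 10), interval = 500)
  c5 <- bb$curves[["5"]]; c10 <- bb$curves[["10"]]
  shared <- intersect(c5$lag_ms[c5$lag_ms > 0], c10$lag_ms[c10$lag_ms > 0])
  m5 <- c5$msd_nm2[match(shared, c5$lag_ms)]
  m10 <- c10$msd_nm2[match(shared, c10$lag_ms)]
  # partial trailing bins perturb the averages slightly; curves agree in
  # shape to well under a percent
  expect_equal(m5 / m5[1], m10 / m10[1], tolerance = 0.01)
  # bin equal to dt is an identity resampling
  cv1 <- msd(bro, time_bin = 1, max_lag = 50)
  tr1 <- as.data.frame(bro)[as.data.frame(bro)$track_id == 1, ]
  d1 <- sum((tr1$x_nm[-1] - tr1$x_nm[-nrow(tr1)])^2 +
            (tr1$y_nm[-1] - tr1$y_nm[-nrow(tr1)])^2) / (nrow(tr1) - 1)
  single <- msd(track_ensemble(tr1), time_bin = 1, max_lag = 1)
  expect_equal(single$msd_nm2[single$lag_ms == 1], d1, tolerance = 1e-9)
})

test_that("track tables round-trip through the CSV schema losslessly", {
  ens <- simulate_tracks(synth_track_config(n_tracks = 5, seed = 30))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_tracks(ens, f1)
  back <- read_tracks(f1)
  expect_equal(as.data.frame(back), as.data.frame(ens), tolerance = 0,
               ignore_attr = TRUE)
  write_tracks(back, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical
})
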