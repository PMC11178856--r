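# rank-based AUC (Wilcoxon form), direction-free
auc_rank <- function(pos, neg) {
  r <- rank(c(pos, neg))
  a <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  max(a, 1 - a)
}

# direct two-pass Pearson evaluation, independent of stats::cor
pearson_two_pass <- function(a, b) {
  am <- mean(a); bm <- mean(b)
  sum((a - am) * (b - bm)) / sqrt(sum((a - am)^2) * sum((b - bm)^2))
}

# noiseless elliptical Gaussian blob image
gauss_blob <- function(nr, nc, r0, c0, sigma_r, sigma_c = sigma_r,
                       A = 1000, offset = 0) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  A * exp(-((rr - r0)^2 / (2 * sigma_r^2) +
            (cc - c0)^2 / (2 * sigma_c^2))) + offset
}

# two-region FLIM stack (left half tau1, right half tau2), equal I0,
# Poisson noise; returns stack + region labels
two_region_stack <- function(I0 = 2000, tau1 = 2, tau2 = 4, side = 24L,
                             seed1 = 11L, seed2 = 12L) {
  mk <- function(tau, seed) {
    cfg <- flim_sim_config(I0_start = I0, I0_stop = I0, I0_step = 40,
                           tau = tau, noise_model = "poisson",
                           patch_shape = c(side, side), seed = seed)
    simulate_flim_stack(cfg, seed = seed)
  }
  a <- mk(tau1, seed1); b <- mk(tau2, seed2)
  st <- flim_stack(array(c(a$counts, b$counts),
                         c(side, 2L * side, dim(a$counts)[3])),
                   bin_width = a$bin_width, offset = a$offset)
  labels <- matrix(rep(c(1L, 2L), each = side * side), side, 2L * side)
  list(stack = st, labels = labels)
}
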