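test_that("Poisson correction divides each bin by the root of its mean", {
  u <- flim_stack(array(rep(c(16, 4), each = 8), c(2, 4, 2)), bin_width = 1)
  cor_u <- poisson_noise_correct(u)
  expect_equal(cor_u$counts[, , 1], matrix(16 / 4, 2, 4))
  expect_equal(cor_u$counts[, , 2], matrix(4 / 2, 2, 4))
  set.seed(7)
  st <- flim_stack(array(rpois(6 * 6 * 10, 30), c(6, 6, 10)), bin_width = 1)
  cor_st <- poisson_noise_correct(st)
  for (k in 1:10)   # brute-force per-bin oracle
    expect_equal(cor_st$counts[, , k],
                 st$counts[, , k] / sqrt(mean(st$counts[, , k])))
  # correction is not idempotent: factors follow the new bin means
  twice <- poisson_noise_correct(cor_st)
  expect_false(isTRUE(all.equal(twice$counts, cor_st$counts)))
  zero <- st; zero$counts[, , 3] <- 0
  expect_error(poisson_noise_correct(zero), "bin 3")
})

test_that("identical decays give zero centered scores everywhere", {
  u <- flim_stack(array(rep(100 * exp(-(1:50) / 10), each = 64),
                        c(8, 8, 50)), bin_width = 0.4)
  res <- ncpca(u, n_components = 3)
  expect_equal(max(abs(res$scores_centered)), 0, tolerance = 1e-10)
})

test_that("the eigenbasis is orthonormal and conserves total variation", {
  tr <- two_region_stack()
  res <- ncpca(tr$stack, n_components = 4)
  V <- t(res$eigenvectors)
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-10)
  expect_lt(abs(sum(res$eigenvalues) - res$total_variance) /
              res$total_variance, 1e-8)
  expect_true(all(diff(res$eigenvalues) <= 1e-10))   # descending
})

test_that("score 2 separates two lifetime regions", {
  tr <- two_region_stack(I0 = 2000, tau1 = 2, tau2 = 4)
  res <- ncpca(tr$stack, n_components = 4)
  s2 <- res$scores[2, , ]
  expect_gt(auc_rank(s2[tr$labels == 2], s2[tr$labels == 1]), 0.9)
})

test_that("scores are equivariant under pixel permutation", {
  tr <- two_region_stack(side = 8L)
  st <- tr$stack
  d <- dim(st$counts)
  set.seed(9)
  perm <- sample(d[1] * d[2])
  M <- st$counts; dim(M) <- c(d[1] * d[2], d[3])
  stp <- flim_stack(array(M[perm, ], d), bin_width = st$bin_width)
  r1 <- ncpca(st, n_components = 2)
  r2 <- ncpca(stp, n_components = 2)
  s1 <- r1$scores[1, , ]; dim(s1) <- NULL
  s2 <- r2$scores[1, , ]; dim(s2) <- NULL
  expect_equal(s2, s1[perm], tolerance = 1e-10)
})

test_that("a pooled basis makes group score comparisons well-defined", {
  tr <- two_region_stack(side = 12L)
  a <- flim_stack(tr$stack$counts[, 1:12, , drop = FALSE],
                  bin_width = tr$stack$bin_width)
  b <- flim_stack(tr$stack$counts[, 13:24, , drop = FALSE],
                  bin_width = tr$stack$bin_width)
  rs <- ncpca(list(a, b), n_components = 3)
  expect_identical(rs[[1]]$eigenvectors, rs[[2]]$eigenvectors)
  same <- compare_scores(rs[[1]], rs[[1]], component = 2)
  expect_identical(same$values_a, same$values_b)
  cmp <- compare_scores(rs[[1]], rs[[2]], component = 2)
  expect_false(isTRUE(all.equal(cmp$median_a, cmp$median_b)))
  expect_error(compare_scores(rs[[1]], rs[[2]], component = 7), "range")
  # outlier pixels are removed by the MAD rule
  rs[[1]]$scores[2, 1, 1] <- 100 * max(abs(rs[[1]]$scores[2, , ]))
  filt <- compare_scores(rs[[1]], rs[[2]], component = 2)
  expect_false(max(rs[[1]]$scores[2, , ]) %in% filt$values_a)
  # different bases are rejected
  other <- ncpca(two_region_stack(side = 8L, seed1 = 31, seed2 = 32)$stack,
                 n_components = 3)
  expect_error(compare_scores(rs[[1]], other, component = 2), "basis")
})

test_that("stacks on different time grids cannot be pooled", {
  a <- flim_stack(array(10, c(4, 4, 10)), bin_width = 0.5)
  b <- flim_stack(array(10, c(4, 4, 10)), bin_width = 0.6)
  expect_error(ncpca(list(a, b)), "time grid")
})
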