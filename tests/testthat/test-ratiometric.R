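test_that("mean brightness omits pixels at or below background", {
  expect_equal(mean_brightness(matrix(10, 4, 4), background = 5), 10)
  half <- matrix(c(0, 10), 4, 4)
  expect_equal(mean_brightness(half, background = 5), 10)
  set.seed(1)
  img <- matrix(runif(400, 0, 20), 20, 20)
  for (b in c(0, 5, 12)) {
    brute <- mean(img[img > b])   # brute-force loop oracle
    expect_equal(mean_brightness(img, background = b), brute)
  }
  expect_error(mean_brightness(matrix(1, 3, 3), background = 5),
               "no pixels")
})

test_that("pearson colocalization matches the direct formula and identities", {
  set.seed(2)
  a <- matrix(rnorm(64, 10), 8, 8)
  expect_equal(pearson_coloc(a, a), 1)
  expect_equal(pearson_coloc(a, 30 - a), -1)
  # hand-computed 4-pixel example: cov = 4, both SS = 5 -> r = 0.8
  expect_equal(pearson_coloc(matrix(1:4, 2), matrix(c(1, 3, 2, 4), 2)), 0.8)
  b <- matrix(rnorm(64, 10), 8, 8)
  expect_equal(pearson_coloc(a, b), pearson_two_pass(a, b))
  expect_equal(pearson_coloc(a, b), pearson_coloc(b, a))
  # invariance under positive affine rescaling
  expect_equal(pearson_coloc(2.5 * a + 7, b), pearson_coloc(a, b))
  expect_error(pearson_coloc(matrix(1, 3, 3), a[1:3, 1:3]), "variance")
})

test_that("ratio maps are smoothed ratios above background", {
  det2 <- matrix(100, 16, 16)
  pair <- channel_pair(image2d(2 * det2), image2d(det2))
  rm_ <- ratio_map(pair, sigma = 1.5, background = 10)
  expect_true(all(rm_$valid_mask))
  expect_equal(rm_$ratio, matrix(2, 16, 16))
  # background above the maximum: all-invalid map, not an error
  rm2 <- ratio_map(pair, sigma = 1.5, background = 500)
  expect_false(any(rm2$valid_mask))
  expect_true(all(is.na(rm2$ratio)))
})

test_that("ratio maps commute with a common detector rescaling", {
  set.seed(3)
  d1 <- matrix(rpois(256, 120), 16, 16)
  d2 <- matrix(rpois(256, 80), 16, 16)
  r1 <- ratio_map(channel_pair(image2d(d1), image2d(d2)), background = 10)
  r2 <- ratio_map(channel_pair(image2d(3 * d1), image2d(3 * d2)),
                  background = 30)
  expect_equal(r1$valid_mask, r2$valid_mask)
  expect_equal(r1$ratio, r2$ratio)
})

test_that("compartment ratios on synthetic scenes are recovered within 5%", {
  cfg <- synth_image_config(
    image_shape = c(72L, 72L), photon_budget = 3000, seed = 31,
    compartments = list(
      list(class = "vesicle",
           shape = list(type = "disk", center = c(24, 36), radius = 10),
           ratio = 1.2),
      list(class = "PM", shape = list(type = "border", width = 4),
           ratio = 0.8)))
  s <- generate_ratiometric_scene(cfg)
  rm_ <- ratio_map(s$pair, sigma = 1.5, background = 20)
  cs <- compartment_stats(rm_, s$masks)
  med <- cs$summary$median_ratio
  names(med) <- cs$summary$class
  expect_lt(abs(med[["vesicle"]] - 1.2) / 1.2, 0.05)
  expect_lt(abs(med[["PM"]] - 0.8) / 0.8, 0.05)
  # ordering preserved and untouched classes empty
  expect_lt(med[["PM"]], med[["vesicle"]])
  expect_equal(cs$summary$n_pixels[cs$summary$class == "tubule"], 0)
})

test_that("normalization divides by the median and is idempotent", {
  pair <- channel_pair(image2d(matrix(200, 8, 8)), image2d(matrix(100, 8, 8)))
  rm_ <- ratio_map(pair, sigma = 0, background = 10)
  n1 <- normalize_ratio(rm_)
  expect_equal(n1$ratio, matrix(1, 8, 8))
  expect_equal(n1$normalization_constant, 2)
  n2 <- normalize_ratio(n1)
  expect_equal(n2$ratio, n1$ratio)
  # reference-region mode maps the reference median to exactly 1
  set.seed(4)
  d1 <- matrix(rpois(256, 150), 16, 16)
  rmr <- ratio_map(channel_pair(image2d(d1), image2d(matrix(100, 16, 16))),
                   sigma = 0, background = 5)
  ref <- matrix(FALSE, 16, 16); ref[1:8, ] <- TRUE
  nr <- normalize_ratio(rmr, "reference-region", reference = ref)
  expect_equal(stats::median(nr$ratio[ref & nr$valid_mask]), 1)
  expect_error(normalize_ratio(rmr, "reference-region",
                               reference = matrix(FALSE, 16, 16)),
               "reference")
})

test_that("the MAD filter removes gross outliers and nothing else", {
  v <- c(1:10, 1000)
  kept <- mad_filter(v, k = 3)
  expect_false(1000 %in% kept)
  expect_setequal(kept, 1:10)
  expect_equal(mad_filter(rep(5, 10)), rep(5, 10))    # MAD = 0 keeps median
  sym <- c(-2, -1, -1, 0, 0, 0, 1, 1, 2)
  expect_equal(mad_filter(sym, k = 3), sym)            # nothing beyond 3 MAD
})

test_that("compartment statistics depend only on in-mask pixels", {
  det2 <- matrix(100, 20, 20)
  pair <- channel_pair(image2d(2 * det2), image2d(det2))
  rm_ <- ratio_map(pair, sigma = 0, background = 10)
  labels <- matrix(0L, 20, 20); labels[5:10, 5:10] <- 1L
  cs1 <- compartment_stats(rm_, compartment_masks(labels))
  expect_equal(cs1$summary$median_ratio[cs1$summary$class == "vesicle"], 2)
  # a wild out-of-mask pixel changes nothing
  rm_$ratio[15, 15] <- 1e6
  cs2 <- compartment_stats(rm_, compartment_masks(labels))
  expect_identical(cs1$summary, cs2$summary)
  expect_error(compartment_stats(rm_, compartment_masks(matrix(0L, 5, 5))),
               "shape")
})

test_that("droplet classification follows green emission monotonically", {
  mask <- matrix(FALSE, 24, 24)
  mask[4:8, 4:8] <- TRUE          # component A
  mask[15:20, 15:20] <- TRUE      # component B
  green <- matrix(0, 24, 24)
  expect_equal(sum(classify_droplets(mask, green, 10)$ld_mask), 0)
  green[15:20, 15:20] <- 50       # only B bright in green
  cl <- classify_droplets(mask, green, 10)
  expect_true(all(cl$ld_mask[15:20, 15:20]))
  expect_false(any(cl$ld_mask[4:8, 4:8]))
  # partition is exclusive and exhaustive
  expect_identical(cl$ld_mask | cl$vesicle_mask, mask)
  expect_false(any(cl$ld_mask & cl$vesicle_mask))
  n_ld <- vapply(c(0, 25, 60, 100), function(th)
    sum(classify_droplets(mask, green, th)$ld_mask), numeric(1))
  expect_true(all(diff(n_ld) <= 0))   # non-increasing in the threshold
})
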