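#' Mean brightness above a background threshold
#'
#' Mean of all pixel values strictly above `background`; pixels at or below
#' the threshold are omitted. An image with no qualifying pixel is an error,
#' never silently 0.
#'
#' @param img an [image2d()] or numeric matrix.
#' @param background background threshold in counts (>= 0).
#' @return Mean counts of the foreground pixels.
#' @export
mean_brightness <- function(img, background = 0) {
  if (background < 0) stop("background must be >= 0")
  v <- as_image_values(img)
  fg <- v[v > background]
  if (length(fg) == 0L)
    stop("no pixels above the background threshold")
  mean(fg)
}

#' Pearson colocalization coefficient
#'
#' Pearson correlation of two channels over a foreground mask:
#' `sum((a - mean(a)) * (b - mean(b))) / sqrt(sum((a - mean(a))^2) *
#' sum((b - mean(b))^2))`. Symmetric in its arguments and invariant to
#' positive affine rescaling of either channel.
#'
#' @param ch1,ch2 [image2d()] objects or matrices of identical shape.
#' @param foreground optional logical matrix selecting the pixels to use
#'   (default: all).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_coloc <- function(ch1, ch2, foreground = NULL) {
  a <- as_image_values(ch1); b <- as_image_values(ch2)
  if (!identical(dim(a), dim(b))) stop("channel shapes differ")
  if (is.null(foreground)) foreground <- matrix(TRUE, nrow(a), ncol(a))
  if (!identical(dim(foreground), dim(a))) stop("mask shape differs")
  av <- a[foreground]; bv <- b[foreground]
  if (length(av) < 2L) stop("need at least 2 foreground pixels")
  if (stats::var(av) == 0 || stats::var(bv) == 0)
    stop("undefined correlation: zero variance in a channel")
  stats::cor(av, bv)
}

# separable Gaussian convolution with reflective (mirror) boundary handling;
# kernel truncated at 4 sigma
smooth_gaussian <- function(mat, sigma) {
  if (sigma == 0) return(mat)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  reflect_idx <- function(p, n) {
    if (n == 1L) return(rep(1L, length(p)))
    q <- (p - 1L) %% (2L * (n - 1L))
    ifelse(q >= n, 2L * (n - 1L) - q, q) + 1L
  }
  conv1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (j in seq_along(k))
      out <- out + k[j] * v[reflect_idx(seq_len(n) + (j - r - 1L), n)]
    out
  }
  sm <- apply(mat, 2L, conv1)              # along rows
  t(apply(sm, 1L, conv1))                  # along columns
}

#' Per-pixel det1/det2 ratio map
#'
#' Smooths each detector image with a Gaussian filter (default sigma 1.5 px,
#' reflective boundaries), then forms the det1/det2 ratio on pixels where
#' both smoothed images exceed the background level. Thresholding happens on
#' the smoothed images, matching the order filter-then-threshold; requiring a
#' strictly positive background guarantees no division by zero on valid
#' pixels.
#'
#' @param pair a [channel_pair()].
#' @param sigma Gaussian filter sigma in pixels (>= 0, default 1.5).
#' @param background background level(s) in counts, strictly positive; a
#'   single value applies to both detectors, a length-2 vector gives
#'   per-detector levels `(det1, det2)`.
#' @return An object of class `ratio_map`: list with `ratio` (matrix, NA on
#'   invalid pixels), `valid_mask`, `normalization_constant` (1 until
#'   [normalize_ratio()] is applied), `pixel_size`, `sigma`, `background`.
#' @export
ratio_map <- function(pair, sigma = 1.5, background) {
  stopifnot(inherits(pair, "channel_pair"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (length(background) == 1L) background <- rep(background, 2L)
  if (length(background) != 2L || any(background <= 0))
    stop("background must be one or two strictly positive values")
  s1 <- smooth_gaussian(pair$det1$values, sigma)
  s2 <- smooth_gaussian(pair$det2$values, sigma)
  valid <- s1 > background[1] & s2 > background[2]
  ratio <- matrix(NA_real_, nrow(s1), ncol(s1))
  ratio[valid] <- s1[valid] / s2[valid]
  structure(list(ratio = ratio, valid_mask = valid,
                 normalization_constant = 1,
                 pixel_size = pair$det1$pixel_size,
                 sigma = sigma, background = background),
            class = "ratio_map")
}

#' @export
print.ratio_map <- function(x, ...) {
  cat(sprintf(
    "<ratio_map> %d x %d px, %d valid (%.1f%%), normalization %g\n",
    nrow(x$ratio), ncol(x$ratio), sum(x$valid_mask),
    100 * mean(x$valid_mask), x$normalization_constant))
  invisible(x)
}

#' Normalize a ratio map
#'
#' Divides the ratio by a normalization constant: the global median of valid
#' pixels, or the median over a supplied reference region. The constant used
#' is stored in the result, and the operation is idempotent on the values
#' (normalizing twice equals normalizing once).
#'
#' @param rm a [ratio_map()].
#' @param mode `"global-median"` or `"reference-region"`.
#' @param reference logical matrix selecting the reference region (required
#'   for `"reference-region"`).
#' @return The normalized `ratio_map` with `normalization_constant` set to
#'   the median that was divided out.
#' @export
normalize_ratio <- function(rm, mode = c("global-median", "reference-region"),
                            reference = NULL) {
  stopifnot(inherits(rm, "ratio_map"))
  mode <- match.arg(mode)
  if (!any(rm$valid_mask)) stop("no valid pixels to normalize")
  sel <- if (mode == "global-median") rm$valid_mask else {
    if (is.null(reference)) stop("reference-region mode needs a reference mask")
    if (!identical(dim(reference), dim(rm$ratio)))
      stop("reference mask shape differs")
    keep <- reference & rm$valid_mask
    if (!any(keep)) stop("reference region contains no valid pixels")
    keep
  }
  const <- stats::median(rm$ratio[sel])
  rm$ratio <- rm$ratio / const
  rm$normalization_constant <- const
  rm
}

#' Median-absolute-deviation outlier filter
#'
#' Keeps values within `k` median absolute deviations of the median
#' (`k = 3` by default, the convention used for pixel-ratio and score
#' distributions). The MAD is scaled by the usual consistency constant
#' 1.4826. If the MAD is zero only values equal to the median survive.
#'
#' @param values numeric vector (non-empty; NAs are dropped).
#' @param k MAD multiplier.
#' @param constant MAD scale factor (default `1.4826`, as in [stats::mad()]).
#' @return The filtered vector.
#' @export
mad_filter <- function(values, k = 3, constant = 1.4826) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("mad_filter needs a non-empty input")
  med <- stats::median(values)
  madv <- constant * stats::median(abs(values - med))
  if (madv == 0) values[values == med]
  else values[abs(values - med) <= k * madv]
}

#' Per-compartment ratio statistics
#'
#' Collects the valid ratio values inside each compartment class, applies the
#' MAD outlier filter per class, and reports the filtered values with their
#' median and pixel count. Classes with no valid pixel are reported as empty
#' rather than raising an error. Only pixels inside the masks can influence
#' the result.
#'
#' @param rm a [ratio_map()].
#' @param masks [compartment_masks()] aligned with the map.
#' @param k MAD multiplier for the outlier filter.
#' @return List with `summary` (data.frame: class, label, n_pixels,
#'   median_ratio, mad) and `values` (named list of MAD-filtered per-class
#'   pixel ratios).
#' @export
compartment_stats <- function(rm, masks, k = 3) {
  stopifnot(inherits(rm, "ratio_map"), inherits(masks, "compartment_masks"))
  if (!identical(dim(masks$labels), dim(rm$ratio)))
    stop("mask and ratio map shapes differ")
  classes <- names(.compartment_levels)
  values <- stats::setNames(vector("list", length(classes)), classes)
  rows <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    lab <- .compartment_levels[[classes[i]]]
    v <- rm$ratio[rm$valid_mask & masks$labels == lab]
    v <- if (length(v)) mad_filter(v, k = k) else numeric(0)
    values[[i]] <- v
    rows[[i]] <- data.frame(
      class = classes[i], label = lab, n_pixels = length(v),
      median_ratio = if (length(v)) stats::median(v) else NA_real_,
      mad = if (length(v)) stats::mad(v) else NA_real_)
  }
  list(summary = do.call(rbind, rows), values = values)
}

#' Split vesicles into vesicles and lipid droplets by green emission
#'
#' Labels the connected components of a vesicle mask and relabels as lipid
#' droplets those components whose mean green intensity exceeds the
#' threshold. The partition is exclusive and exhaustive over the input
#' vesicle pixels, and the number of droplets is non-increasing in the
#' threshold.
#'
#' @param vesicle_mask logical matrix of vesicle pixels.
#' @param green green-channel [image2d()] or matrix.
#' @param green_threshold mean-green threshold in counts (>= 0).
#' @return List with logical matrices `vesicle_mask` and `ld_mask`.
#' @export
classify_droplets <- function(vesicle_mask, green, green_threshold) {
  if (green_threshold < 0) stop("green_threshold must be >= 0")
  g <- as_image_values(green)
  if (!identical(dim(vesicle_mask), dim(g))) stop("shapes differ")
  comp <- EBImage::bwlabel(vesicle_mask * 1)
  ld <- matrix(FALSE, nrow(g), ncol(g))
  for (lab in setdiff(unique(as.vector(comp)), 0)) {
    px <- comp == lab
    if (mean(g[px]) > green_threshold) ld[px] <- TRUE
  }
  list(vesicle_mask = vesicle_mask & !ld, ld_mask = ld)
}
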