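#' Two-dimensional microscopy image
#'
#' Lightweight container for a single-detector count image. Values are photon
#' counts (or any finite per-pixel quantity); `pixel_size` is the physical
#' pixel pitch in nanometres. Images are indexed row-major with the origin at
#' the top-left corner, x increasing along columns and y along rows — the same
#' convention used by the track CSV schema, so masks, images and localizations
#' align without further bookkeeping.
#'
#' @param values numeric matrix of per-pixel values; must be finite.
#' @param pixel_size pixel pitch in nm (default 1).
#' @return An object of class `image2d` with elements `values` and
#'   `pixel_size`.
#' @examples
#' img <- image2d(matrix(rpois(64, 50), 8, 8), pixel_size = 40)
#' mean_brightness(img, background = 10)
#' @export
image2d <- function(values, pixel_size = 1) {
  values <- as.matrix(values)
  if (!is.numeric(values) || length(dim(values)) != 2L)
    stop("'values' must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("image must be at least 1x1")
  if (!all(is.finite(values)))
    stop("image values must all be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number")
  structure(list(values = values, pixel_size = as.numeric(pixel_size)),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px, pixel size %g nm, range [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.image2d <- function(x) dim(x$values)

as_image_values <- function(img) {
  if (inherits(img, "image2d")) img$values else as.matrix(img)
}

#' Registered two-detector channel pair
#'
#' Holds the two registered detector images of a ratiometric acquisition:
#' `det1` is the far-red detector, `det2` the shorter-wavelength red detector.
#' The det1/det2 ratio tracks the polarity-dependent red shift of
#' solvatochromic probes (lower ratio, tighter lipid packing).
#'
#' @param det1,det2 `image2d` objects with identical shape and pixel size.
#' @return An object of class `channel_pair`.
#' @export
channel_pair <- function(det1, det2) {
  if (!inherits(det1, "image2d")) det1 <- image2d(det1)
  if (!inherits(det2, "image2d")) det2 <- image2d(det2)
  if (!identical(dim(det1$values), dim(det2$values)))
    stop("det1 and det2 must have identical shapes")
  if (det1$pixel_size != det2$pixel_size)
    stop("det1 and det2 must have identical pixel sizes")
  structure(list(det1 = det1, det2 = det2), class = "channel_pair")
}

#' @export
print.channel_pair <- function(x, ...) {
  cat(sprintf("<channel_pair> %d x %d px, pixel size %g nm\n",
              nrow(x$det1$values), ncol(x$det1$values), x$det1$pixel_size))
  invisible(x)
}

#' Time-binned FLIM photon-count stack
#'
#' Per-pixel photon-arrival histograms from time-correlated counting. The
#' stack is an array `rows x cols x bins`; bin k covers
#' `[offset + (k-1)*bin_width, offset + k*bin_width)` ns and is represented by
#' its centre `offset + (k - 1/2)*bin_width`. `rep_period` is the laser
#' repetition period in ns (25 ns for an 80/2 = 40 MHz pulsed source).
#'
#' @param counts numeric array `rows x cols x bins` of (possibly
#'   noise-perturbed, hence possibly negative) counts.
#' @param bin_width time-bin width in ns.
#' @param offset acquisition offset of the first bin edge in ns.
#' @param rep_period laser repetition period in ns (default 25).
#' @param pixel_size pixel pitch in nm.
#' @return An object of class `flim_stack`.
#' @seealso [flim_time_centers()], [linearized_lifetime_fit()]
#' @export
flim_stack <- function(counts, bin_width, offset = 0, rep_period = 25,
                       pixel_size = 1) {
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("'counts' must be a rows x cols x bins array")
  if (!all(is.finite(counts))) stop("counts must be finite")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  if (offset < 0) stop("offset must be >= 0")
  duration <- dim(counts)[3L] * bin_width
  if (duration > rep_period)
    warning("time window exceeds the repetition period")
  structure(list(counts = counts, bin_width = as.numeric(bin_width),
                 offset = as.numeric(offset),
                 rep_period = as.numeric(rep_period),
                 pixel_size = as.numeric(pixel_size)),
            class = "flim_stack")
}

#' Bin-centre time grid of a FLIM stack
#'
#' @param stack a `flim_stack`.
#' @return Numeric vector of bin centres in ns,
#'   `offset + (k - 1/2) * bin_width` for k = 1..bins.
#' @export
flim_time_centers <- function(stack) {
  stopifnot(inherits(stack, "flim_stack"))
  k <- seq_len(dim(stack$counts)[3L])
  stack$offset + (k - 0.5) * stack$bin_width
}

#' @export
print.flim_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<flim_stack> %d x %d px, %d bins of %g ns (offset %g ns, period %g ns)\n",
    d[1], d[2], d[3], x$bin_width, x$offset, x$rep_period))
  invisible(x)
}

#' @export
dim.flim_stack <- function(x) dim(x$counts)

# canonical label encoding shared by masks, the scene generator and the io
# layer; 0 is background
.compartment_levels <- c(vesicle = 1L, LD = 2L, tubule = 3L, PM = 4L,
                         filopodium = 5L)

#' Integer-labelled compartment masks
#'
#' One label per pixel: 0 background, 1 vesicle, 2 lipid droplet (LD),
#' 3 tubule, 4 plasma membrane (PM), 5 filopodium.
#'
#' @param labels integer matrix of per-pixel labels in 0..5.
#' @param pixel_size pixel pitch in nm.
#' @return An object of class `compartment_masks`.
#' @export
compartment_masks <- function(labels, pixel_size = 1) {
  labels <- as.matrix(labels)
  if (!all(labels %in% 0:5))
    stop("labels must be integers in 0..5")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, pixel_size = as.numeric(pixel_size)),
            class = "compartment_masks")
}

#' @export
print.compartment_masks <- function(x, ...) {
  tab <- table(factor(x$labels, levels = 0:5,
                      labels = c("background", names(.compartment_levels))))
  cat(sprintf("<compartment_masks> %d x %d px\n",
              nrow(x$labels), ncol(x$labels)))
  print(tab)
  invisible(x)
}

#' Compartment label codes
#'
#' @return Named integer vector mapping compartment class names to mask
#'   labels (background is 0 and has no entry).
#' @export
compartment_codes <- function() .compartment_levels

#' Single-molecule track ensemble
#'
#' A time-ordered table of 2D localizations grouped by molecule. Columns:
#' `track_id` (integer or character), `t_ms` (time in ms, strictly increasing
#' within a track), `x_nm`, `y_nm` (position in nm, origin at the image
#' top-left, x rightward, y downward) and `photons` (photon count per
#' localization, >= 1).
#'
#' @param df data.frame with the five schema columns.
#' @param truth optional list of ground-truth parameters attached by the
#'   simulator (kept as attribute `truth`).
#' @return An object of classes `track_ensemble` and `data.frame`.
#' @export
track_ensemble <- function(df, truth = NULL) {
  need <- c("track_id", "t_ms", "x_nm", "y_nm", "photons")
  if (!all(need %in% names(df)))
    stop("track table must have columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (any(!is.finite(df$t_ms))) stop("t_ms must be finite")
  if (any(df$photons < 1)) stop("photons must be >= 1")
  df <- df[order(df$track_id, df$t_ms), , drop = FALSE]
  rownames(df) <- NULL
  dup <- unlist(tapply(df$t_ms, df$track_id, function(t) c(FALSE, diff(t) <= 0)))
  if (any(dup)) stop("t_ms must be strictly increasing within each track")
  structure(df, class = c("track_ensemble", "data.frame"), truth = truth)
}

#' @export
print.track_ensemble <- function(x, ...) {
  cat(sprintf("<track_ensemble> %d localizations in %d tracks\n",
              nrow(x), length(unique(x$track_id))))
  NextMethod()
}

split_tracks <- function(ensemble) {
  split(as.data.frame(ensemble), ensemble$track_id)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generator determinism contracts flow through here.
with_fixed_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
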