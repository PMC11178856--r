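#' Configuration for a synthetic ratiometric scene
#'
#' Describes a two-detector scene with labelled membrane compartments, each
#' carrying a ground-truth det1/det2 emission ratio and a ground-truth green
#' fraction (share of the photon budget emitted in the green channel, used to
#' emulate lipid-droplet staining). Geometry primitives cover the five
#' compartment classes: disks (vesicles/LDs), annuli (vesicle rims), lines
#' (tubules, filopodia) and border bands (plasma membrane).
#'
#' @param image_shape integer vector `c(rows, cols)` in pixels.
#' @param pixel_size pixel pitch in nm.
#' @param compartments list of compartment descriptions, each a list with
#'   elements `class` (one of `"vesicle"`, `"LD"`, `"tubule"`, `"PM"`,
#'   `"filopodium"`), `shape` (see Details), `ratio` (> 0) and optional
#'   `green_frac` in `[0, 1]` (default 0).
#' @param background_level expected background counts per pixel per detector.
#' @param photon_budget expected total counts per in-compartment pixel across
#'   both detectors; `Inf` disables Poisson noise entirely.
#' @param seed RNG seed; a fixed seed makes the generated scene bit-identical
#'   across calls.
#'
#' @details A `shape` is a list with a `type` field:
#' * `disk`: `center = c(row, col)`, `radius` (px);
#' * `annulus`: `center`, `r_inner`, `r_outer` (px);
#' * `line`: `from = c(row, col)`, `to = c(row, col)`, `halfwidth` (px);
#' * `border`: `width` (px) band along the image edge.
#'
#' @return An object of class `synth_image_config`.
#' @export
synth_image_config <- function(image_shape = c(96L, 96L), pixel_size = 40,
                               compartments = list(),
                               background_level = 2,
                               photon_budget = 2000, seed = 1L) {
  if (length(image_shape) != 2L || any(image_shape < 1))
    stop("image_shape must be two positive integers")
  for (cp in compartments) {
    if (!cp$class %in% names(.compartment_levels))
      stop("unknown compartment class: ", cp$class)
    if (is.null(cp$ratio) || cp$ratio <= 0)
      stop("every compartment needs a ground-truth ratio > 0")
    gf <- if (is.null(cp$green_frac)) 0 else cp$green_frac
    if (gf < 0 || gf > 1) stop("green_frac must be in [0, 1]")
  }
  if (background_level < 0) stop("background_level must be >= 0")
  if (photon_budget <= 0) stop("photon_budget must be > 0")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size,
                 compartments = compartments,
                 background_level = background_level,
                 photon_budget = photon_budget,
                 seed = seed),
            class = "synth_image_config")
}

rasterize_shape <- function(shape, dims) {
  rr <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  switch(shape$type,
    disk = {
      d2 <- (rr - shape$center[1])^2 + (cc - shape$center[2])^2
      d2 <= shape$radius^2
    },
    annulus = {
      d2 <- (rr - shape$center[1])^2 + (cc - shape$center[2])^2
      d2 <= shape$r_outer^2 & d2 >= shape$r_inner^2
    },
    line = {
      # distance from each pixel centre to the segment from..to
      a <- shape$from; b <- shape$to
      ab <- b - a
      len2 <- sum(ab^2)
      tpar <- if (len2 == 0) 0 else
        pmin(1, pmax(0, ((rr - a[1]) * ab[1] + (cc - a[2]) * ab[2]) / len2))
      d2 <- (rr - (a[1] + tpar * ab[1]))^2 + (cc - (a[2] + tpar * ab[2]))^2
      d2 <= shape$halfwidth^2
    },
    border = {
      w <- shape$width
      rr <= w | rr > dims[1] - w | cc <= w | cc > dims[2] - w
    },
    stop("unknown shape type: ", shape$type)
  )
}

#' Generate a synthetic two-detector ratiometric scene
#'
#' Builds label masks from the configured geometry, assigns each compartment
#' pixel an expected detector split `det1 = ratio/(1+ratio) * budget`,
#' `det2 = budget/(1+ratio)` (so the expected det1/det2 ratio equals the
#' ground truth exactly before noise), sets background pixels to
#' `background_level` in both detectors, and applies independent per-pixel
#' Poisson noise unless the photon budget is infinite. A green-channel image
#' is generated the same way from each compartment's `green_frac`.
#'
#' Compartments of different classes must not overlap; the configuration is
#' rejected otherwise. Same-class overlaps merge.
#'
#' @param config a [synth_image_config()].
#' @return A list with elements `pair` ([channel_pair]), `green` ([image2d]),
#'   `masks` ([compartment_masks]), `truth` (data.frame: label, class, ratio,
#'   green_frac, n_pixels) and `config`.
#' @export
generate_ratiometric_scene <- function(config) {
  stopifnot(inherits(config, "synth_image_config"))
  dims <- config$image_shape
  # an infinite budget means "no shot noise": expected intensities are
  # rendered at a nominal 1000-count scale (the ratio is scale-free)
  noiseless <- !is.finite(config$photon_budget)
  budget <- if (noiseless) 1000 else config$photon_budget
  labels <- matrix(0L, dims[1], dims[2])
  claimed_class <- matrix(NA_character_, dims[1], dims[2])
  det1 <- matrix(config$background_level, dims[1], dims[2])
  det2 <- matrix(config$background_level, dims[1], dims[2])
  green <- matrix(config$background_level, dims[1], dims[2])
  truth <- list()
  for (cp in config$compartments) {
    m <- rasterize_shape(cp$shape, dims)
    clash <- m & !is.na(claimed_class) & claimed_class != cp$class
    if (any(clash))
      stop("compartments of different classes overlap (",
           cp$class, " vs ", claimed_class[which(clash)[1]], ")")
    claimed_class[m] <- cp$class
    lab <- .compartment_levels[[cp$class]]
    labels[m] <- lab
    gf <- if (is.null(cp$green_frac)) 0 else cp$green_frac
    det2[m] <- budget / (1 + cp$ratio)
    det1[m] <- budget * cp$ratio / (1 + cp$ratio)
    green[m] <- budget * gf
    truth[[length(truth) + 1L]] <-
      data.frame(label = lab, class = cp$class, ratio = cp$ratio,
                 green_frac = gf, n_pixels = sum(m))
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(label = integer(), class = character(), ratio = numeric(),
               green_frac = numeric(), n_pixels = integer())
  if (!noiseless) {
    with_fixed_seed(config$seed, {
      det1 <- matrix(stats::rpois(length(det1), det1), dims[1], dims[2])
      det2 <- matrix(stats::rpois(length(det2), det2), dims[1], dims[2])
      green <- matrix(stats::rpois(length(green), green), dims[1], dims[2])
    })
  }
  list(pair = channel_pair(image2d(det1, config$pixel_size),
                           image2d(det2, config$pixel_size)),
       green = image2d(green, config$pixel_size),
       masks = compartment_masks(labels, config$pixel_size),
       truth = truth,
       config = config)
}
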