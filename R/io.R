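# --- TIFF + YAML-sidecar storage -------------------------------------------
#
# The tiff package stores 32-bit samples as an unsigned-integer mapping of
# [0, 1]; true float32 samples are not available. Images are therefore
# rescaled to [0, 1] with the value range recorded in a YAML sidecar
# (<path>.yaml). Integer data is rounded on read and round-trips exactly;
# float maps round-trip to ~2e-10 of the value range.

sidecar_path <- function(path) paste0(path, ".yaml")

encode_plane <- function(m, lo, hi) {
  if (hi == lo) matrix(0, nrow(m), ncol(m)) else (m - lo) / (hi - lo)
}

decode_plane <- function(m, lo, hi, integer) {
  out <- m * (hi - lo) + lo
  if (integer) round(out) else out
}

# restore integer storage for data flagged integer in the sidecar, so that
# integer-valued inputs round-trip with their original type
maybe_integerize <- function(x, meta) {
  if (isTRUE(meta$integer) &&
      max(abs(range(x))) <= .Machine$integer.max) storage.mode(x) <- "integer"
  x
}

#' Write / read a 2D image as TIFF with a YAML sidecar
#'
#' `write_image` stores an [image2d()] as a single-page 32-bit TIFF plus a
#' YAML sidecar (`<path>.yaml`) holding the pixel size, the value range used
#' for scaling, and whether the data is integer-valued (integer images
#' round-trip losslessly). `read_image` reverses the mapping; a missing
#' sidecar is an explicit error listing the required keys.
#'
#' @param img an [image2d()].
#' @param path TIFF file path.
#' @return `write_image` returns `path` invisibly; `read_image` returns an
#'   [image2d()].
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "image2d"))
  v <- img$values
  lo <- min(v); hi <- max(v)
  is_int <- all(v == round(v))
  tiff::writeTIFF(encode_plane(v, lo, hi), path, bits.per.sample = 32L)
  yaml::write_yaml(list(kind = "image2d", pixel_size = img$pixel_size,
                        value_min = lo, value_max = hi, integer = is_int),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  meta <- read_sidecar(path, c("pixel_size", "value_min", "value_max",
                               "integer"))
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  v <- decode_plane(m, meta$value_min, meta$value_max, meta$integer)
  image2d(maybe_integerize(v, meta), pixel_size = meta$pixel_size)
}

read_sidecar <- function(path, required) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing metadata sidecar ", sp, "; required keys: ",
         paste(required, collapse = ", "))
  meta <- yaml::read_yaml(sp)
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("metadata sidecar ", sp, " lacks required keys: ",
         paste(missing, collapse = ", "))
  meta
}

#' Write / read a FLIM stack as multi-page TIFF with YAML metadata
#'
#' One TIFF page per time bin; the sidecar records `bin_width`, `offset`,
#' `rep_period`, `pixel_size` and the value scaling. Reading a stack whose
#' sidecar is missing or lacks the time-grid keys is an explicit error
#' naming the missing keys.
#'
#' @param stack a [flim_stack()].
#' @param path TIFF file path.
#' @return `write_flim_stack` returns `path` invisibly; `read_flim_stack`
#'   returns a [flim_stack()].
#' @export
write_flim_stack <- function(stack, path) {
  stopifnot(inherits(stack, "flim_stack"))
  v <- stack$counts
  lo <- min(v); hi <- max(v)
  is_int <- all(v == round(v))
  pages <- lapply(seq_len(dim(v)[3]),
                  function(k) encode_plane(v[, , k], lo, hi))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(kind = "flim_stack", bin_width = stack$bin_width,
                        offset = stack$offset, rep_period = stack$rep_period,
                        pixel_size = stack$pixel_size,
                        value_min = lo, value_max = hi, integer = is_int),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_flim_stack
#' @export
read_flim_stack <- function(path) {
  meta <- read_sidecar(path, c("bin_width", "offset", "rep_period",
                               "value_min", "value_max", "integer"))
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    arr[, , k] <- decode_plane(p, meta$value_min, meta$value_max,
                               meta$integer)
  }
  arr <- maybe_integerize(arr, meta)
  flim_stack(arr, bin_width = meta$bin_width, offset = meta$offset,
             rep_period = meta$rep_period,
             pixel_size = if (is.null(meta$pixel_size)) 1 else
               meta$pixel_size)
}

#' Write / read compartment label masks as TIFF
#'
#' @param masks a [compartment_masks()].
#' @param path TIFF file path.
#' @return `write_masks` returns `path` invisibly; `read_masks` a
#'   [compartment_masks()].
#' @export
write_masks <- function(masks, path) {
  stopifnot(inherits(masks, "compartment_masks"))
  tiff::writeTIFF(masks$labels / 255, path, bits.per.sample = 8L)
  yaml::write_yaml(list(kind = "compartment_masks",
                        pixel_size = masks$pixel_size,
                        encoding = "0 background, 1 vesicle, 2 LD, 3 tubule, 4 PM, 5 filopodium"),
                   sidecar_path(path))
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path) {
  meta <- read_sidecar(path, "pixel_size")
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  compartment_masks(round(m * 255), pixel_size = meta$pixel_size)
}

# format doubles so that write -> read -> write is byte-identical ( %.17g
# strings parse back to the same double)
fmt_g17 <- function(x) {
  if (is.integer(x) || all(x == round(x))) format(x, scientific = FALSE)
  else sprintf("%.17g", x)
}

#' Write / read single-molecule tracks as CSV
#'
#' Columns: `track_id`, `t_ms`, `x_nm`, `y_nm`, `photons` (nm / ms units,
#' origin at the image top-left, x rightward, y downward). Doubles are
#' serialized with 17 significant digits so that write -> read -> write
#' round-trips bit-identically.
#'
#' @param ensemble a [track_ensemble()].
#' @param path CSV file path.
#' @return `write_tracks` returns `path` invisibly; `read_tracks` a
#'   [track_ensemble()].
#' @export
write_tracks <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "track_ensemble"))
  df <- as.data.frame(ensemble)
  lines <- c("track_id,t_ms,x_nm,y_nm,photons",
             paste(df$track_id, fmt_g17(df$t_ms), fmt_g17(df$x_nm),
                   fmt_g17(df$y_nm), df$photons, sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  track_ensemble(df)
}
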