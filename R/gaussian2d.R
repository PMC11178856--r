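#' Vesicle size estimation by 2D Gaussian fitting
#'
#' Detects isolated blob-like local maxima above a detection threshold and
#' fits each with an axis-aligned elliptical 2D Gaussian plus constant
#' offset,
#' `A * exp(-((x - x0)^2 / (2 sx^2) + (y - y0)^2 / (2 sy^2))) + b`,
#' in a square window of half-width `ceiling(3.5 * psf_sigma)` pixels (7
#' nominal PSF sigmas wide) centred on the maximum. Overlapping detections
#' are resolved brighter-peak-first. The full width at half maximum per axis
#' is `2 * sqrt(2 * log(2)) * sigma`. Fits that fail to converge, or whose
#' FWHM exceeds the fitting window, are discarded.
#'
#' @param img an [image2d()] (pixel size used to report nm) or matrix.
#' @param detection_threshold minimum peak height in counts.
#' @param psf_sigma nominal PSF sigma in pixels (sets the window size and the
#'   fit initialization; default 2).
#' @return data.frame with one row per accepted fit: `center_x_nm`,
#'   `center_y_nm` (x along columns, y along rows, origin at the top-left
#'   pixel centre), `fwhm_x_nm`, `fwhm_y_nm`, `amplitude`, `offset`,
#'   `fit_residual` (RMS residual / amplitude). Zero detections give an
#'   empty data.frame.
#' @export
vesicle_fwhm <- function(img, detection_threshold, psf_sigma = 2) {
  px_nm <- if (inherits(img, "image2d")) img$pixel_size else 1
  v <- as_image_values(img)
  nr <- nrow(v); nc <- ncol(v)
  half <- ceiling(3.5 * psf_sigma)
  empty <- data.frame(center_x_nm = numeric(), center_y_nm = numeric(),
                      fwhm_x_nm = numeric(), fwhm_y_nm = numeric(),
                      amplitude = numeric(), offset = numeric(),
                      fit_residual = numeric())

  # 8-neighbourhood local maxima above threshold
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- v
  nbr_max <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nbr_max <- pmax(nbr_max,
                    pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc])
  }
  peaks <- which(v > detection_threshold & v >= nbr_max, arr.ind = TRUE)
  if (nrow(peaks) == 0L) return(empty)
  peaks <- peaks[order(v[peaks], decreasing = TRUE), , drop = FALSE]

  # greedy suppression: brighter peaks claim their window first
  taken <- matrix(FALSE, nr, nc)
  records <- list()
  for (p in seq_len(nrow(peaks))) {
    r0 <- unname(peaks[p, 1]); c0 <- unname(peaks[p, 2])
    if (taken[r0, c0]) next
    rs <- max(1L, r0 - half):min(nr, r0 + half)
    cs <- max(1L, c0 - half):min(nc, c0 + half)
    taken[rs, cs] <- TRUE
    win <- v[rs, cs]
    d <- data.frame(z = as.vector(win),
                    col = rep(cs, each = length(rs)),
                    row = rep(rs, times = length(cs)))
    st <- list(A = v[r0, c0] - min(win), x0 = c0, y0 = r0,
               sx = psf_sigma, sy = psf_sigma, b = min(win))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        z ~ A * exp(-((col - x0)^2 / (2 * sx^2) +
                      (row - y0)^2 / (2 * sy^2))) + b,
        data = d, start = st,
        lower = c(A = 0, x0 = min(cs), y0 = min(rs),
                  sx = 1e-3, sy = 1e-3, b = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    fw <- 2 * sqrt(2 * log(2)) * abs(cf[c("sx", "sy")])
    if (any(!is.finite(fw)) || any(fw <= 0) ||
        any(fw > (2 * half + 1)) || cf[["A"]] <= 0) next
    rms <- sqrt(mean(stats::resid(fit)^2))
    records[[length(records) + 1L]] <- data.frame(
      center_x_nm = (cf[["x0"]] - 1) * px_nm,
      center_y_nm = (cf[["y0"]] - 1) * px_nm,
      fwhm_x_nm = fw[["sx"]] * px_nm,
      fwhm_y_nm = fw[["sy"]] * px_nm,
      amplitude = cf[["A"]], offset = cf[["b"]],
      fit_residual = rms / cf[["A"]])
  }
  if (length(records) == 0L) return(empty)
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}
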