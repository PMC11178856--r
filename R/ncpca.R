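#' Poisson noise correction of a FLIM stack
#'
#' Stabilizes the Poisson variance of photon-count data by dividing each
#' time-bin image by the square root of that bin's mean intensity. The
#' scaling factors are recorded in the `correction_factors` attribute. The
#' operation is not idempotent: applying it again rescales by the corrected
#' stack's new bin means.
#'
#' @param stack a [flim_stack()]; every time-bin must have a strictly
#'   positive mean.
#' @return The corrected [flim_stack()] with attributes
#'   `correction_factors` (multipliers `1/sqrt(mean_k)`) and `bin_means`.
#' @export
poisson_noise_correct <- function(stack) {
  stopifnot(inherits(stack, "flim_stack"))
  means <- apply(stack$counts, 3L, mean)
  bad <- which(means <= 0)
  if (length(bad))
    stop("time-bin ", bad[1], " has non-positive mean intensity (",
         signif(means[bad[1]], 4), "); cannot noise-correct")
  fac <- 1 / sqrt(means)
  corrected <- sweep(stack$counts, 3L, fac, `*`)
  out <- flim_stack(corrected, bin_width = stack$bin_width,
                    offset = stack$offset, rep_period = stack$rep_period,
                    pixel_size = stack$pixel_size)
  attr(out, "correction_factors") <- fac
  attr(out, "bin_means") <- means
  out
}

same_time_grid <- function(a, b) {
  isTRUE(all.equal(a$bin_width, b$bin_width)) &&
    isTRUE(all.equal(a$offset, b$offset)) &&
    dim(a$counts)[3] == dim(b$counts)[3]
}

#' Noise-corrected principal component analysis of FLIM stacks
#'
#' Poisson-corrects each stack (each with its own bin means), treats every
#' foreground pixel's corrected decay curve as an observation, and
#' eigen-decomposes the pooled pixels' time-bin second-moment matrix. The
#' decomposition is deliberately uncentered: the first eigenvector is then
#' the intensity-weighted mean-decay direction (score 1 resembles an
#' intensity image), and the second captures the leading decay-shape
#' contrast, which is where lifetime differences between samples appear.
#' Each pixel is projected onto the leading eigenvectors to give per-pixel
#' score images, `s[PC, pixel] = sum_i v[PC, i] * I[i, pixel]` with `I` the
#' corrected decay. `scores` holds this raw projection; `scores_centered`
#' the projection of the mean-subtracted decay (useful for distributional
#' comparisons around zero). When several stacks are supplied the basis is
#' computed on the pooled pixels so scores are comparable across groups.
#'
#' Eigenvector signs are fixed by making each vector's largest-magnitude
#' element positive; the PCA sign is otherwise arbitrary and group
#' comparisons need a convention.
#'
#' @param stacks a [flim_stack()] or list of stacks sharing one time grid.
#' @param n_components number of score components to retain (default 4:
#'   higher components are typically at the noise level).
#' @param background foreground threshold on a pixel's total raw counts;
#'   pixels at or below it are excluded from the basis and scored NA.
#' @return For a single stack an `ncpca_result`: list with `eigenvectors`
#'   (`n_components` x bins), `eigenvalues` (all, descending; their sum
#'   equals `total_variance`, the mean squared norm of the pooled corrected
#'   decays), `scores` and `scores_centered` (`n_components` x rows x cols
#'   arrays), `center` (pooled mean corrected decay), `n_components`,
#'   `total_variance`. For a list of stacks, a list of `ncpca_result`s
#'   sharing the same basis.
#' @export
ncpca <- function(stacks, n_components = 4L, background = 0) {
  single <- inherits(stacks, "flim_stack")
  if (single) stacks <- list(stacks)
  if (!length(stacks) || !all(vapply(stacks, inherits, TRUE, "flim_stack")))
    stop("'stacks' must be a flim_stack or a list of them")
  for (s in stacks[-1])
    if (!same_time_grid(stacks[[1]], s))
      stop("stacks do not share a common time grid")
  nbin <- dim(stacks[[1]]$counts)[3]
  if (n_components < 1 || n_components > nbin)
    stop("n_components must be in 1..", nbin)

  corrected <- lapply(stacks, poisson_noise_correct)
  fg <- lapply(stacks, function(s) {
    tot <- apply(s$counts, c(1L, 2L), sum)
    tot > background
  })
  X <- do.call(rbind, lapply(seq_along(stacks), function(i) {
    m <- stack_pixel_matrix(corrected[[i]])
    m[as.vector(fg[[i]]), , drop = FALSE]
  }))
  if (nrow(X) < 2L) stop("need at least 2 foreground pixels")
  mu <- colMeans(X)
  # second-moment (uncentered) decomposition: the first component is then
  # the intensity-weighted mean-decay direction and the second the leading
  # decay-shape contrast, which is the separation the method relies on
  covm <- crossprod(X) / (nrow(X) - 1)
  eig <- eigen(covm, symmetric = TRUE)
  V <- eig$vectors
  # sign convention: largest-magnitude element of each eigenvector positive
  for (j in seq_len(ncol(V))) {
    k <- which.max(abs(V[, j]))
    if (V[k, j] < 0) V[, j] <- -V[, j]
  }
  Vk <- V[, seq_len(n_components), drop = FALSE]

  results <- lapply(seq_along(stacks), function(i) {
    d <- dim(stacks[[i]]$counts)
    M <- stack_pixel_matrix(corrected[[i]])          # pixels x bins
    raw <- M %*% Vk                                  # pixels x comps
    cen <- sweep(M, 2L, mu) %*% Vk
    fgv <- as.vector(fg[[i]])
    raw[!fgv, ] <- NA_real_
    cen[!fgv, ] <- NA_real_
    scores <- aperm(array(raw, c(d[1], d[2], n_components)), c(3, 1, 2))
    scoresc <- aperm(array(cen, c(d[1], d[2], n_components)), c(3, 1, 2))
    structure(list(eigenvectors = t(Vk), eigenvalues = eig$values,
                   scores = scores, scores_centered = scoresc,
                   center = mu, n_components = n_components,
                   total_variance = sum(X^2) / (nrow(X) - 1),
                   foreground = fg[[i]]),
              class = "ncpca_result")
  })
  if (single) results[[1]] else results
}

#' @export
print.ncpca_result <- function(x, ...) {
  ev <- x$eigenvalues[seq_len(x$n_components)]
  cat(sprintf(
    "<ncpca_result> %d components over %d bins; leading variance shares: %s\n",
    x$n_components, ncol(x$eigenvectors),
    paste(sprintf("%.1f%%", 100 * ev / sum(x$eigenvalues)), collapse = " ")))
  invisible(x)
}

#' Compare score distributions between two groups
#'
#' Extracts the per-pixel values of one score component from two NC-PCA
#' results that share the same eigenvector basis, removes outliers with the
#' MAD filter, and reports both filtered distributions with their medians.
#' No hypothesis test is attached; the comparison is distributional.
#'
#' @param resultA,resultB `ncpca_result` objects from one [ncpca()] call on
#'   pooled stacks (identical bases).
#' @param component score component index.
#' @param k MAD multiplier for [mad_filter()].
#' @return List with `values_a`, `values_b` (MAD-filtered score values),
#'   `median_a`, `median_b`, `component`, `k`.
#' @export
compare_scores <- function(resultA, resultB, component = 2L, k = 3) {
  stopifnot(inherits(resultA, "ncpca_result"),
            inherits(resultB, "ncpca_result"))
  if (!isTRUE(all.equal(resultA$eigenvectors, resultB$eigenvectors,
                        tolerance = 1e-12)))
    stop("results do not share the same eigenvector basis")
  if (component < 1 || component > resultA$n_components)
    stop("component out of range (1..", resultA$n_components, ")")
  va <- resultA$scores[component, , ]
  vb <- resultB$scores[component, , ]
  va <- mad_filter(va[is.finite(va)], k = k)
  vb <- mad_filter(vb[is.finite(vb)], k = k)
  list(values_a = va, values_b = vb,
       median_a = stats::median(va), median_b = stats::median(vb),
       component = component, k = k)
}
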