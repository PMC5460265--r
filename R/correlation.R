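#' Zero-lag normalized cross-correlation of two images
#'
#' Both images are smoothed with an isotropic Gaussian of SD
#' \code{smoothing_sigma} (so that cell and EPS densities, rather than
#' pixel-exact overlap, are compared), cropped to the ROI, standardized, and
#' their Pearson correlation returned. The images are compared at fixed
#' alignment; no lag search is performed.
#'
#' @param a,b Numeric matrices on the same grid (e.g. EPS values and a cell
#'   occupancy mask).
#' @param pixel_size µm per pixel.
#' @param roi ROI rectangle, 0-based half-open; default whole image.
#' @param smoothing_sigma Gaussian SD in µm (default 2).
#' @return Pearson correlation in [-1, 1].
#' @export
normalized_cross_correlation <- function(a, b, pixel_size,
                                         roi = c(0L, nrow(a), 0L, ncol(a)),
                                         smoothing_sigma = 2) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)), pixel_size > 0)
  as <- cpp_gauss_smooth(a + 0, smoothing_sigma / pixel_size)
  bs <- cpp_gauss_smooth(b + 0, smoothing_sigma / pixel_size)
  rows <- (roi[1] + 1):roi[2]; cols <- (roi[3] + 1):roi[4]
  va <- as[rows, cols]; vb <- bs[rows, cols]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("correlation undefined: an image is constant within the ROI")
  stats::cor(as.vector(va), as.vector(vb))
}

#' Spatial block-permutation null for the cross-correlation
#'
#' Estimates the chance level of \code{\link{normalized_cross_correlation}}
#' by tiling the ROI of \code{b} into square blocks of side
#' \code{block_size} and shuffling the block positions uniformly at random
#' (partial edge blocks stay fixed), recomputing the smoothed correlation
#' for each permutation. The block is the permutation unit — pixel-level
#' shuffling would destroy within-cell structure and make the null
#' trivially tight — and defaults to the ~10 µm EPS correlation scale.
#' Set \code{block_size} to one pixel width for pixel-mode comparison.
#'
#' @param a,b Numeric matrices on the same grid.
#' @param pixel_size µm per pixel.
#' @param roi ROI rectangle; default whole image.
#' @param n Number of permutations (>= 100; default 1000).
#' @param block_size Block side in µm (default 10).
#' @param smoothing_sigma Gaussian SD in µm (default 2).
#' @param seed Optional integer seed.
#' @return A \code{correlation_result}: observed \code{r}, \code{null_mean},
#'   \code{null_sd}, \code{z_score}, \code{n_permutations},
#'   \code{smoothing_sigma}, and the vector of null correlations.
#' @export
bootstrap_null <- function(a, b, pixel_size, roi = c(0L, nrow(a), 0L, ncol(a)),
                           n = 1000, block_size = 10, smoothing_sigma = 2,
                           seed = NULL) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  if (n < 100) stop("need at least 100 permutations")
  set_seed_if(seed)
  rows <- (roi[1] + 1):roi[2]; cols <- (roi[3] + 1):roi[4]
  block_px <- max(1L, round(block_size / pixel_size))
  if ((length(rows) %/% block_px) * (length(cols) %/% block_px) < 4)
    stop("ROI holds fewer than 4 blocks; reduce block_size")
  sigma_px <- smoothing_sigma / pixel_size
  a_roi <- a[rows, cols] + 0
  b_roi <- b[rows, cols] + 0
  a_s <- cpp_gauss_smooth(a_roi, sigma_px)
  b_s <- cpp_gauss_smooth(b_roi, sigma_px)
  if (stats::sd(a_s) == 0 || stats::sd(b_s) == 0)
    stop("correlation undefined: an image is constant within the ROI")
  r_obs <- stats::cor(as.vector(a_s), as.vector(b_s))
  nulls <- cpp_block_null(a_s, b_roi, block_px, sigma_px, as.integer(n))
  nm <- mean(nulls); ns <- stats::sd(nulls)
  structure(list(r = r_obs, null_mean = nm, null_sd = ns,
                 z_score = (r_obs - nm) / ns, n_permutations = n,
                 smoothing_sigma = smoothing_sigma, block_size = block_size,
                 null_r = nulls),
            class = "correlation_result")
}

#' Fold change of the EPS-cell correlation across the bubble passage
#'
#' Computes r(EPS before, cells after) / r(EPS before, cells before). When
#' lists of replicate images are supplied, also reports the standard error
#' of the mean ratio across replicates. If the pre-bubble correlation is
#' not positive the ratio is undefined and only the r values are returned.
#'
#' @param eps_before EPS matrix, or list of matrices (replicates).
#' @param cells_before,cells_after Cell matrices matching
#'   \code{eps_before}'s structure.
#' @param pixel_size µm per pixel.
#' @param roi ROI rectangle applied to every replicate; default whole image.
#' @param smoothing_sigma Gaussian SD in µm (default 2).
#' @return List with per-replicate \code{r_before} and \code{r_after},
#'   \code{ratio} (mean over replicates; NA when undefined), \code{sem}
#'   (NA with a single replicate) and \code{defined}.
#' @export
correlation_ratio <- function(eps_before, cells_before, cells_after,
                              pixel_size, roi = NULL, smoothing_sigma = 2) {
  if (!is.list(eps_before)) {
    eps_before <- list(eps_before)
    cells_before <- list(cells_before)
    cells_after <- list(cells_after)
  }
  k <- length(eps_before)
  stopifnot(length(cells_before) == k, length(cells_after) == k)
  r_before <- r_after <- numeric(k)
  for (i in seq_len(k)) {
    ri <- if (is.null(roi)) c(0L, nrow(eps_before[[i]]), 0L, ncol(eps_before[[i]]))
          else roi
    r_before[i] <- normalized_cross_correlation(eps_before[[i]], cells_before[[i]],
                                                pixel_size, ri, smoothing_sigma)
    r_after[i] <- normalized_cross_correlation(eps_before[[i]], cells_after[[i]],
                                               pixel_size, ri, smoothing_sigma)
  }
  defined <- all(r_before > 0)
  ratios <- if (defined) r_after / r_before else rep(NA_real_, k)
  list(r_before = r_before, r_after = r_after,
       ratio = if (defined) mean(ratios) else NA_real_,
       sem = if (defined && k > 1) stats::sd(ratios) / sqrt(k) else NA_real_,
       defined = defined)
}
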