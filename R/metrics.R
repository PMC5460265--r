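#' Binary patch image
#'
#' A binary mask with its pixel size and an analysis region of interest
#' (ROI), the hydrophobic patch, in 0-based half-open pixel coordinates
#' \code{c(r0, r1, c0, c1)}.
#'
#' @param mask Logical matrix (TRUE = foreground/cells).
#' @param pixel_size µm per pixel.
#' @param roi ROI rectangle; defaults to the whole image.
#' @return A \code{binary_patch} object.
#' @export
binary_patch <- function(mask, pixel_size,
                         roi = c(0L, nrow(mask), 0L, ncol(mask))) {
  stopifnot(is.matrix(mask), is.logical(mask), pixel_size > 0,
            length(roi) == 4)
  if (roi[1] < 0 || roi[3] < 0 || roi[2] > nrow(mask) || roi[4] > ncol(mask) ||
      roi[2] <= roi[1] || roi[4] <= roi[3])
    stop("roi must be a non-empty rectangle inside the mask")
  structure(list(mask = mask, pixel_size = pixel_size, roi = as.integer(roi)),
            class = "binary_patch")
}

roi_crop <- function(b) b$mask[(b$roi[1] + 1):b$roi[2], (b$roi[3] + 1):b$roi[4]]

#' Otsu threshold of a 16-bit image
#'
#' Standard between-class-variance maximization on a 256-bin histogram of
#' the ROI pixels. Errors on a degenerate (single-valued) histogram.
#'
#' @param img Integer/numeric matrix (e.g. from \code{\link{read_tiff}} or
#'   \code{\link{render_image}}).
#' @param pixel_size µm per pixel; defaults to the \code{pixel_size}
#'   attribute of \code{img}.
#' @param roi ROI rectangle (0-based half-open); default whole image.
#' @param nbins Histogram bins (default 256).
#' @return A \code{binary_patch} (foreground = above threshold) with the
#'   threshold stored in attribute \code{threshold}.
#' @export
binarize <- function(img, pixel_size = attr(img, "pixel_size"),
                     roi = c(0L, nrow(img), 0L, ncol(img)), nbins = 256) {
  stopifnot(is.matrix(img))
  if (is.null(pixel_size)) stop("pixel_size required")
  if (!all(is.finite(img))) stop("image contains non-finite values")
  v <- img[(roi[1] + 1):roi[2], (roi[3] + 1):roi[4]]
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("degenerate histogram: image is constant within the ROI")
  h <- tabulate(pmin(nbins, 1L + floor((v - lo) / (hi - lo) * nbins)), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  thr <- lo + k / nbins * (hi - lo)
  b <- binary_patch(img > thr, pixel_size, roi)
  attr(b, "threshold") <- thr
  b
}

#' Surface coverage
#'
#' Fraction of the ROI (the hydrophobic patch) covered by foreground,
#' in percent.
#'
#' @param b A \code{\link{binary_patch}}.
#' @return Coverage in percent.
#' @export
surface_coverage <- function(b) {
  stopifnot(inherits(b, "binary_patch"))
  100 * mean(roi_crop(b))
}

#' Segment holes and compute porosity
#'
#' Holes are connected components (4-connectivity) of the background within
#' the ROI, after a morphological closing of the foreground with a disk of
#' radius \code{close_r} that seals the one-cell-wide digitization gaps in
#' levees. Components touching the ROI border are kept; components smaller
#' than \code{min_area} are discarded. Porosity is the total hole area as a
#' percentage of the ROI area — computed from segmented holes, not as
#' 100 - coverage.
#'
#' @param b A \code{\link{binary_patch}} (foreground = cells).
#' @param close_r Closing disk radius, µm (default 1).
#' @param min_area Minimum hole area, µm^2 (default 3).
#' @return List with \code{holes} (data.frame: id, area_um2,
#'   equivalent_radius_um, centroid_x_um, centroid_y_um), \code{porosity}
#'   (percent) and \code{labels} (hole label matrix over the ROI).
#' @export
segment_holes <- function(b, close_r = 1, min_area = 3) {
  stopifnot(inherits(b, "binary_patch"))
  px <- b$pixel_size
  fg <- roi_crop(b)
  closed <- if (close_r > 0)
    cpp_binary_erode(cpp_binary_dilate(fg, close_r / px), close_r / px)
  else fg
  lab <- cpp_label_components(!closed, 4L)
  nlab <- max(lab)
  if (nlab == 0) {
    return(list(holes = data.frame(id = integer(), area_um2 = numeric(),
                                   equivalent_radius_um = numeric(),
                                   centroid_x_um = numeric(),
                                   centroid_y_um = numeric()),
                porosity = 0, labels = lab))
  }
  idx <- which(lab > 0)
  lv <- lab[idx]
  npix <- tabulate(lv, nlab)
  area <- npix * px^2
  keep <- which(area >= min_area)
  nr <- nrow(lab)
  rows_i <- (idx - 1L) %% nr + 1L
  cols_i <- (idx - 1L) %/% nr + 1L
  sums <- rowsum(cbind(as.numeric(rows_i), as.numeric(cols_i)), lv)
  lab_ids <- as.integer(rownames(sums))
  pos <- match(keep, lab_ids)
  cx <- (sums[pos, 2] / npix[keep] - 0.5) * px
  cy <- (sums[pos, 1] / npix[keep] - 0.5) * px
  remap <- integer(nlab)
  remap[keep] <- seq_along(keep)
  relab <- matrix(0L, nrow(lab), ncol(lab))
  relab[idx] <- remap[lv]
  holes <- data.frame(id = seq_along(keep), area_um2 = area[keep],
                      equivalent_radius_um = sqrt(area[keep] / pi),
                      centroid_x_um = cx, centroid_y_um = cy)
  list(holes = holes, porosity = 100 * sum(area[keep]) / (length(lab) * px^2),
       labels = relab)
}

#' Box-counting fractal dimension
#'
#' Counts N(s), the number of s-by-s pixel boxes (grid anchored at the ROI
#' origin) containing at least one foreground pixel, for dyadic s from 2 up
#' to ROI_side/4 (the largest dyadic scale, ROI_side/2, is excluded to avoid
#' saturation). D is the least-squares slope of ln N against ln(1/s).
#'
#' @param b A \code{\link{binary_patch}} with ROI side >= 64 pixels and at
#'   least one foreground pixel.
#' @return A \code{fractal_fit}: list with \code{D}, \code{box_sizes},
#'   \code{counts}, \code{fit_r2}.
#' @export
fractal_dimension <- function(b) {
  stopifnot(inherits(b, "binary_patch"))
  fg <- roi_crop(b)
  if (!any(fg)) stop("no foreground pixels in the ROI")
  side <- min(dim(fg))
  if (side < 64) stop("ROI side must be >= 64 pixels for a stable fit")
  smax <- side / 4
  sizes <- 2^(1:floor(log2(smax)))
  if (length(sizes) < 4) stop("fewer than 4 usable box scales")
  counts <- cpp_box_counts(fg, as.integer(sizes))
  x <- log(1 / sizes); y <- log(counts)
  fit <- stats::lm(y ~ x)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(fit$residuals^2) / tss else 1
  structure(list(D = unname(stats::coef(fit)[2]), box_sizes = sizes,
                 counts = as.integer(counts), fit_r2 = r2),
            class = "fractal_fit")
}

#' Mean distance between individual cells
#'
#' Mean nearest-neighbour distance between cell centroids (default), or the
#' mean over all pairs.
#'
#' @param cells A \code{cell_map} or an n x 2 matrix of µm coordinates.
#' @param method "nearest" (default) or "allpairs".
#' @return Distance in µm.
#' @export
mean_intercell_distance <- function(cells, method = c("nearest", "allpairs")) {
  method <- match.arg(method)
  xy <- if (inherits(cells, "cell_map")) cells$centroids else as.matrix(cells)
  if (nrow(xy) < 2) stop("need at least 2 cells")
  if (method == "nearest")
    mean(FNN::get.knn(xy, k = 1)$nn.dist)
  else
    mean(stats::dist(xy))
}

#' Characterize hole-growth curves
#'
#' Averages the normalized hole-area curves (with SEM across holes) and fits
#' a continuous 3-segment piecewise-linear model to the mean curve by least
#' squares over a breakpoint grid. Reports segment slopes, breakpoints, the
#' growth duration (first crossing of 1 % to first crossing of 99 % of the
#' final mean), and whether the profile is slow-fast-slow (middle slope
#' strictly greatest). If three segments do not beat a single line by at
#' least 1 % of its residual sum of squares the fit is flagged degenerate
#' and no phase flag is claimed.
#'
#' @param tracks A \code{dewetting_result} or a long data.frame with columns
#'   hole_id, t_s, area_um2.
#' @param n_breaks Breakpoint grid resolution (default 25 per breakpoint).
#' @return List with \code{mean_curve} (t_s, mean, sem), \code{slopes},
#'   \code{breakpoints}, \code{duration_s}, \code{slow_fast_slow},
#'   \code{degenerate}.
#' @export
characterize_growth <- function(tracks, n_breaks = 25) {
  if (inherits(tracks, "dewetting_result")) tracks <- tracks$tracks
  stopifnot(all(c("hole_id", "t_s", "area_um2") %in% names(tracks)))
  ids <- unique(tracks$hole_id)
  if (length(ids) < 1) stop("no hole tracks")
  tgrid <- sort(unique(tracks$t_s))
  if (length(tgrid) < 10) stop("need at least 10 time samples per track")
  curves <- vapply(ids, function(id) {
    tr <- tracks[tracks$hole_id == id, ]
    a <- stats::approx(tr$t_s, tr$area_um2, xout = tgrid, rule = 2)$y
    if (max(a) <= 0) rep(NA_real_, length(tgrid)) else a / max(a)
  }, numeric(length(tgrid)))
  curves <- curves[, colSums(is.na(curves)) == 0, drop = FALSE]
  if (ncol(curves) == 0) stop("no hole ever opened")
  m <- rowMeans(curves)
  sem <- apply(curves, 1, stats::sd) / sqrt(ncol(curves))
  # growth duration from the mean curve
  i1 <- which(m >= 0.01 * max(m))[1]
  i99 <- which(m >= 0.99 * max(m))[1]
  duration <- tgrid[i99] - tgrid[i1]
  # 3-segment continuous piecewise-linear fit over a breakpoint grid
  y <- m; x <- tgrid
  rss1 <- sum(stats::lm(y ~ x)$residuals^2)
  cand <- stats::quantile(x, probs = seq(0.05, 0.95, length.out = n_breaks),
                          names = FALSE)
  best <- list(rss = Inf)
  for (b1 in cand) for (b2 in cand) {
    if (b2 <= b1) next
    if (sum(x <= b1) < 3 || sum(x > b1 & x <= b2) < 3 || sum(x > b2) < 3) next
    X <- cbind(1, x, pmax(x - b1, 0), pmax(x - b2, 0))
    f <- stats::lm.fit(X, y)
    rss <- sum(f$residuals^2)
    if (rss < best$rss) best <- list(rss = rss, beta = f$coefficients,
                                     b1 = b1, b2 = b2)
  }
  if (!is.finite(best$rss)) stop("could not fit a 3-segment model")
  slopes <- c(best$beta[2], best$beta[2] + best$beta[3],
              best$beta[2] + best$beta[3] + best$beta[4])
  names(slopes) <- c("initial", "middle", "final")
  tss <- sum((y - mean(y))^2)
  degenerate <- rss1 <= 1e-10 * tss || (rss1 - best$rss) < 0.01 * rss1
  tol <- 0.1 * max(abs(slopes))
  flag <- !degenerate && slopes[2] > slopes[1] + tol && slopes[2] > slopes[3] + tol
  list(mean_curve = data.frame(t_s = tgrid, mean = m, sem = sem),
       slopes = slopes, breakpoints = c(best$b1, best$b2),
       duration_s = duration, slow_fast_slow = unname(flag),
       degenerate = degenerate, n_holes = ncol(curves))
}

#' Full metrics report for a binary patch image
#'
#' @param b A \code{\link{binary_patch}}.
#' @param close_r,min_area Passed to \code{\link{segment_holes}}.
#' @return A one-row data.frame: coverage, porosity, n_holes, mean and
#'   median hole equivalent radius, fractal dimension D and its fit R^2.
#' @export
metrics_report <- function(b, close_r = 1, min_area = 3) {
  seg <- segment_holes(b, close_r, min_area)
  fd <- tryCatch(fractal_dimension(b), error = function(e) NULL)
  data.frame(
    coverage_pct = surface_coverage(b),
    porosity_pct = seg$porosity,
    n_holes = nrow(seg$holes),
    mean_hole_radius_um = if (nrow(seg$holes)) mean(seg$holes$equivalent_radius_um) else NA,
    median_hole_radius_um = if (nrow(seg$holes)) stats::median(seg$holes$equivalent_radius_um) else NA,
    fractal_D = if (is.null(fd)) NA else fd$D,
    fractal_fit_r2 = if (is.null(fd)) NA else fd$fit_r2
  )
}
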