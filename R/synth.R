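#' Geometry of a hydrophobic patch image
#'
#' The imaged field is one square patch plus a margin of off-patch substrate
#' on every side, discretized at \code{pixel_size} micrometres per pixel.
#' Patch sides of 100, 200, 300 and 400 µm mirror the printed patch sizes;
#' other positive sides are allowed.
#'
#' @param side Patch side in µm (default 200).
#' @param margin Margin width in µm on each side (default 10).
#' @param pixel_size µm per pixel (default 0.25, resolving 1 µm cells).
#' @return A \code{patch_geometry} object with the grid dimensions and the
#'   patch rectangle in 0-based, half-open pixel coordinates
#'   \code{c(r0, r1, c0, c1)} (rows are y, increasing downward).
#' @export
patch_geometry <- function(side = 200, margin = 10, pixel_size = 0.25) {
  stopifnot(side > 0, margin >= 0, pixel_size > 0)
  if (!side %in% c(100, 200, 300, 400))
    message("non-standard patch side ", side, " µm (printed patches are 100-400 µm)")
  m_px <- round(margin / pixel_size)
  s_px <- round(side / pixel_size)
  n <- s_px + 2L * m_px
  structure(list(side = side, margin = margin, pixel_size = pixel_size,
                 n_px = n, patch_px = c(m_px, m_px + s_px, m_px, m_px + s_px)),
            class = "patch_geometry")
}

#' Synthetic-data generator configuration
#'
#' Captures the statistical structure of the fluorescence data being
#' emulated: an EPS field that is spatially heterogeneous at a ~10 µm scale
#' and a near-uniform cell monolayer whose coverage depends on biofilm age
#' (31.6 %, 44.6 % and 49.5 % at 4, 8 and 12 h).
#'
#' @param age_h Biofilm age in hours: 4, 8 or 12. Sets the default coverage.
#' @param target_coverage Occupied fraction of the patch in (0, 0.6]; 0 is
#'   allowed as the empty-map limit. Defaults to the age-specific coverage.
#' @param eps_corr_length Correlation length of the EPS field, µm (default 10).
#' @param eps_lognormal_sigma Log-scale SD of EPS amplitudes (default 0.8);
#'   0 gives a spatially constant field.
#' @param eps_cell_coupling Probability weight in [0, 1] tying cell placement
#'   to EPS (default 0.2: near-uniform cover, weakly EPS-correlated).
#' @param cell_radius Cell disk radius, µm (default 0.5).
#' @param overlap_factor Minimum centroid separation as a fraction of one
#'   cell diameter (default 0.9; slight overlap allowed).
#' @param margin_density Relative placement density in the off-patch margin
#'   (default 0.3; colonization off the patch is slower).
#' @param noise Two-element vector \code{c(gaussian_sd, background_level)} in
#'   16-bit counts used by \code{\link{render_image}}.
#' @param max_attempts Bound on rejection-sampling attempts (default 2e6).
#' @param seed Optional integer seed applied by the generators.
#' @return A validated \code{synth_config} list.
#' @export
synth_config <- function(age_h = 8, target_coverage = NULL,
                         eps_corr_length = 10, eps_lognormal_sigma = 0.8,
                         eps_cell_coupling = 0.2, cell_radius = 0.5,
                         overlap_factor = 0.9, margin_density = 0.3,
                         noise = c(gaussian_sd = 500, background_level = 2000),
                         max_attempts = 2e6, seed = NULL) {
  if (!age_h %in% c(4, 8, 12)) stop("age_h must be 4, 8 or 12")
  if (is.null(target_coverage))
    target_coverage <- c(`4` = 0.316, `8` = 0.446, `12` = 0.495)[[as.character(age_h)]]
  if (target_coverage < 0 || target_coverage > 0.6)
    stop("target_coverage must lie in [0, 0.6]")
  if (eps_cell_coupling < 0 || eps_cell_coupling > 1)
    stop("eps_cell_coupling must lie in [0, 1]")
  stopifnot(eps_corr_length > 0, eps_lognormal_sigma >= 0, cell_radius > 0,
            overlap_factor > 0, margin_density >= 0, length(noise) == 2)
  structure(list(age_h = age_h, target_coverage = target_coverage,
                 eps_corr_length = eps_corr_length,
                 eps_lognormal_sigma = eps_lognormal_sigma,
                 eps_cell_coupling = eps_cell_coupling,
                 cell_radius = cell_radius, overlap_factor = overlap_factor,
                 margin_density = margin_density, noise = noise,
                 max_attempts = max_attempts, seed = seed),
            class = "synth_config")
}

set_seed_if <- function(seed) if (!is.null(seed)) set.seed(as.integer(seed))

#' Generate a heterogeneous EPS field
#'
#' Gaussian random field with isotropic Gaussian autocorrelation (1/e
#' crossing at \code{eps_corr_length}), exponentiated to lognormal
#' amplitudes. The construction smooths white noise with a Gaussian kernel
#' of SD \code{eps_corr_length/2}, which yields exactly the target Gaussian
#' autocorrelation, then applies \code{exp(sigma * z)}.
#'
#' @param geom A \code{\link{patch_geometry}}.
#' @param cfg A \code{\link{synth_config}}.
#' @param seed Optional seed (defaults to \code{cfg$seed}).
#' @return An \code{eps_field}: list with \code{values} (non-negative
#'   matrix), \code{pixel_size}, and the patch rectangle.
#' @export
generate_eps_field <- function(geom, cfg, seed = cfg$seed) {
  stopifnot(inherits(geom, "patch_geometry"), inherits(cfg, "synth_config"))
  px <- geom$pixel_size
  if (cfg$eps_corr_length <= 2 * px)
    stop("eps_corr_length must exceed 2 pixels (", 2 * px, " µm) to be resolved")
  set_seed_if(seed)
  n <- geom$n_px
  if (cfg$eps_lognormal_sigma == 0) {
    vals <- matrix(1, n, n)
  } else {
    z <- matrix(stats::rnorm(n * n), n, n)
    s_px <- cfg$eps_corr_length / 2 / px
    f <- cpp_gauss_smooth(z, s_px)
    f <- (f - mean(f)) / stats::sd(f)
    vals <- exp(cfg$eps_lognormal_sigma * f)
  }
  structure(list(values = vals, pixel_size = px, patch_px = geom$patch_px,
                 geom = geom), class = "eps_field")
}

#' Normalize an EPS field to [0, 1]
#'
#' \code{method = "max"} divides by the maximum (used for placement
#' probabilities); \code{method = "quantile"} divides by the given upper
#' quantile and clamps at 1, which is robust to the heavy lognormal tail and
#' is used for adhesion and rupture resistance.
#'
#' @param eps An \code{eps_field} or numeric matrix.
#' @param method "max" or "quantile".
#' @param q Quantile used when \code{method = "quantile"}.
#' @return A matrix with values in [0, 1].
#' @export
normalize_eps <- function(eps, method = c("max", "quantile"), q = 0.99) {
  v <- if (inherits(eps, "eps_field")) eps$values else eps
  method <- match.arg(method)
  top <- if (method == "max") max(v) else stats::quantile(v, q, names = FALSE)
  if (top <= 0) return(matrix(0, nrow(v), ncol(v)))
  pmin(v / top, 1)
}

#' Generate a cell monolayer as a hard-disk point pattern
#'
#' Cells (disks of radius \code{cell_radius}) are placed by sequential
#' rejection sampling: a candidate position is accepted with probability
#' \code{(1 - coupling) + coupling * EPS} (EPS normalized by its 0.99
#' quantile and clamped, as in the adhesion law — normalizing by the raw
#' maximum would let the heavy lognormal tail crush the coupling),
#' damped by \code{margin_density} outside the patch, and subject to a
#' minimum centroid separation. Placement stops when the occupied fraction
#' of the patch reaches \code{target_coverage} (overshoot is at most one
#' cell's area, well within 0.5 %).
#'
#' @param geom A \code{\link{patch_geometry}}.
#' @param eps An \code{eps_field} on the same grid.
#' @param cfg A \code{\link{synth_config}}.
#' @param seed Optional seed (defaults to \code{cfg$seed}).
#' @return A \code{cell_map}: centroids (n x 2 matrix, µm), occupancy mask,
#'   cell radius, pixel size, patch rectangle and achieved coverage.
#' @export
generate_cell_map <- function(geom, eps, cfg, seed = cfg$seed) {
  stopifnot(inherits(geom, "patch_geometry"), inherits(eps, "eps_field"),
            inherits(cfg, "synth_config"))
  if (!all(dim(eps$values) == geom$n_px)) stop("EPS grid does not match geometry")
  set_seed_if(seed)
  pp <- geom$patch_px
  if (cfg$target_coverage == 0) {
    cent <- matrix(numeric(0), 0, 2)
    occ <- matrix(FALSE, geom$n_px, geom$n_px)
    return(structure(list(centroids = cent, occupancy = occ,
                          cell_radius = cfg$cell_radius,
                          pixel_size = geom$pixel_size, patch_px = pp,
                          coverage = 0), class = "cell_map"))
  }
  res <- cpp_place_cells(normalize_eps(eps, "quantile"), geom$pixel_size,
                         pp[1], pp[2], pp[3], pp[4],
                         cfg$target_coverage, cfg$eps_cell_coupling,
                         cfg$cell_radius, cfg$overlap_factor,
                         cfg$margin_density, cfg$max_attempts)
  occ <- cpp_stamp_disks(geom$n_px, geom$n_px, res$centroids,
                         cfg$cell_radius, geom$pixel_size)
  structure(list(centroids = res$centroids, occupancy = occ,
                 cell_radius = cfg$cell_radius, pixel_size = geom$pixel_size,
                 patch_px = pp, coverage = res$coverage),
            class = "cell_map")
}

#' Rebuild the occupancy mask of a cell map from its centroids
#' @param cells A \code{cell_map}.
#' @return The same \code{cell_map} with a freshly stamped occupancy mask.
#' @export
refresh_occupancy <- function(cells) {
  stopifnot(inherits(cells, "cell_map"))
  n <- nrow(cells$occupancy)
  cells$occupancy <- cpp_stamp_disks(n, ncol(cells$occupancy), cells$centroids,
                                     cells$cell_radius, cells$pixel_size)
  cells
}

#' Render a field or cell map as a 16-bit fluorescence-like image
#'
#' Scales the input to the 16-bit range, adds a constant background level
#' and Gaussian read noise, and clamps to [0, 65535]. More than 1 % of
#' pixels clipped at either end triggers a saturation warning.
#'
#' @param x An \code{eps_field}, \code{cell_map}, or numeric matrix.
#' @param cfg A \code{\link{synth_config}} supplying the noise parameters.
#' @param seed Optional seed for the noise (defaults to \code{cfg$seed}).
#' @param scale Peak signal above background, counts (default 40000).
#' @return Integer matrix with a \code{pixel_size} attribute, ready for
#'   \code{\link{write_tiff}}.
#' @export
render_image <- function(x, cfg, seed = cfg$seed, scale = 40000) {
  stopifnot(inherits(cfg, "synth_config"))
  v <- if (inherits(x, "eps_field")) x$values
       else if (inherits(x, "cell_map")) x$occupancy + 0
       else x
  if (!all(is.finite(v))) stop("input contains non-finite values")
  px <- if (is.list(x) && !is.null(x$pixel_size)) x$pixel_size
        else attr(x, "pixel_size")
  set_seed_if(seed)
  top <- max(v)
  norm <- if (top > 0) v / top else v
  img <- cfg$noise[[2]] + norm * scale
  if (cfg$noise[[1]] > 0)
    img <- img + stats::rnorm(length(img), sd = cfg$noise[[1]])
  clipped <- mean(img < 0 | img > 65535)
  if (clipped > 0.01)
    warning(sprintf("%.1f%% of pixels clipped to the 16-bit range", 100 * clipped))
  img[img < 0] <- 0; img[img > 65535] <- 65535
  out <- matrix(as.integer(round(img)), nrow(v), ncol(v))
  attr(out, "pixel_size") <- px
  out
}
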