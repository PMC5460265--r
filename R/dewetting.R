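#' Configuration of the dewetting simulator
#'
#' The simulator reproduces the mechanism by which an evaporating residual
#' liquid film ruptures at discrete sites and the receding contact lines
#' scrape cells outward into levees. Three regimes map onto biofilm age:
#' \describe{
#'   \item{removal_4h}{weak adhesion: contacted cells detach with
#'     probability \code{p_detach} and leave the domain.}
#'   \item{rearrangement_8h}{intermediate adhesion: weakly adhering cells
#'     are pushed outward along the front normal and accumulate as load on
#'     the contact line; strongly adhering cells pin it locally.}
#'   \item{no_effect_12h}{strong adhesion everywhere: the front passes over
#'     the cells and the map is returned unchanged.}
#' }
#' Per-cell adhesion is \code{age_factor * EPS + cell_bonus} (EPS normalized
#' by its 0.99 quantile) compared against \code{capillary_force}.
#'
#' The default kinematics give the observed slow-linear-slow area growth: a
#' linear speed ramp over \code{ramp_time} (slow opening), a 1/r geometric
#' factor so hole area grows linearly in time (middle phase), and
#' load-dependent slowing near pinning (slow finish). Defaults were
#' calibrated once so the 8 h regime on a 200 µm patch lands in the observed
#' end state (porosity ~68 %, hole equivalent radius 6.5-8 µm, ~5 s per
#' hole); see the package vignette.
#'
#' @param regime One of "rearrangement_8h", "removal_4h", "no_effect_12h".
#' @param age_factor,cell_bonus Adhesion law coefficients; regime-specific
#'   defaults (0.6/0 removal, 1/0 rearrangement, 1/1 no-effect).
#' @param capillary_force Dimensionless scraping threshold (default 0.28).
#' @param p_detach Detachment probability in the removal regime (default 0.7).
#' @param pin_threshold Load units at which a front segment pins (default 30).
#' @param resist_scale EPS pinning resistance scale, load units (default 60:
#'   high-EPS pixels can pin a lightly loaded segment outright).
#' @param nucleation_spacing Minimum distance between rupture sites, µm
#'   (default 12; calibrated against the observed hole scale).
#' @param nucleation_count Optional cap on the number of sites.
#' @param front_speed_max Peak front speed, µm/s (default 7).
#' @param ramp_time Speed ramp duration after nucleation, s (default 1).
#' @param inv_r,r_ref Geometric speed factor min(1, r_ref/r) giving
#'   linear-in-time area growth (default on, r_ref = 2 µm).
#' @param dt Time step, s; must be <= 0.02 (the 50 frames/s imaging cadence).
#' @param total_time Simulated time, s; >= 5 (default 10, the bubble
#'   passage time; the hole-opening itself takes ~5 s).
#' @param t_evap Nucleation window, s: rupture times are drawn uniformly in
#'   [0, t_evap]. Defaults to the evaporation time of a 0.1 µm film at the
#'   default evaporation rate (~2 s), via \code{\link{evaporation_time}}.
#' @param push_spacing Minimum centroid separation enforced when a scraped
#'   cell is re-deposited, µm (default 0.5: scraped cells may pile up,
#'   levees are concentrated/multilayered).
#' @param push_search Outward search range for re-deposition, µm (default 10).
#' @param stall_frac A front segment whose load slowdown factor
#'   (1 - load/pin_threshold) falls to this fraction is considered stalled
#'   and pins (default 0.15).
#' @param stall_speed Absolute front-speed floor in µm/s; after the ramp, a
#'   segment moving slower than this pins (default 0.2).
#' @param seed Optional integer seed.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(regime = c("rearrangement_8h", "removal_4h", "no_effect_12h"),
                       age_factor = NULL, cell_bonus = NULL,
                       capillary_force = 0.28, p_detach = 0.7,
                       pin_threshold = 30, resist_scale = 60,
                       nucleation_spacing = 12, nucleation_count = Inf,
                       front_speed_max = 7, ramp_time = 1,
                       inv_r = TRUE, r_ref = 2,
                       dt = 0.02, total_time = 10, t_evap = NULL,
                       push_spacing = 0.5, push_search = 10, stall_frac = 0.15,
                       stall_speed = 0.2, seed = NULL) {
  regime <- match.arg(regime)
  presets <- list(removal_4h = c(0.6, 0), rearrangement_8h = c(1, 0),
                  no_effect_12h = c(1, 1))
  if (is.null(age_factor)) age_factor <- presets[[regime]][1]
  if (is.null(cell_bonus)) cell_bonus <- presets[[regime]][2]
  if (dt <= 0 || dt > 0.02)
    stop("dt must be in (0, 0.02] s to resolve the 50 frames/s cadence")
  if (total_time < 5) stop("total_time must be >= 5 s (the process takes ~5 s)")
  if (is.null(t_evap)) {
    p <- physical_params()
    t_evap <- evaporation_time(1e-7, p)
  }
  stopifnot(capillary_force > 0, pin_threshold > 0, resist_scale >= 0,
            nucleation_spacing > 0, front_speed_max > 0, ramp_time >= 0,
            r_ref > 0, t_evap >= 0, p_detach >= 0, p_detach <= 1)
  structure(list(regime = regime, age_factor = age_factor,
                 cell_bonus = cell_bonus, capillary_force = capillary_force,
                 p_detach = p_detach, pin_threshold = pin_threshold,
                 resist_scale = resist_scale,
                 nucleation_spacing = nucleation_spacing,
                 nucleation_count = nucleation_count,
                 front_speed_max = front_speed_max, ramp_time = ramp_time,
                 inv_r = inv_r, r_ref = r_ref, dt = dt,
                 total_time = total_time, t_evap = t_evap,
                 push_spacing = push_spacing, push_search = push_search,
                 stall_frac = stall_frac, stall_speed = stall_speed,
                 seed = seed), class = "sim_config")
}

#' Local adhesion strength map
#'
#' \code{age_factor * EPS + cell_bonus * occupancy}, with EPS normalized by
#' its 0.99 quantile: the spatial distribution of EPS is the primary
#' determinant of local adhesion, with an additive bonus on cell-occupied
#' pixels.
#'
#' @param eps An \code{eps_field}.
#' @param cells A \code{cell_map} on the same grid.
#' @param cfg A \code{\link{sim_config}}.
#' @return A non-negative matrix on the EPS grid.
#' @export
adhesion_field <- function(eps, cells, cfg) {
  stopifnot(inherits(eps, "eps_field"), inherits(cells, "cell_map"),
            inherits(cfg, "sim_config"))
  cfg$age_factor * normalize_eps(eps, "quantile") +
    cfg$cell_bonus * (cells$occupancy + 0)
}

cell_pixel_index <- function(cells) {
  n <- nrow(cells$occupancy)
  pr <- pmin(n - 1L, pmax(0L, floor(cells$centroids[, 2] / cells$pixel_size)))
  pc <- pmin(ncol(cells$occupancy) - 1L,
             pmax(0L, floor(cells$centroids[, 1] / cells$pixel_size)))
  cbind(pr + 1L, pc + 1L)
}

#' Select film-rupture nucleation sites
#'
#' Rupture starts in cell-free voids where the film is least stabilized:
#' sites are chosen greedily by ascending rupture resistance (normalized
#' EPS, infinite on cell-occupied pixels; ties broken in row-major order)
#' subject to a minimum inter-site spacing. The whole imaged field is
#' eligible — the residual film evaporates over the off-patch margin too.
#'
#' @param eps An \code{eps_field}.
#' @param cells A \code{cell_map}.
#' @param cfg A \code{\link{sim_config}}.
#' @return Integer matrix of 0-based (row, col) pixel sites.
#' @export
nucleate_ruptures <- function(eps, cells, cfg) {
  stopifnot(inherits(eps, "eps_field"), inherits(cells, "cell_map"),
            inherits(cfg, "sim_config"))
  resistance <- normalize_eps(eps, "quantile")
  resistance[cells$occupancy] <- 1e30
  maxs <- if (is.finite(cfg$nucleation_count)) as.integer(cfg$nucleation_count)
          else .Machine$integer.max
  cpp_nucleate(resistance, 0L, nrow(resistance), 0L, ncol(resistance),
               cfg$nucleation_spacing / eps$pixel_size, maxs)
}

#' Run the dewetting simulation
#'
#' Nucleates holes at times drawn uniformly in [0, \code{t_evap}], advances
#' all contact-line fronts until every segment is pinned or
#' \code{total_time} is reached, and returns the final cell map, the hole
#' label image and per-hole area tracks sampled at \code{dt}.
#'
#' @param eps An \code{eps_field} (never modified: bubble passage has a
#'   negligible effect on the EPS distribution).
#' @param cells A \code{cell_map} on the same grid.
#' @param cfg A \code{\link{sim_config}}.
#' @param seed Optional seed (defaults to \code{cfg$seed}).
#' @return A \code{dewetting_result}: \code{cells_final} (a
#'   \code{cell_map}), \code{hole_labels} (integer matrix, 0 = intact),
#'   \code{tracks} (data.frame hole_id, t_s, area_um2, area_norm),
#'   \code{sites}, \code{t_nuc}, \code{events}, \code{finished}.
#' @export
run_dewetting <- function(eps, cells, cfg, seed = cfg$seed) {
  stopifnot(inherits(eps, "eps_field"), inherits(cells, "cell_map"),
            inherits(cfg, "sim_config"))
  if (!all(dim(eps$values) == dim(cells$occupancy)))
    stop("EPS field and cell map are on different grids")
  set_seed_if(seed)
  sites <- nucleate_ruptures(eps, cells, cfg)
  t_nuc <- stats::runif(nrow(sites), 0, cfg$t_evap)
  eps_q <- normalize_eps(eps, "quantile")
  idx <- cell_pixel_index(cells)
  adhesion <- if (nrow(idx) > 0)
    cfg$age_factor * eps_q[idx] + cfg$cell_bonus * (cells$occupancy[idx] + 0)
  else numeric(0)
  regime_code <- match(cfg$regime,
                       c("removal_4h", "rearrangement_8h", "no_effect_12h")) - 1L
  res <- cpp_run_dewetting(eps_q, cells$centroids, adhesion, sites, t_nuc,
                           eps$pixel_size, cells$cell_radius, regime_code,
                           cfg$capillary_force, cfg$p_detach,
                           cfg$pin_threshold, cfg$resist_scale,
                           cfg$front_speed_max, cfg$ramp_time,
                           cfg$inv_r, cfg$r_ref, cfg$dt, cfg$total_time,
                           cfg$push_spacing, cfg$push_search,
                           cfg$stall_frac, cfg$stall_speed, 1L)
  if (!res$finished)
    warning(res$n_active_fronts, " front segments still unpinned at total_time = ",
            cfg$total_time, " s")
  keep <- !res$removed
  cells_final <- cells
  cells_final$centroids <- res$centroids[keep, , drop = FALSE]
  cells_final <- refresh_occupancy(cells_final)
  cells_final$coverage <- NA_real_
  # long-format per-hole area tracks; holes that never opened are dropped
  amax <- apply(res$areas_um2, 2, max)
  open <- which(amax > 0)
  tracks <- do.call(rbind, lapply(open, function(h) {
    data.frame(hole_id = h, t_s = res$times,
               area_um2 = res$areas_um2[, h],
               area_norm = res$areas_um2[, h] / amax[h])
  }))
  structure(list(cells_final = cells_final, hole_labels = res$hole_labels,
                 tracks = tracks, sites = sites, t_nuc = t_nuc,
                 events = res$events, finished = res$finished,
                 n_active_fronts = res$n_active_fronts,
                 cells_initial = cells, removed = res$removed,
                 config = cfg, pixel_size = eps$pixel_size),
            class = "dewetting_result")
}

#' Contrast of initial EPS between hole interiors and levees
#'
#' Holes should form where there was the least EPS: compares the initial
#' EPS values of hole-interior pixels against the levee band (pixels within
#' \code{band_um} outside a hole) with a one-sided Wilcoxon rank-sum test.
#'
#' @param result A \code{dewetting_result}.
#' @param eps The initial \code{eps_field} used in the run.
#' @param band_um Levee band width, µm (default 2).
#' @return List with mean EPS inside holes and in the levee band, and the
#'   one-sided p-value for interior < levee.
#' @export
hole_eps_contrast <- function(result, eps, band_um = 2) {
  stopifnot(inherits(result, "dewetting_result"), inherits(eps, "eps_field"))
  hole <- result$hole_labels > 0
  band <- cpp_binary_dilate(hole, band_um / eps$pixel_size) & !hole
  if (!any(hole) || !any(band)) stop("no holes or empty levee band")
  inside <- eps$values[hole]
  levee <- eps$values[band]
  p <- stats::wilcox.test(inside, levee, alternative = "less")$p.value
  list(mean_hole = mean(inside), mean_levee = mean(levee), p_value = p)
}

#' Cell-density enrichment in the levee band
#'
#' Ratio of the final occupancy fraction within \code{band_um} of hole
#' boundaries to the initial occupancy fraction of the patch; values > 1
#' indicate that scraped cells accumulated into levees.
#'
#' @param result A \code{dewetting_result}.
#' @param band_um Band width around hole boundaries, µm (default 2).
#' @return The enrichment ratio (final band density / initial patch density).
#' @export
levee_enrichment <- function(result, band_um = 2) {
  stopifnot(inherits(result, "dewetting_result"))
  hole <- result$hole_labels > 0
  band <- cpp_binary_dilate(hole, band_um / result$pixel_size) & !hole
  pp <- result$cells_initial$patch_px
  rows <- (pp[1] + 1):pp[2]; cols <- (pp[3] + 1):pp[4]
  init_density <- mean(result$cells_initial$occupancy[rows, cols])
  if (!any(band) || init_density == 0) stop("empty levee band or empty patch")
  mean(result$cells_final$occupancy[band]) / init_density
}
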