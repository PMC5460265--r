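#' Default end-to-end pipeline configuration
#'
#' One global seed is split deterministically into per-stage substreams
#' (generation, simulation, correlation), so any stage can be reproduced in
#' isolation. Every numeric default documents its source in the stage
#' constructors (\code{\link{physical_params}}, \code{\link{synth_config}},
#' \code{\link{sim_config}}).
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory; created by \code{\link{run_pipeline}}.
#' @param side Patch side, µm.
#' @param age_h Biofilm age (4, 8, 12); also selects the simulator regime.
#' @param pixel_size µm per pixel.
#' @param n_perm Permutations for the correlation null (0 skips the null).
#' @return A \code{pipeline_config} list that round-trips losslessly through
#'   JSON (\code{\link{write_config}} / \code{\link{read_config}}).
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("dewpatch_run_"),
                            side = 200, age_h = 8, pixel_size = 0.25,
                            n_perm = 0) {
  regime <- c(`4` = "removal_4h", `8` = "rearrangement_8h",
              `12` = "no_effect_12h")[[as.character(age_h)]]
  structure(list(
    seed = as.integer(seed), out_dir = out_dir,
    geometry = list(side = side, margin = 10, pixel_size = pixel_size),
    physics = list(mu_Pa_s = 1e-3, U_m_s = 250e-6, sigma_N_m = 50e-3,
                   H_m = 50e-6, L_bubble_m = 2.5e-3, E_kg_m2_s = 5e-5,
                   rho_kg_m3 = 1000, Q_m3_s = 3e-9 / 60, W_m = 4e-3,
                   bretherton_c = 1),
    synth = list(age_h = age_h),
    sim = list(regime = regime),
    metrics = list(close_r = 1, min_area = 3),
    correlation = list(n_perm = n_perm, block_size = 10, smoothing_sigma = 2)
  ), class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#' @param cfg A \code{pipeline_config}.
#' @param path File path.
#' @return \code{write_config}: the path, invisibly. \code{read_config}: a
#'   \code{pipeline_config}.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "pipeline_config")
}

stage_seed <- function(seed, k) (abs(seed) %% 1000003L) * 100L + k

#' Run the full generate-simulate-analyze-correlate pipeline
#'
#' Generates a synthetic EPS field and cell monolayer, runs the dewetting
#' simulator, measures coverage/porosity/hole morphometry/fractal dimension
#' before and after, computes the EPS-cell correlations (optionally with the
#' block-permutation null), and writes all artifacts to \code{cfg$out_dir}:
#' \code{eps.tif}, \code{cells_before.tif}, \code{cells_after.tif},
#' \code{holes.tif}, \code{hole_tracks.csv}, \code{holes.csv},
#' \code{report.csv}, \code{correlation.csv}, \code{resolved_config.json}
#' and \code{run.log}.
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @param write Write artifacts to disk (default TRUE).
#' @return Invisibly, a list with all stage objects and the report rows.
#' @export
run_pipeline <- function(cfg = pipeline_config(), write = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  logline <- character(0)
  say <- function(...) logline <<- c(logline, paste0(format(Sys.time(), "%H:%M:%S "), ...))
  stage <- "setup"
  result <- tryCatch({
    geom <- patch_geometry(cfg$geometry$side, cfg$geometry$margin,
                           cfg$geometry$pixel_size)
    scfg <- do.call(synth_config, cfg$synth)
    simargs <- cfg$sim
    simcfg <- do.call(sim_config, simargs)
    px <- geom$pixel_size

    stage <- "synth"
    say("generating EPS field and cell map (seed ", cfg$seed, ")")
    eps <- generate_eps_field(geom, scfg, seed = stage_seed(cfg$seed, 1L))
    cells <- generate_cell_map(geom, eps, scfg, seed = stage_seed(cfg$seed, 2L))
    say(sprintf("placed %d cells, patch coverage %.2f%%",
                nrow(cells$centroids), 100 * cells$coverage))

    stage <- "simulate"
    say("running dewetting simulator, regime ", simcfg$regime)
    res <- run_dewetting(eps, cells, simcfg, seed = stage_seed(cfg$seed, 3L))
    say(sprintf("%d holes nucleated; events: %s", length(unique(res$tracks$hole_id)),
                paste(names(res$events), res$events, sep = "=", collapse = ", ")))

    stage <- "analyze"
    roi <- geom$patch_px
    b_before <- binary_patch(cells$occupancy, px, roi)
    b_after <- binary_patch(res$cells_final$occupancy, px, roi)
    rep_before <- cbind(when = "before", metrics_report(b_before,
                        cfg$metrics$close_r, cfg$metrics$min_area))
    rep_after <- cbind(when = "after", metrics_report(b_after,
                       cfg$metrics$close_r, cfg$metrics$min_area))
    report <- rbind(rep_before, rep_after)
    seg_after <- segment_holes(b_after, cfg$metrics$close_r, cfg$metrics$min_area)
    growth <- tryCatch(characterize_growth(res), error = function(e) NULL)
    say(sprintf("porosity after: %.1f%%; mean hole radius %.2f µm",
                rep_after$porosity_pct, rep_after$mean_hole_radius_um))

    stage <- "correlate"
    ccfg <- cfg$correlation
    r_before <- normalized_cross_correlation(eps$values, cells$occupancy + 0,
                                             px, roi, ccfg$smoothing_sigma)
    r_after <- normalized_cross_correlation(eps$values,
                                            res$cells_final$occupancy + 0,
                                            px, roi, ccfg$smoothing_sigma)
    corr <- data.frame(r_before = r_before, r_after = r_after,
                       ratio = if (r_before > 0) r_after / r_before else NA_real_)
    null_after <- NULL
    if (!is.null(ccfg$n_perm) && ccfg$n_perm >= 100) {
      null_after <- bootstrap_null(eps$values, res$cells_final$occupancy + 0,
                                   px, roi, n = ccfg$n_perm,
                                   block_size = ccfg$block_size,
                                   smoothing_sigma = ccfg$smoothing_sigma,
                                   seed = stage_seed(cfg$seed, 4L))
      corr$null_mean <- null_after$null_mean
      corr$null_sd <- null_after$null_sd
      corr$z_after <- null_after$z_score
    }
    say(sprintf("r(before)=%.3f r(after)=%.3f ratio=%.2f",
                r_before, r_after, corr$ratio))

    list(geom = geom, eps = eps, cells_before = cells, sim = res,
         report = report, holes = seg_after$holes, growth = growth,
         correlation = corr, null_after = null_after, config = cfg)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (write) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(cfg$out_dir, f)
    scfg2 <- do.call(synth_config, cfg$synth)
    write_tiff(render_image(result$eps, scfg2, seed = stage_seed(cfg$seed, 5L)),
               out("eps.tif"), pixel_size = result$geom$pixel_size)
    write_tiff(render_image(result$cells_before, scfg2,
                            seed = stage_seed(cfg$seed, 6L)),
               out("cells_before.tif"), pixel_size = result$geom$pixel_size)
    write_tiff(render_image(result$sim$cells_final, scfg2,
                            seed = stage_seed(cfg$seed, 7L)),
               out("cells_after.tif"), pixel_size = result$geom$pixel_size)
    write_tiff(result$sim$hole_labels, out("holes.tif"),
               pixel_size = result$geom$pixel_size)
    utils::write.csv(result$sim$tracks, out("hole_tracks.csv"), row.names = FALSE)
    utils::write.csv(result$holes, out("holes.csv"), row.names = FALSE)
    utils::write.csv(result$report, out("report.csv"), row.names = FALSE)
    utils::write.csv(result$correlation, out("correlation.csv"), row.names = FALSE)
    write_config(cfg, out("resolved_config.json"))
    writeLines(logline, out("run.log"))
  }
  invisible(result)
}
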