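test_that("nucleation picks cell-free low-resistance sites with spacing", {
  geom <- patch_geometry(25, 0, 0.25)
  n <- geom$n_px
  # uniform EPS, a ring of cells with one interior void: the first site must
  # fall inside the void (cell pixels carry infinite resistance)
  vals <- matrix(1, n, n)
  eps <- manual_eps(geom, vals)
  theta <- seq(0, 2 * pi, length.out = 60)
  cent <- cbind(12.5 + 6 * cos(theta), 12.5 + 6 * sin(theta))
  cells <- structure(list(centroids = cent,
                          occupancy = cpp_stamp_disks(n, n, cent, 1.5, 0.25),
                          cell_radius = 1.5, pixel_size = 0.25,
                          patch_px = geom$patch_px, coverage = NA),
                     class = "cell_map")
  cfg <- sim_config(nucleation_spacing = 4)
  sites <- nucleate_ruptures(eps, cells, cfg)
  site_um <- (sites[, 2:1] + 0.5) * 0.25  # (x, y)
  d_center <- sqrt(rowSums((site_um - 12.5)^2))
  expect_true(any(d_center < 4.5))              # a site inside the void
  expect_false(any(cells$occupancy[sites + 1])) # never on a cell
  if (nrow(sites) > 1) {
    dd <- as.matrix(stats::dist(sites))
    diag(dd) <- Inf
    expect_gte(min(dd), 4 / 0.25)
  }
  # EPS with a single global minimum basin: first site sits in the basin
  xy <- (seq_len(n) - 0.5) * 0.25
  vals2 <- outer(xy, xy, function(y, x) 1 + ((x - 18)^2 + (y - 6)^2) / 100)
  eps2 <- manual_eps(geom, vals2 / max(vals2))
  empty <- structure(list(centroids = matrix(numeric(0), 0, 2),
                          occupancy = matrix(FALSE, n, n),
                          cell_radius = 0.5, pixel_size = 0.25,
                          patch_px = geom$patch_px, coverage = 0),
                     class = "cell_map")
  s2 <- nucleate_ruptures(eps2, empty, cfg)
  expect_equal((s2[1, 2] + 0.5) * 0.25, 18, tolerance = 0.5)
  expect_equal((s2[1, 1] + 0.5) * 0.25, 6, tolerance = 0.5)
})

test_that("no-effect regime returns the input cell map unchanged", {
  r <- small_run(seed = 1, regime = "no_effect_12h")
  expect_identical(r$res$cells_final$centroids, r$world$cells$centroids)
  expect_identical(r$res$cells_final$occupancy, r$world$cells$occupancy)
  expect_equal(sum(r$res$removed), 0)
})

test_that("rearrangement conserves cell count; removal only deletes", {
  r8 <- small_run(seed = 1, regime = "rearrangement_8h")
  expect_equal(nrow(r8$res$cells_final$centroids),
               nrow(r8$world$cells$centroids))
  expect_equal(r8$res$events[["cells_removed"]], 0)
  r4 <- small_run(seed = 1, regime = "removal_4h")
  n0 <- nrow(r4$world$cells$centroids)
  n1 <- nrow(r4$res$cells_final$centroids)
  expect_lt(n1, n0)
  expect_equal(n0 - n1, r4$res$events[["cells_removed"]])
  # removal regime never relocates survivors
  kept <- r4$world$cells$centroids[!r4$res$removed, , drop = FALSE]
  expect_identical(r4$res$cells_final$centroids, kept)
})

test_that("hole areas are non-decreasing and holes stay disjoint and 4-connected", {
  r <- small_run(seed = 1, regime = "rearrangement_8h")
  tr <- r$res$tracks
  for (id in unique(tr$hole_id)) {
    a <- tr$area_um2[tr$hole_id == id]
    expect_true(all(diff(a) >= 0))
    an <- tr$area_norm[tr$hole_id == id]
    expect_equal(an[length(an)], 1)
  }
  # each labelled hole is one 4-connected component
  lab <- r$res$hole_labels
  ids <- sample(setdiff(unique(as.vector(lab)), 0), 12)
  for (id in ids) {
    cc <- cpp_label_components(lab == id, 4L)
    expect_equal(max(cc), 1)
  }
})

test_that("holes form where there is least EPS and levees are enriched", {
  for (s in 1:2) {
    r <- small_run(seed = s, regime = "rearrangement_8h")
    ct <- hole_eps_contrast(r$res, r$world$eps)
    expect_lt(ct$mean_hole, ct$mean_levee)
    expect_lt(ct$p_value, 1e-6)
    expect_gt(levee_enrichment(r$res), 1)
  }
})

test_that("the EPS field is never modified by the simulator", {
  r <- small_run(seed = 1, regime = "rearrangement_8h")
  fresh <- generate_eps_field(r$world$geom, r$world$cfg)
  expect_identical(r$world$eps$values, fresh$values)
})

test_that("identical seeds give identical final states", {
  w <- small_world(seed = 3)
  sc <- sim_config("rearrangement_8h", seed = 77)
  a <- suppressWarnings(run_dewetting(w$eps, w$cells, sc))
  b <- suppressWarnings(run_dewetting(w$eps, w$cells, sc))
  expect_identical(a$cells_final$centroids, b$cells_final$centroids)
  expect_identical(a$hole_labels, b$hole_labels)
  expect_identical(a$tracks, b$tracks)
})

test_that("zero nucleation sites leave the biofilm untouched", {
  w <- small_world(seed = 1)
  sc <- sim_config("rearrangement_8h", nucleation_count = 0, seed = 1)
  res <- run_dewetting(w$eps, w$cells, sc)
  expect_identical(res$cells_final$centroids, w$cells$centroids)
  expect_true(all(res$hole_labels == 0))
  expect_null(res$tracks)
})

test_that("a lone unpinnable hole grows linearly in area after the ramp", {
  geom <- patch_geometry(50, 0, 0.5)
  eps <- manual_eps(geom, matrix(1e-3, geom$n_px, geom$n_px))
  empty <- structure(list(centroids = matrix(numeric(0), 0, 2),
                          occupancy = matrix(FALSE, geom$n_px, geom$n_px),
                          cell_radius = 0.5, pixel_size = 0.5,
                          patch_px = geom$patch_px, coverage = 0),
                     class = "cell_map")
  sc <- sim_config("rearrangement_8h", nucleation_count = 1,
                   pin_threshold = 1e9, resist_scale = 0, t_evap = 0,
                   stall_speed = 0, total_time = 6, seed = 1)
  res <- suppressWarnings(run_dewetting(eps, empty, sc))
  tr <- res$tracks
  mid <- tr[tr$t_s > 2 & tr$t_s < 5, ]
  fit <- stats::lm(area_um2 ~ t_s, data = mid)
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_gt(stats::coef(fit)[2], 0)
})
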