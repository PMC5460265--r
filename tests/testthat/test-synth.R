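test_that("EPS field is reproducible, positive, and constant when sigma = 0", {
  geom <- patch_geometry(50, 5, 0.25)
  cfg <- synth_config(age_h = 8, seed = 11)
  a <- generate_eps_field(geom, cfg)
  b <- generate_eps_field(geom, cfg)
  expect_identical(a$values, b$values)
  expect_true(all(a$values > 0))
  cfg0 <- synth_config(age_h = 8, eps_lognormal_sigma = 0)
  f0 <- generate_eps_field(geom, cfg0, seed = 1)
  expect_true(all(f0$values == f0$values[1, 1]))
  expect_error(generate_eps_field(patch_geometry(50, 5, pixel_size = 6),
                                  cfg, seed = 1), "corr_length")
})

test_that("EPS autocorrelation crosses 1/e near the configured length scale", {
  geom <- patch_geometry(100, 0, 0.5)
  cfg <- synth_config(age_h = 8, eps_corr_length = 10)
  crossings <- vapply(1:10, function(s) {
    v <- generate_eps_field(geom, cfg, seed = s)$values
    n <- ncol(v)
    lags_px <- 1:60
    ac <- vapply(lags_px, function(k)
      stats::cor(as.vector(v[, 1:(n - k)]), as.vector(v[, (k + 1):n])), 0)
    i <- which(ac <= exp(-1))[1]
    # linear interpolation of the crossing lag, in µm
    x1 <- lags_px[i - 1]; x2 <- lags_px[i]
    (x1 + (ac[i - 1] - exp(-1)) / (ac[i - 1] - ac[i]) * (x2 - x1)) * 0.5
  }, 0)
  expect_gt(mean(crossings), 8)   # 10 µm - 20 %
  expect_lt(mean(crossings), 12)  # 10 µm + 20 %
})

test_that("cell placement recovers the requested coverage", {
  geom <- patch_geometry(50, 5, 0.25)
  cfg <- synth_config(age_h = 8, seed = 2)
  eps <- generate_eps_field(geom, cfg)
  for (target in c(0.1, 0.3, 0.45)) {
    cfg_t <- synth_config(age_h = 8, target_coverage = target, seed = 2)
    cm <- generate_cell_map(geom, eps, cfg_t)
    b <- binary_patch(cm$occupancy, geom$pixel_size, geom$patch_px)
    expect_equal(surface_coverage(b), 100 * target, tolerance = 0.5 / target)
  }
})

test_that("age-specific default coverages follow the growth curve", {
  w <- small_world(seed = 1, age_h = 8)
  b <- binary_patch(w$cells$occupancy, 0.25, w$geom$patch_px)
  expect_equal(surface_coverage(b), 44.6, tolerance = 0.5 / 44.6)
  expect_equal(synth_config(age_h = 4)$target_coverage, 0.316)
  expect_equal(synth_config(age_h = 12)$target_coverage, 0.495)
})

test_that("empty and limiting cases of placement behave", {
  geom <- patch_geometry(50, 5, 0.25)
  cfg <- synth_config(age_h = 8, target_coverage = 0, seed = 1)
  eps <- generate_eps_field(geom, synth_config(age_h = 8, seed = 3))
  cm0 <- generate_cell_map(geom, eps, cfg)
  expect_equal(nrow(cm0$centroids), 0)
  expect_false(any(cm0$occupancy))
  # full coupling to a binary EPS mask confines all cells to the mask
  vals <- matrix(0, geom$n_px, geom$n_px)
  vals[, seq_len(geom$n_px / 2)] <- 1
  mask_eps <- manual_eps(geom, vals)
  cfgc <- synth_config(age_h = 8, target_coverage = 0.15,
                       eps_cell_coupling = 1, seed = 4)
  cmc <- generate_cell_map(geom, mask_eps, cfgc)
  px_col <- floor(cmc$centroids[, 1] / geom$pixel_size)
  expect_true(all(px_col < geom$n_px / 2))
  # unreachable coverage errors with the achieved value in the message
  cfg_hi <- synth_config(age_h = 12, target_coverage = 0.6,
                         max_attempts = 2e4, seed = 5)
  expect_error(generate_cell_map(geom, eps, cfg_hi), "achieved")
})

test_that("placement determinism: same seed gives identical maps", {
  geom <- patch_geometry(50, 5, 0.25)
  cfg <- synth_config(age_h = 8, seed = 6)
  eps <- generate_eps_field(geom, cfg)
  a <- generate_cell_map(geom, eps, cfg)
  b <- generate_cell_map(geom, eps, cfg)
  expect_identical(a$centroids, b$centroids)
  expect_identical(a$occupancy, b$occupancy)
})

test_that("pre-bubble EPS-cell association is positive but weak", {
  w <- small_world(seed = 1)
  r <- normalized_cross_correlation(w$eps$values, w$cells$occupancy + 0,
                                    0.25, w$geom$patch_px)
  expect_gt(r, 0)
  expect_lt(r, 0.3)
})

test_that("rendering is an affine rescale without noise and is seed-stable", {
  geom <- patch_geometry(50, 5, 0.25)
  cfg <- synth_config(age_h = 8, seed = 7,
                      noise = c(gaussian_sd = 0, background_level = 100))
  eps <- generate_eps_field(geom, cfg)
  img <- render_image(eps, cfg, scale = 1000)
  expected <- as.integer(round(100 + eps$values / max(eps$values) * 1000))
  expect_identical(as.vector(img), expected)
  # empty map renders as background plus noise only
  cfg_n <- synth_config(age_h = 8, target_coverage = 0,
                        noise = c(gaussian_sd = 50, background_level = 500))
  cm0 <- generate_cell_map(geom, eps, cfg_n, seed = 1)
  img0 <- render_image(cm0, cfg_n, seed = 1)
  expect_equal(mean(img0), 500, tolerance = 0.01)
  expect_lt(stats::sd(img0), 60)
  # determinism through to the written file: frozen golden checksum for the
  # seed-0 fixture (computed once from this exact construction)
  f1 <- withr::local_tempfile(fileext = ".tif")
  f2 <- withr::local_tempfile(fileext = ".tif")
  cfg2 <- synth_config(age_h = 8, seed = 0)
  write_tiff(render_image(eps, cfg2, seed = 0), f1, pixel_size = 0.25)
  write_tiff(render_image(eps, cfg2, seed = 0), f2, pixel_size = 0.25)
  expect_identical(digest::digest(file = f1), digest::digest(file = f2))
  expect_identical(digest::digest(file = f1), "04fb7538d889c11ade14b72fdf0cb5cf")
})

test_that("saturation is flagged", {
  geom <- patch_geometry(25, 0, 0.25)
  cfg <- synth_config(age_h = 8, noise = c(0, 60000))
  eps <- generate_eps_field(geom, cfg, seed = 1)
  expect_warning(render_image(eps, cfg, scale = 40000), "clipped")
})
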