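test_that("fast box counts equal the exhaustive brute-force count", {
  set.seed(31)
  for (i in 1:4) {
    n <- sample(33:64, 1)
    mask <- matrix(runif(n * n) < runif(1, 0.02, 0.5), n, n)
    sizes <- c(2L, 3L, 4L, 5L, 7L, 8L, 16L, 32L)
    fast <- cpp_box_counts(mask, sizes)
    slow <- vapply(sizes, function(s) brute_box_count(mask, s), 0L)
    expect_identical(as.integer(fast), slow)
  }
})

test_that("fractal dimension recovers analytic values", {
  px <- 0.25
  filled <- binary_patch(matrix(TRUE, 128, 128), px)
  expect_equal(fractal_dimension(filled)$D, 2, tolerance = 0.05 / 2)
  line <- matrix(FALSE, 128, 128); line[64, ] <- TRUE
  expect_equal(fractal_dimension(binary_patch(line, px))$D, 1, tolerance = 0.05)
  carpet <- sierpinski_carpet(5)  # 243 x 243, D = ln 8 / ln 3
  fit <- fractal_dimension(binary_patch(carpet, px))
  expect_equal(fit$D, log(8) / log(3), tolerance = 0.05 / 1.893)
  # monotone under the subset relation on these fixtures
  Dl <- fractal_dimension(binary_patch(line, px))$D
  expect_lt(Dl, fit$D)
  expect_lt(fit$D, fractal_dimension(filled)$D + 1e-9)
  # counts non-increasing in box size
  expect_true(all(diff(fit$counts) <= 0))
  expect_error(fractal_dimension(binary_patch(matrix(FALSE, 128, 128), px)),
               "foreground")
  expect_error(fractal_dimension(binary_patch(matrix(TRUE, 32, 32), px)),
               ">= 64")
})

test_that("surface coverage and its complement sum exactly to 100", {
  px <- 0.5
  expect_equal(surface_coverage(binary_patch(matrix(TRUE, 10, 10), px)), 100)
  half <- matrix(rep(c(TRUE, FALSE), each = 50), 10, 10)
  expect_equal(surface_coverage(binary_patch(half, px)), 50)
  set.seed(8)
  m <- matrix(runif(400) < 0.3, 20, 20)
  b <- binary_patch(m, px)
  bg <- binary_patch(!m, px)
  expect_equal(surface_coverage(b) + surface_coverage(bg), 100)
})

test_that("an analytic disk is segmented at its true radius", {
  px <- 0.25
  n <- 201
  xy <- (seq_len(n) - 0.5) * px
  hole <- outer(xy, xy, function(y, x) sqrt((x - 25)^2 + (y - 25)^2) <= 7)
  seg <- segment_holes(binary_patch(!hole, px), close_r = 0)
  expect_equal(nrow(seg$holes), 1)
  expect_equal(seg$holes$equivalent_radius_um, 7, tolerance = px / 7)
  expect_equal(seg$holes$centroid_x_um, 25, tolerance = px)
  # no background at all: empty table, zero porosity
  seg0 <- segment_holes(binary_patch(matrix(TRUE, 64, 64), px))
  expect_equal(nrow(seg0$holes), 0)
  expect_equal(seg0$porosity, 0)
})

test_that("porosity is invariant under pattern translation", {
  px <- 0.25
  n <- 160
  base <- matrix(TRUE, n, n)
  xy <- seq_len(n)
  put_hole <- function(m, cx, cy, r_px) {
    d <- outer(xy, xy, function(y, x) (x - cx)^2 + (y - cy)^2 <= r_px^2)
    m[d] <- FALSE
    m
  }
  m1 <- put_hole(put_hole(base, 40, 40, 12), 100, 90, 18)
  m2 <- put_hole(put_hole(base, 55, 52, 12), 115, 102, 18)  # shifted +15,+12
  p1 <- segment_holes(binary_patch(m1, px))$porosity
  p2 <- segment_holes(binary_patch(m2, px))$porosity
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("Otsu binarization splits a bimodal image and rejects degenerate input", {
  set.seed(12)
  truth <- matrix(runif(96 * 96) < 0.4, 96, 96)
  img <- matrix(ifelse(truth, 40000L, 5000L), 96, 96)
  b <- binarize(img, pixel_size = 0.25)
  expect_identical(b$mask, truth)
  expect_error(binarize(matrix(7L, 64, 64), pixel_size = 1), "degenerate")
  # round trip through rendering at low noise: near-perfect Jaccard
  w <- small_world(seed = 1)
  cfg <- synth_config(age_h = 8, noise = c(gaussian_sd = 800,
                                           background_level = 2000))
  img2 <- render_image(w$cells, cfg, seed = 9)
  b2 <- binarize(img2, pixel_size = 0.25, roi = w$geom$patch_px)
  rows <- (w$geom$patch_px[1] + 1):w$geom$patch_px[2]
  cols <- (w$geom$patch_px[3] + 1):w$geom$patch_px[4]
  truth2 <- w$cells$occupancy[rows, cols]
  got <- b2$mask[rows, cols]
  jacc <- sum(got & truth2) / sum(got | truth2)
  expect_gte(jacc, 0.95)
})

test_that("mean inter-cell distance matches lattice and Poisson references", {
  expect_equal(mean_intercell_distance(rbind(c(0, 0), c(10, 0))), 10)
  g <- as.matrix(expand.grid(x = seq(0, 45, by = 3), y = seq(0, 45, by = 3)))
  expect_equal(mean_intercell_distance(g), 3)
  expect_equal(mean_intercell_distance(rbind(c(0, 0), c(10, 0)), "allpairs"), 10)
  # Poisson field: mean nearest-neighbour distance ~ 0.5 / sqrt(lambda)
  set.seed(99)
  n <- 1e4; L <- 100
  pts <- cbind(runif(n, 0, L), runif(n, 0, L))
  expect_equal(mean_intercell_distance(pts), 0.5 / sqrt(n / L^2),
               tolerance = 0.05)
  expect_error(mean_intercell_distance(rbind(c(1, 1))), "at least 2")
})

test_that("growth-curve phase analysis classifies shapes correctly", {
  t <- seq(0, 10, by = 0.02)
  mk <- function(a) data.frame(hole_id = 1, t_s = t, area_um2 = a)
  # logistic-like curve: slow-fast-slow
  g1 <- characterize_growth(mk(1 / (1 + exp(-(t - 5) * 1.5))))
  expect_true(g1$slow_fast_slow)
  expect_false(g1$degenerate)
  # pure linear: degenerate, no flag
  g2 <- characterize_growth(mk(t))
  expect_true(g2$degenerate)
  expect_false(g2$slow_fast_slow)
  # concave saturating curve: not slow-fast-slow
  g3 <- characterize_growth(mk(sqrt(t)))
  expect_false(g3$slow_fast_slow)
  expect_error(characterize_growth(mk(t)[1:5, ]), "10 time samples")
})
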