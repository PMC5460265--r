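test_that("cross-correlation hits the exact limits and affine invariance", {
  set.seed(5)
  a <- matrix(runif(120 * 120), 120, 120)
  expect_equal(normalized_cross_correlation(a, a, 0.25), 1)
  expect_equal(normalized_cross_correlation(a, max(a) - a, 0.25), -1)
  r0 <- normalized_cross_correlation(a, a^2, 0.25)
  expect_equal(normalized_cross_correlation(3 * a - 7, 0.5 * a^2 + 11, 0.25), r0)
  expect_error(normalized_cross_correlation(a, matrix(1, 120, 120), 0.25),
               "constant")
})

test_that("independent fields decorrelate at the expected rate", {
  set.seed(6)
  n <- 200
  rs <- vapply(1:5, function(i) {
    a <- cpp_gauss_smooth(matrix(rnorm(n * n), n, n), 4)
    b <- cpp_gauss_smooth(matrix(rnorm(n * n), n, n), 4)
    normalized_cross_correlation(a, b, 0.25, smoothing_sigma = 0)
  }, 0)
  # effective sample size ~ (n / (2 sigma))^2 blobs
  n_eff <- (n / 8)^2
  expect_lt(max(abs(rs)), 3 / sqrt(n_eff))
})

test_that("block permutation preserves each block's pixel multiset", {
  set.seed(9)
  m <- matrix(rnorm(96 * 96), 96, 96)
  p <- cpp_block_permute_once(m, 16L)
  expect_identical(sort(as.vector(p)), sort(as.vector(m)))
  blocks <- function(x) {
    out <- list()
    for (br in 0:5) for (bc in 0:5)
      out[[length(out) + 1]] <-
        sort(as.vector(x[br * 16 + 1:16, bc * 16 + 1:16]))
    out
  }
  mb <- blocks(m); pb <- blocks(p)
  # every permuted block equals some original block
  expect_true(all(vapply(pb, function(b)
    any(vapply(mb, identical, TRUE, x = b)), TRUE)))
})

test_that("the block-permutation null is centred on zero", {
  w <- small_world(seed = 1)
  bn <- bootstrap_null(w$eps$values, w$cells$occupancy + 0, 0.25,
                       roi = w$geom$patch_px, n = 1000, seed = 123)
  expect_lt(abs(bn$null_mean), 0.02)
  expect_gt(bn$null_sd, 0)
  expect_equal(length(bn$null_r), 1000)
  expect_error(bootstrap_null(w$eps$values, w$cells$occupancy + 0, 0.25,
                              n = 50), "100 permutations")
  expect_error(bootstrap_null(matrix(1:64, 8), matrix(1:64, 8), 0.25,
                              block_size = 10, n = 100), "4 blocks")
})

test_that("post-bubble correlation exceeds the null by a wide margin", {
  r <- small_run(seed = 1, regime = "rearrangement_8h")
  w <- r$world
  bn <- bootstrap_null(w$eps$values, r$res$cells_final$occupancy + 0, 0.25,
                       roi = w$geom$patch_px, n = 200, seed = 11)
  expect_gt(bn$z_score, 3)
})

test_that("correlation ratio handles identity, coupling and degenerate cases", {
  w <- small_world(seed = 1)
  occ <- w$cells$occupancy + 0
  same <- correlation_ratio(w$eps$values, occ, occ, 0.25, roi = w$geom$patch_px)
  expect_equal(same$ratio, 1)
  r <- small_run(seed = 1, regime = "rearrangement_8h")
  cc <- correlation_ratio(w$eps$values, occ, r$res$cells_final$occupancy + 0,
                          0.25, roi = w$geom$patch_px)
  expect_true(cc$defined)
  expect_gt(cc$ratio, 1)
  # an anti-correlated "before" map makes the ratio undefined
  anti <- correlation_ratio(w$eps$values, max(w$eps$values) - w$eps$values,
                            occ, 0.25, roi = w$geom$patch_px)
  expect_false(anti$defined)
  expect_true(is.na(anti$ratio))
  # replicate lists produce a SEM
  cc2 <- correlation_ratio(list(w$eps$values, w$eps$values), list(occ, occ),
                           list(occ, occ), 0.25, roi = w$geom$patch_px)
  expect_equal(cc2$ratio, 1)
  expect_equal(cc2$sem, 0)
})
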