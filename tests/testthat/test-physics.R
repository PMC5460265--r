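test_that("capillary number reproduces the published span and scales linearly", {
  p50 <- physical_params(sigma = 50e-3)
  p25 <- physical_params(sigma = 25e-3)
  expect_equal(capillary_number(p50), 5e-6)
  expect_equal(capillary_number(p25), 1e-5)
  expect_equal(capillary_number(physical_params(mu = 2e-3)),
               2 * capillary_number(physical_params(mu = 1e-3)))
  # linear in mu and U, inverse in sigma, on random draws
  set.seed(42)
  for (i in 1:20) {
    mu <- runif(1, 5e-4, 5e-3); U <- runif(1, 1e-5, 1e-3)
    sg <- runif(1, 15e-3, 24e-3); k <- runif(1, 1.1, 4)  # k*sg stays in range
    base <- capillary_number(physical_params(mu = mu, U = U, sigma = sg))
    expect_equal(capillary_number(physical_params(mu = k * mu, U = U, sigma = sg)),
                 k * base)
    expect_equal(capillary_number(physical_params(mu = mu, U = k * U, sigma = sg)),
                 k * base)
    expect_equal(capillary_number(physical_params(mu = mu, U = U, sigma = k * sg)),
                 base / k)
  }
})

test_that("Bretherton film thickness matches direct evaluation and limits", {
  # oracle: direct evaluation of c * H * Ca^(2/3)
  expect_equal(film_thickness(physical_params(sigma = 25e-3)),
               50e-6 * (1e-5)^(2 / 3), tolerance = 1e-12)
  expect_equal(film_thickness(physical_params(sigma = 25e-3)), 2.32e-8,
               tolerance = 1e-3)
  expect_equal(film_thickness(physical_params(sigma = 50e-3)), 1.46e-8,
               tolerance = 1e-2)
  expect_equal(film_thickness(physical_params(U = 0)), 0)  # Ca = 0 limit
  # monotone increasing in Ca (via U)
  hs <- vapply(c(1, 2, 4, 8) * 1e-4,
               function(U) film_thickness(physical_params(U = U)), 0)
  expect_true(all(diff(hs) > 0))
  expect_equal(film_thickness(physical_params(), c = 1.34),
               1.34 * film_thickness(physical_params()))
})

test_that("evaporation and bubble passage times match the published estimates", {
  p <- physical_params(E = 5e-5)
  expect_equal(evaporation_time(1e-7, p), 2)
  expect_equal(evaporation_time(1e-7, physical_params(E = 1e-4)), 1)
  expect_equal(evaporation_time(0, p), 0)
  # monotone: increasing in h, decreasing in E
  expect_true(evaporation_time(2e-7, p) > evaporation_time(1e-7, p))
  expect_true(evaporation_time(1e-7, suppressWarnings(physical_params(E = 2e-4))) <
              evaporation_time(1e-7, p))
  expect_equal(bubble_passage_time(physical_params()), 10)
  expect_equal(bubble_passage_time(physical_params(L_bubble = 0)), 0)
  expect_equal(bubble_passage_time(physical_params(L_bubble = 5e-3)), 20)
})

test_that("channel flow quantities match the operating point", {
  p <- physical_params()
  expect_equal(mean_velocity(p), 250e-6)
  expect_equal(mean_velocity(physical_params(Q = 2 * p$Q)), 2 * mean_velocity(p))
  expect_equal(mean_velocity(physical_params(Q = 6e-11, W = 4e-3, H = 5e-5)), 3e-4)
  expect_equal(wall_shear_rate(p), 30)
  expect_equal(wall_shear_rate(p, U_mean = 0), 0)
  expect_equal(wall_shear_rate(physical_params(H = 25e-6, Q = p$Q / 2)), 60)
})

test_that("composition: film evaporates before the bubble has passed", {
  for (sigma in c(25e-3, 37e-3, 50e-3)) {
    p <- physical_params(sigma = sigma)
    h <- film_thickness(p, c = 1)
    expect_lte(h, 1e-7)  # h <= 0.1 µm
    expect_lt(evaporation_time(h, p), bubble_passage_time(p))
  }
})

test_that("parameter validation rejects bad inputs and flags odd E", {
  expect_error(physical_params(mu = -1), "strictly positive")
  expect_error(physical_params(sigma = 0.5), "plausible range")
  expect_error(capillary_number(list(mu = 1)), "physical_params")
  expect_error(film_thickness(physical_params(), c = 0), "positive")
  expect_error(evaporation_time(-1, physical_params()), "non-negative")
  expect_warning(physical_params(E = 5e-3), "outside the documented")
  expect_s3_class(physics_report(), "data.frame")
})
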