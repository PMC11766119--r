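test_that("Logan rate matches direct substitution and vanishes at t_max", {
  # at T = t_max the two exponentials cancel for any parameter set
  for (i in 1:20) {
    p <- random_params("logan")
    expect_equal(logan_rate(p[["t_max"]], p[["psi"]], p[["rho"]],
                            p[["t_max"]], p[["delta_t"]]), 0)
  }
  # direct high-precision substitution (L1 published parameters, 28 C)
  expect_equal(logan_rate(28, 0.08, 0.093, 32.6, 1.5), 1.0041571,
               tolerance = 1e-6)
  expect_equal(logan_rate(0, 0, 0.1, 33, 2), 0)
  expect_error(logan_rate(20, 0.08, 0.093, 32.6, -1), "delta_t")
  expect_error(logan_rate(NaN, 0.08, 0.093, 32.6, 1.5), "finite")
})

test_that("Briere rate is zero at and beyond both thresholds, positive between", {
  expect_equal(briere_rate(8, 1e-4, 2, 8, 33), 0)
  expect_equal(briere_rate(33, 1e-4, 2, 8, 33), 0)
  expect_equal(briere_rate(5, 1e-4, 2, 8, 33), 0)
  expect_equal(briere_rate(40, 1e-4, 2, 8, 33), 0)
  # 1e-4 * 20 * 12 * sqrt(13)
  expect_equal(briere_rate(20, 1e-4, 2, 8, 33), 1e-4 * 20 * 12 * sqrt(13))
  for (i in 1:20) {
    p <- random_params("briere")
    inside <- seq(p[["t_low"]] + 0.01, p[["t_max"]] - 0.01, length.out = 25)
    expect_true(all(briere_rate(inside, p[["a"]], p[["m"]],
                                p[["t_low"]], p[["t_max"]]) > 0))
  }
  expect_error(briere_rate(20, 1e-4, 2, 33, 8), "t_low")
  expect_error(briere_rate(20, 1e-4, 0, 8, 33), "m must")
})

test_that("Sharpe-De Michele evaluates in the Celsius parse", {
  # published egg coefficients bracket the observed egg rate 1/0.8 d
  v <- sharpe_demichele_rate(26, 4.78, -113.99, 20.44, 272.13, 6.76, -137.53)
  expect_equal(v, 1.2898915, tolerance = 1e-6)
  # all-zero coefficients: every exponential is 1
  expect_equal(sharpe_demichele_rate(26, 0, 0, 0, 0, 0, 0), 26 / 3)
  # a huge low-inactivation term drives the denominator to infinity
  expect_lt(sharpe_demichele_rate(26, 0, 0, 500, 0, 0, 0), 1e-100)
  expect_error(sharpe_demichele_rate(0, 1, 1, 1, 1, 1, 1), "singular")
  # Kelvin alternative shifts the evaluation temperature
  expect_equal(sharpe_demichele_rate(26, 0, 0, 0, 0, 0, 0, kelvin = TRUE),
               (26 + 273.15) / 3)
})

test_that("Lactin rates: lam = 0 reproduces Lactin-1 bit for bit", {
  for (i in 1:20) {
    p <- random_params("lactin1")
    t <- runif(5, 0, 40)
    expect_identical(lactin_rate(t, p[["a"]], p[["t_max"]], p[["delta_t"]]),
                     lactin_rate(t, p[["a"]], p[["t_max"]], p[["delta_t"]],
                                 lam = 0))
    expect_equal(lactin_rate(p[["t_max"]], p[["a"]], p[["t_max"]],
                             p[["delta_t"]]), 0)
  }
  # G(t_max) = lam for the Lactin-2 variant
  expect_equal(lactin_rate(33.9, 0.14, 33.9, 6.9, lam = -0.3), -0.3)
  expect_equal(lactin_rate(27, 0.14, 33.9, 6.9, lam = -0.3), 1.1647041,
               tolerance = 1e-6)
})

test_that("bathtub mortality is the plain quartic, unclipped", {
  expect_equal(bathtub_mortality(0, 0, 0, 0, 0, 2), 2)
  expect_equal(bathtub_mortality(1, 1, 1, 1, 1, 1), 5)
  expect_equal(bathtub_mortality(10, 1e-5, -1e-3, 0.03, -0.3, 1),
               1e-5 * 1e4 - 1e-3 * 1e3 + 0.03 * 100 - 0.3 * 10 + 1)
  # negative output is passed through, not clipped
  expect_lt(bathtub_mortality(33, 1.2e-5, -8e-4, 2e-2, -0.3, 2), 0)
})

test_that("Kim-Lee mortality: minimum 1 - k at the optimum, saturates to 1", {
  for (i in 1:20) {
    p <- random_params("kimlee")
    expect_equal(kimlee_mortality(p[["t_opt_survival"]], p[["k"]],
                                  p[["rho_t"]], p[["t_opt_survival"]]),
                 1 - p[["k"]])
    expect_equal(kimlee_mortality(p[["t_opt_survival"]] - 10 * p[["rho_t"]],
                                  p[["k"]], p[["rho_t"]],
                                  p[["t_opt_survival"]]), 1,
                 tolerance = 1e-8)
  }
  expect_equal(kimlee_mortality(22, 1, 5, 22), 0)
  # extreme cold saturates through IEEE overflow without NaN
  expect_equal(kimlee_mortality(-10, 0.9, 0.01, 30), 1)
})

test_that("fertility curve peaks at tau and is symmetric about it", {
  expect_equal(fertility_curve(24, pi, 1, 1, 24, 0), 2)
  for (i in 1:20) {
    p <- random_params("fertility_gaussianlike")
    peak <- p[["alpha"]] * (p[["gamma_"]] + 1) /
      (pi * p[["lam"]]^(2 * p[["gamma_"]] + 2)) *
      (p[["lam"]]^2 + p[["delta"]]^2)^p[["gamma_"]]
    expect_equal(fertility_curve(p[["tau"]], p[["alpha"]], p[["gamma_"]],
                                 p[["lam"]], p[["tau"]], p[["delta"]]),
                 peak, tolerance = 1e-10)
    x <- runif(5, 0, 25)
    expect_equal(fertility_curve(p[["tau"]] + x, p[["alpha"]], p[["gamma_"]],
                                 p[["lam"]], p[["tau"]], p[["delta"]]),
                 fertility_curve(p[["tau"]] - x, p[["alpha"]], p[["gamma_"]],
                                 p[["lam"]], p[["tau"]], p[["delta"]]))
  }
  # negative base with non-integer exponent: defined as zero
  expect_equal(fertility_curve(60, 100, 1.5, 2, 23, 0), 0)
  expect_error(fertility_curve(20, 1, 1, 0, 23, 0), "lam")
})

test_that("registry lists families and round-trips parameter sets", {
  expect_setequal(rate_model(),
                  c("logan", "briere", "sharpe_demichele", "lactin1",
                    "lactin2", "bathtub", "kimlee",
                    "fertility_gaussianlike"))
  p <- c(psi = 0.08, rho = 0.093, t_max = 32.6, delta_t = 1.5)
  flat <- params_to_list(p, "logan")
  expect_equal(params_from_list(flat), p)
  expect_error(rate_model("gompertz"), "unknown model")
  expect_error(params_from_list(list(model = "logan", psi = 1)),
               "incomplete")
  # registry evaluator agrees with the exported function
  expect_equal(rate_model("logan")$fn(28, p),
               logan_rate(28, 0.08, 0.093, 32.6, 1.5))
})
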