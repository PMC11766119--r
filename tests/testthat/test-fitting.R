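test_that("dataset builders emit the documented point structure", {
  durs <- data.frame(individual_id = as.character(1:3), temperature_C = 20,
                     stage = "egg", duration_days = c(1, 2, 4),
                     completed = TRUE)
  ds <- build_development_dataset(durs, "egg")
  expect_equal(ds$response, c(1, 0.5, 0.25))
  expect_equal(attr(ds, "response_kind"), "development_rate")

  lt <- data.frame(stage = "egg", temperature_C = c(6, 26),
                   n_entered = c(50, 50), n_survived = c(13, 48))
  mds <- build_mortality_dataset(lt, "egg")
  expect_equal(nrow(mds), 2)  # one point per temperature
  expect_equal(mds$response, c(0.74, 0.04))

  lon <- data.frame(individual_id = c("m", "f"), temperature_C = 25,
                    sex = c("male", "female"), longevity_days = c(22, 20))
  lds <- build_longevity_dataset(lon, "male")
  expect_equal(lds$response, 1 / 22)
  expect_equal(nrow(lds), 1)
  expect_error(build_longevity_dataset(lon[0, ], "male"), "no adults")
})

test_that("a perfect fit reports R2 = 1, zero RMSE and chi-squared", {
  t <- seq(10, 32, 2)
  y <- logan_rate(t, 0.08, 0.093, 32.6, 1.5)
  g <- goodness_of_fit(y, y, 4)
  expect_equal(g$r_squared, 1)
  expect_equal(g$rmse, 0)
  expect_equal(g$chi_squared, 0)
  expect_equal(g$ndf, length(t) - 4)
})

test_that("goodness of fit matches an independent hand computation", {
  obs <- c(1, 2, 3)
  pred <- c(1.1, 1.9, 3.2)
  g <- goodness_of_fit(obs, pred, 1)
  # spreadsheet-style arithmetic, written out term by term
  ss_res <- 0.1^2 + 0.1^2 + 0.2^2
  expect_equal(g$r_squared, 1 - ss_res / 2, tolerance = 1e-12)
  expect_equal(g$rmse, sqrt(ss_res / 3), tolerance = 1e-12)
  expect_equal(g$chi_squared,
               0.1^2 / 1.1 + 0.1^2 / 1.9 + 0.2^2 / 3.2, tolerance = 1e-12)
  expect_equal(g$ndf, 2)
  # a constant prediction equal to the mean has R2 = 0
  expect_equal(goodness_of_fit(obs, rep(2, 3), 1)$r_squared, 0)
  # tiny predictions are excluded from chi-squared and counted
  g2 <- goodness_of_fit(c(0, 1), c(0, 1), 1)
  expect_equal(g2$n_excluded, 1)
  # constant observations leave R2 undefined
  expect_true(is.na(goodness_of_fit(c(2, 2), c(1, 2), 1)$r_squared))
})

test_that("noise-free self-generated data are recovered by every family", {
  # full-precision recovery is exercised in the acceptance suite; here a
  # representative threshold family at a reduced start budget
  t <- seq(8, 32, length.out = 20)
  truth <- c(psi = 0.08, rho = 0.093, t_max = 32.6, delta_t = 1.5)
  ds <- rate_dataset(t, logan_rate(t, 0.08, 0.093, 32.6, 1.5))
  f <- fit_model(ds, "logan", n_starts = 32, seed = 5)
  expect_true(f$converged)
  expect_lt(max(abs(f$estimates - truth) / truth), 1e-3)
  expect_lt(f$rmse, 1e-8)
  expect_equal(f$ndf, 16)
})

test_that("fits are invariant to point order and dataset duplication", {
  t <- seq(10, 31, 3)
  y <- lactin_rate(t, 0.12, 33.5, 5) + 0.01 * sin(seq_along(t))
  ds <- rate_dataset(t, y)
  f1 <- fit_model(ds, "lactin1", n_starts = 16, seed = 9)
  perm <- c(4, 1, 7, 2, 6, 3, 5, 8)
  f2 <- fit_model(rate_dataset(t[perm], y[perm]), "lactin1",
                  n_starts = 16, seed = 9)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-6)
  f3 <- fit_model(rate_dataset(c(t, t), c(y, y)), "lactin1",
                  n_starts = 16, seed = 9)
  expect_equal(f1$estimates, f3$estimates, tolerance = 1e-6)
  # duplication doubles the information: standard errors shrink
  expect_true(all(f3$std_errors < f1$std_errors))
})

test_that("fixed-seed fits are bit-reproducible", {
  ds <- rate_dataset(seq(10, 31, 3),
                     logan_rate(seq(10, 31, 3), 0.08, 0.093, 32.6, 1.5))
  f1 <- fit_model(ds, "logan", n_starts = 16, seed = 2)
  f2 <- fit_model(ds, "logan", n_starts = 16, seed = 2)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$rmse, f2$rmse)
})

test_that("underdetermined fits are refused", {
  ds <- rate_dataset(c(10, 20, 30), c(0.1, 0.5, 0.2))
  expect_error(fit_model(ds, "logan"), "degrees of freedom")
})

test_that("model ranking is by RMSE with R-squared tie-break", {
  mk <- function(rmse, r2, ds) structure(
    list(model_key = "logan", r_squared = r2, rmse = rmse,
         chi_squared = 0.1, ndf = 5, converged = TRUE, data = ds),
    class = "fit_result")
  ds <- rate_dataset(1:10, (1:10) / 10)
  cmp <- compare_models(list(mk(0.2, 0.9, ds), mk(0.1, 0.5, ds)))
  expect_equal(cmp$rmse, c(0.1, 0.2))
  tie <- compare_models(list(mk(0.1, 0.8, ds), mk(0.1, 0.9, ds)))
  expect_equal(tie$r_squared, c(0.9, 0.8))
  other <- rate_dataset(1:10, (10:1) / 10)
  expect_error(compare_models(list(mk(0.1, 0.9, ds), mk(0.1, 0.9, other))),
               "different datasets")
})

test_that("the generating family wins the comparison on its own data", {
  t <- rep(seq(9, 32, length.out = 14), each = 3)
  set.seed(33)
  y <- logan_rate(t, 0.08, 0.093, 32.6, 1.5) + rnorm(length(t), 0, 0.005)
  ds <- rate_dataset(t, pmax(y, 0))
  fits <- lapply(c("logan", "briere", "lactin1", "lactin2"),
                 function(k) fit_model(ds, k, n_starts = 24, seed = 4))
  cmp <- compare_models(fits)
  expect_equal(cmp$model_key[1], "logan")
})

test_that("Sharpe-De Michele standard errors are withheld when unreliable", {
  t <- seq(8, 32, length.out = 20)
  y <- sharpe_demichele_rate(t, 4.78, -113.99, 20.44, 272.13, 6.76, -137.53)
  f <- fit_model(rate_dataset(t, y), "sharpe_demichele", n_starts = 32,
                 seed = 6)
  expect_true(f$converged)
  expect_lt(f$rmse, 1e-6)       # curve recovered even if parameters are not
  expect_true(all(is.na(f$std_errors)))
})
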