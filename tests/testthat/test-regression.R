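panel_cn <- china_covariates()
deaths_cn <- china_fatalities()
fit_reg <- fatality_lm(panel_cn, deaths_cn)

test_that("covariate correlations match the published magnitudes and are negative", {
  ct <- covariate_correlations(panel_cn, deaths_cn)
  expect_equal(round(ct$magnitude, 3),
               c(0.941, 0.987, 0.971, 0.951, 0.974, 0.890))
  expect_true(all(ct$r < 0))  # covariates rise, deaths fall
  expect_equal(min(round(ct$magnitude, 3)), 0.890)
})

test_that("correlation handles exact linear and degenerate columns", {
  p <- panel_cn
  p$vehicles_1e4 <- as.numeric(deaths_cn)
  expect_equal(covariate_correlations(p, deaths_cn)$r[1], 1.0)
  p$vehicles_1e4 <- -as.numeric(deaths_cn)
  ct <- covariate_correlations(p, deaths_cn)
  expect_equal(ct$r[1], -1.0)
  expect_equal(ct$magnitude[1], 1.0)
  p$vehicles_1e4 <- 5
  expect_error(covariate_correlations(p, deaths_cn),
               "vehicles_1e4.*zero variance")
})

test_that("OLS refit matches the published coefficient table at printed precision", {
  tab <- fit_reg$coefficients
  expect_equal(round(unname(tab[, "estimate"]), 3),
               c(779909.386, -9.153, -5.403, -0.147, 0.087, -0.028, 0.003))
  expect_equal(round(unname(tab[, "std_error"]), 3),
               c(802935.957, 21.124, 5.943, 0.235, 0.141, 0.027, 0.003))
  expect_equal(round(unname(tab[, "t_value"]), 3),
               c(0.971, -0.433, -0.909, -0.625, 0.618, -1.054, 1.023))
  expect_equal(round(unname(tab[, "p_value"]), 2),
               c(0.40, 0.69, 0.43, 0.58, 0.58, 0.37, 0.38))
})

test_that("overall F and determination statistics are as published", {
  expect_equal(unname(fit_reg$fstatistic["value"]), 67.431, tolerance = 1e-4)
  expect_identical(unname(fit_reg$fstatistic[c("df1", "df2")]), c(6, 3))
  # the printed "R^2 = 0.996" is actually multiple R; R^2 is ~0.9926
  expect_equal(fit_reg$r, 0.9963, tolerance = 1e-4)
  expect_equal(fit_reg$r.squared, 0.99264, tolerance = 1e-4)
  expect_true(fit_reg$r.squared >= 0 && fit_reg$r.squared <= 1)
})

test_that("fitted values reproduce the published prediction table within 1 person", {
  published <- c(110334, 105103, 97660, 96681, 89975,
                 83033, 72208, 69830, 64208, 62035)
  expect_true(all(abs(round(as.numeric(fitted(fit_reg))) - published) <= 1))
  # residuals of an intercept model sum to zero
  expect_equal(sum(as.numeric(residuals(fit_reg))), 0, tolerance = 1e-6)
})

test_that("prediction on new covariate rows applies the fitted equation", {
  hold <- china_covariates(holdout = TRUE)
  pred <- predict(fit_reg, hold)
  expect_identical(series_years(pred), 2012:2013L)
  # full-precision coefficients give 61893 / 74038 for 2012/2013; the
  # published 62402 / 73962 stem from display-rounded coefficients
  expect_equal(round(as.numeric(pred)), c(61893, 74038))
  b <- c(779909.386, -9.153, -5.403, -0.147, 0.087, -0.028, 0.003)
  X <- cbind(1, as.matrix(hold[, -1]))
  expect_equal(round(drop(X %*% b)), c(62402, 73962))
  # schema error on a missing column
  expect_error(predict(fit_reg, hold[, -2]), "missing column")
})

test_that("an exactly linear response is fit exactly", {
  p <- panel_cn
  y <- annual_series(3000 + 2.5 * p$vehicles_1e4, years = p$year)
  fit <- fatality_lm(p, y)
  expect_equal(unname(coef(fit)), c(3000, 2.5, 0, 0, 0, 0, 0),
               tolerance = 1e-6)
  expect_equal(fit$r.squared, 1, tolerance = 1e-9)
  expect_equal(as.numeric(fitted(fit)), as.numeric(y), tolerance = 1e-8)
})

test_that("coefficients agree with closed-form normal equations on 2-covariate subproblems", {
  y <- as.numeric(deaths_cn)
  pairs <- list(c("vehicles_1e4", "population_1e4"),
                c("gdp_1e8", "road_km"),
                c("freight_1e4t", "passengers_1e4"))
  for (pr in pairs) {
    oracle <- ols2_closed_form(panel_cn[[pr[1]]], panel_cn[[pr[2]]], y)
    lmfit <- stats::lm(y ~ panel_cn[[pr[1]]] + panel_cn[[pr[2]]])
    expect_equal(unname(coef(lmfit)), unname(oracle), tolerance = 1e-10)
  }
})

test_that("exactly collinear designs are rejected with the column named", {
  p <- panel_cn
  p$road_km <- 2 * p$gdp_1e8
  expect_error(fatality_lm(p, deaths_cn), "collinear.*road_km")
})

test_that("misaligned or underdetermined inputs are rejected", {
  expect_error(fatality_lm(panel_cn, annual_series(1:10, start = 2003)),
               "align")
  expect_error(fatality_lm(panel_cn[1:5, ],
                           annual_series(as.numeric(deaths_cn)[1:5],
                                         start = 2002)),
               "at least")
})
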