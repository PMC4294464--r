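# canonical covariate columns and their human-readable labels
.panel_cols <- c(vehicles_1e4   = "Vehicle population (10^4 vehicles)",
                 population_1e4 = "Population (10^4 persons)",
                 gdp_1e8        = "GDP (10^8 yuan)",
                 freight_1e4t   = "Freight volume by road (10^4 t)",
                 passengers_1e4 = "Passenger volume by road (10^4 persons)",
                 road_km        = "Road mileage (km)")

#' Validate a covariate panel
#'
#' A covariate panel is a data frame with a `year` column and the six
#' macro-level exposure covariates used by the fatality regression:
#' `vehicles_1e4` (vehicle population, 10^4 vehicles), `population_1e4`
#' (10^4 persons), `gdp_1e8` (10^8 yuan), `freight_1e4t` (road freight,
#' 10^4 t), `passengers_1e4` (road passengers, 10^4 persons) and `road_km`
#' (road mileage, km).
#'
#' @param x a data frame.
#' @return the validated data frame, classed `covariate_panel`.
#' @export
covariate_panel <- function(x) {
  x <- as.data.frame(x)
  need <- c("year", names(.panel_cols))
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("covariate panel is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (cn in need) {
    if (!is.numeric(x[[cn]]))
      stop("covariate panel column '", cn, "' is not numeric", call. = FALSE)
    if (anyNA(x[[cn]]))
      stop("covariate panel column '", cn, "' has missing cells", call. = FALSE)
  }
  x <- x[need]
  class(x) <- c("covariate_panel", "data.frame")
  x
}

#' Pearson correlation of each covariate with the response
#'
#' Computes the product-moment correlation of each of the six covariates
#' with the annual response. Both the signed value and its magnitude are
#' reported: in the bundled Chinese data every covariate trends upward
#' while deaths trend downward, so all signed correlations are negative
#' although published tables print magnitudes.
#'
#' @param panel a [covariate_panel()].
#' @param response an [annual_series()] aligned with `panel$year`.
#' @return data frame with columns `variable`, `label`, `r` (signed) and
#'   `magnitude`.
#' @examples
#' covariate_correlations(china_covariates(), china_fatalities())
#' @export
covariate_correlations <- function(panel, response) {
  panel <- covariate_panel(panel)
  response <- as_annual_series(response)
  .check_panel_alignment(panel, response)
  if (nrow(panel) < 3L)
    stop("need at least 3 observations for a correlation", call. = FALSE)
  y <- as.numeric(response)
  r <- vapply(names(.panel_cols), function(cn) {
    s <- panel[[cn]]
    if (stats::sd(s) == 0)
      stop("correlation undefined: column '", cn, "' has zero variance",
           call. = FALSE)
    stats::cor(s, y)
  }, numeric(1))
  data.frame(variable = names(.panel_cols),
             label = unname(.panel_cols),
             r = unname(r), magnitude = abs(unname(r)))
}

.check_panel_alignment <- function(panel, response) {
  if (!identical(as.integer(panel$year), series_years(response)))
    stop("panel years and response years do not align", call. = FALSE)
  invisible(TRUE)
}

#' Six-covariate linear regression of annual fatalities
#'
#' Fits, by ordinary least squares with intercept (QR decomposition via
#' [stats::lm()]), the regression of the annual death toll on the six
#' covariates of a [covariate_panel()]:
#' \deqn{Y = b_0 + b_1 S_1 + \dots + b_6 S_6 + \varepsilon .}
#' With ten annual observations and seven parameters the residual degrees
#' of freedom are 3, so individual t-tests are weak and near-collinearity
#' among the trending covariates is expected; the overall F test is the
#' meaningful diagnostic.
#'
#' @param panel a [covariate_panel()] of training years.
#' @param response an [annual_series()] of deaths, aligned with the panel.
#' @return An object of class `fatality_lm`: the underlying `lm` fit plus
#'   `coefficients` table (estimate, SE, t, p), `r.squared`, `r` (multiple
#'   correlation), `fstatistic` (value, df1, df2), `fitted`
#'   (`annual_series`), `observed` and `call`. Methods: `print`, `summary`,
#'   `coef`, `fitted`, `residuals`, `predict`, `plot`.
#' @examples
#' fit <- fatality_lm(china_covariates(), china_fatalities())
#' fit$fstatistic  # F = 67.431 on 6 and 3 df
#' @export
fatality_lm <- function(panel, response) {
  panel <- covariate_panel(panel)
  response <- as_annual_series(response)
  .check_panel_alignment(panel, response)
  p <- length(.panel_cols)
  if (nrow(panel) < p + 2L)
    stop("need at least ", p + 2L,
         " rows to fit 7 parameters with residual df >= 1", call. = FALSE)

  # Equilibrate: the covariates span 4 orders of magnitude and, being
  # co-trending macro indicators, are near-collinear; scaling each column
  # to unit RMS before the QR solve keeps the design numerically sound.
  # Estimates, SEs and all scale-invariant diagnostics transform back.
  dat <- cbind(deaths = as.numeric(response), panel[names(.panel_cols)])
  scales <- vapply(dat[names(.panel_cols)],
                   function(v) sqrt(mean(v^2)), numeric(1))
  scales[scales == 0] <- 1  # let the rank check report the dead column
  sdat <- dat
  for (cn in names(.panel_cols)) sdat[[cn]] <- dat[[cn]] / scales[[cn]]

  form <- stats::as.formula(paste("deaths ~", paste(names(.panel_cols),
                                                    collapse = " + ")))
  lmfit <- stats::lm(form, data = sdat, tol = 1e-12)
  if (lmfit$rank < p + 1L) {
    dropped <- names(which(is.na(stats::coef(lmfit))))
    stop("rank-deficient design: collinear column(s) ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  # noise-free synthetic data fit exactly; summary.lm's warning about a
  # perfect fit is expected there, not actionable
  sm <- withCallingHandlers(
    summary(lmfit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ctab <- sm$coefficients
  colnames(ctab) <- c("estimate", "std_error", "t_value", "p_value")
  ctab[names(.panel_cols), c("estimate", "std_error")] <-
    ctab[names(.panel_cols), c("estimate", "std_error")] / scales

  structure(
    list(lm = lmfit,
         coefficients = ctab,
         r.squared = sm$r.squared,
         r = sqrt(sm$r.squared),
         sigma = sm$sigma,
         fstatistic = c(value = unname(sm$fstatistic[1L]),
                        df1 = unname(sm$fstatistic[2L]),
                        df2 = unname(sm$fstatistic[3L])),
         fitted = annual_series(unname(stats::fitted(lmfit)),
                                years = panel$year),
         observed = response,
         call = match.call()),
    class = "fatality_lm")
}

#' @export
coef.fatality_lm <- function(object, ...) {
  stats::setNames(object$coefficients[, "estimate"],
                  rownames(object$coefficients))
}

#' @export
fitted.fatality_lm <- function(object, ...) object$fitted

#' @export
residuals.fatality_lm <- function(object, ...) {
  annual_series(unname(stats::residuals(object$lm)),
                series_years(object$observed))
}

#' @export
print.fatality_lm <- function(x, ...) {
  cat("Fatality regression (OLS, 6 covariates + intercept)\n")
  print(round(x$coefficients, 3))
  cat(sprintf("\nR^2 = %.4f  (multiple R = %.4f)\n", x$r.squared, x$r))
  cat(sprintf("F = %.3f on %d and %d df\n", x$fstatistic["value"],
              as.integer(x$fstatistic["df1"]), as.integer(x$fstatistic["df2"])))
  invisible(x)
}

#' @export
summary.fatality_lm <- function(object, ...) {
  rep <- relative_errors(object$observed, object$fitted)
  structure(list(fit = object, errors = rep,
                 comprehensive = comprehensive_error(rep)),
            class = "summary.fatality_lm")
}

#' @export
print.summary.fatality_lm <- function(x, ...) {
  print(x$fit)
  cat("\nResidual test:\n")
  print(x$errors)
  cat(sprintf("Comprehensive error (all years): %.3f%%\n", x$comprehensive))
  invisible(x)
}

#' Predict fatalities for new covariate rows
#'
#' @param object a [fatality_lm()] fit.
#' @param newdata a [covariate_panel()] (any years).
#' @param rounded round predictions to whole persons? Default `FALSE`;
#'   full precision is kept internally and rounding is for table display.
#' @param ... unused.
#' @return an [annual_series()] of predictions.
#' @export
predict.fatality_lm <- function(object, newdata, rounded = FALSE, ...) {
  newdata <- covariate_panel(newdata)
  X <- cbind(1, as.matrix(newdata[names(.panel_cols)]))
  pred <- drop(X %*% coef(object))
  if (rounded) pred <- round(pred)
  annual_series(pred, years = newdata$year)
}

#' @export
plot.fatality_lm <- function(x, ...) {
  yrs <- series_years(x$observed)
  graphics::plot(yrs, as.numeric(x$observed), pch = 16,
                 xlab = "Year", ylab = "Deaths",
                 main = "Fatality regression fit", ...)
  graphics::lines(yrs, as.numeric(x$fitted), col = "firebrick", lwd = 2)
  graphics::legend("topright", legend = c("observed", "fitted"),
                   pch = c(16, NA), lty = c(NA, 1),
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}
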