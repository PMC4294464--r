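#' Fit a grey Verhulst model to an annual series
#'
#' Estimates the two parameters of the grey Verhulst model, the grey-system
#' form of logistic (Verhulst) saturation dynamics
#' \deqn{x^{(1)\prime} + a\,x^{(1)} = \mu\,(x^{(1)})^2}
#' on a short, positive annual series. The discretised model
#' \deqn{x^{(0)}(k) + a\,z^{(1)}(k) = \mu\,z^{(1)}(k)^2}
#' is solved for `(a, mu)` by least squares (QR), where `x^{(0)}` is the
#' differenced series and `z^{(1)}` the consecutive-neighbour mean sequence.
#'
#' `a` is the development coefficient (1/year) governing the speed of
#' approach to saturation; `mu` is the grey action quantity, setting the
#' saturation level `a/mu`. The fitted trajectory comes from the
#' time-response function of the whitened equation (see [time_response()]),
#' anchored at the first observed value.
#'
#' @param series an [annual_series()] (or coercible data frame) of positive
#'   values, length >= 4.
#' @param orientation `"observed_as_accumulated"` (default) treats the raw
#'   series itself as the accumulated sequence x(1) and fits its first
#'   differences — the convention for series that are already S-shaped /
#'   saturating, such as the national fatality counts this package ships.
#'   `"classic_ago"` first cumulates the raw series (the textbook AGO
#'   route) and fits the raw values as x(0).
#' @return An object of class `grey_verhulst` with components `a`, `mu`,
#'   `anchor` (x(1)(0), the first accumulated value), `orientation`,
#'   `observed`, `fitted` (both `annual_series`), and `call`. Methods:
#'   `print`, `summary`, `coef`, `fitted`, `residuals`, `predict`, `plot`.
#' @examples
#' fit <- grey_verhulst(china_fatalities())
#' coef(fit)             # a = 0.12238288, mu = 6.89e-7
#' predict(fit, horizon = 2)
#' @seealso [time_response()], [relative_errors()], [simulate_logistic_series()]
#' @export
grey_verhulst <- function(series,
                          orientation = c("observed_as_accumulated",
                                          "classic_ago")) {
  orientation <- match.arg(orientation)
  series <- as_annual_series(series)
  if (length(series) < 4L)
    stop("grey Verhulst fit needs at least 4 observations", call. = FALSE)
  if (any(as.numeric(series) <= 0))
    stop("grey Verhulst dynamics assume positive values; ",
         "series contains a nonpositive observation", call. = FALSE)

  # x1: the accumulated sequence the dynamics are fitted to
  x1 <- if (orientation == "classic_ago") cumsum(as.numeric(series))
        else as.numeric(series)
  x0 <- diff(x1)                      # response, k = 2..n
  z  <- mean_sequence(x1)             # background values z(1)(k)

  B <- cbind(-z, z^2)
  qrB <- qr(B)
  if (qrB$rank < 2L)
    stop("degenerate fit: the 2-parameter least-squares system is singular ",
         "(is the series constant?)", call. = FALSE)
  theta <- qr.coef(qrB, x0)
  a <- unname(theta[1L]); mu <- unname(theta[2L])

  fit <- structure(
    list(a = a, mu = mu, anchor = x1[1L], orientation = orientation,
         observed = series, call = match.call()),
    class = "grey_verhulst")
  fit$fitted <- annual_series(.gv_fitted_observed(fit, length(series)),
                              series_years(series))
  fit
}

# time-response values on the x1 (accumulated) scale at indices k = 0..(m-1)
.gv_x1hat <- function(fit, k) time_response(fit, k)

# fitted values on the observed scale for the first m years
.gv_fitted_observed <- function(fit, m) {
  x1hat <- .gv_x1hat(fit, 0:(m - 1L))
  if (fit$orientation == "classic_ago") c(x1hat[1L], diff(x1hat)) else x1hat
}

#' Time-response function of a grey Verhulst fit
#'
#' Evaluates the closed-form solution of the whitened Verhulst equation,
#' \deqn{\hat x^{(1)}(k+1) = \frac{a\,x^{(1)}(0)}{\mu x^{(1)}(0) +
#'   (a - \mu x^{(1)}(0))\,e^{a k}},}
#' at nonnegative indices `k` (k = 0 returns the anchor exactly). Values are
#' on the accumulated (x(1)) scale; under the default orientation that is
#' the observed scale.
#'
#' @param fit a `grey_verhulst` object (or any list with `a`, `mu`, `anchor`).
#' @param k vector of nonnegative integer indices.
#' @return numeric vector of model values.
#' @examples
#' fit <- grey_verhulst(china_fatalities())
#' round(time_response(fit, 0:2))  # 109381 104176 98860
#' @export
time_response <- function(fit, k) {
  if (any(k < 0)) stop("'k' must be nonnegative", call. = FALSE)
  a <- fit$a; mu <- fit$mu; x10 <- fit$anchor
  den <- mu * x10 + (a - mu * x10) * exp(a * k)
  if (any(!is.finite(den)) || any(abs(den) < .Machine$double.eps * abs(a * x10)))
    stop("time-response denominator vanishes at some requested index",
         call. = FALSE)
  a * x10 / den
}

#' @export
coef.grey_verhulst <- function(object, ...) c(a = object$a, mu = object$mu)

#' @export
fitted.grey_verhulst <- function(object, ...) object$fitted

#' @export
residuals.grey_verhulst <- function(object, ...) {
  annual_series(as.numeric(object$observed) - as.numeric(object$fitted),
                series_years(object$observed))
}

#' @export
print.grey_verhulst <- function(x, digits = 8, ...) {
  cat("Grey Verhulst model (", x$orientation, ")\n", sep = "")
  cat("  development coefficient a  :", format(x$a, digits = digits), "\n")
  cat("  grey action quantity mu    :", format(x$mu, digits = digits), "\n")
  cat("  anchor x(1)(0)             :", format(x$anchor), "\n")
  cat("  saturation level a/mu      :", format(x$a / x$mu, digits = digits), "\n")
  invisible(x)
}

#' @describeIn grey_verhulst residual test: per-year relative errors and the
#'   comprehensive error with the anchor year excluded (it is exact by
#'   construction).
#' @param object,x a `grey_verhulst` object.
#' @param ... unused.
#' @export
summary.grey_verhulst <- function(object, ...) {
  rep <- relative_errors(object$observed, object$fitted)
  structure(list(fit = object, errors = rep,
                 comprehensive = comprehensive_error(rep, exclude_anchor = TRUE)),
            class = "summary.grey_verhulst")
}

#' @export
print.summary.grey_verhulst <- function(x, ...) {
  print(x$fit)
  cat("\nResidual test:\n")
  print(x$errors)
  cat(sprintf("Comprehensive error (anchor year excluded): %.3f%%\n",
              x$comprehensive))
  invisible(x)
}

#' Forecast from a grey Verhulst fit
#'
#' Extends the fitted time-response trajectory beyond the sample. Year
#' `first_year + n + j - 1` (j = 1..horizon) is evaluated at index
#' `k = n + j - 1`, the continuation of the in-sample index.
#'
#' @param object a `grey_verhulst` fit.
#' @param horizon number of years beyond the sample (>= 1).
#' @param rounded round forecasts to whole persons (counts)? Default `FALSE`.
#' @param ... unused.
#' @return an [annual_series()] of `horizon` out-of-sample values.
#' @export
predict.grey_verhulst <- function(object, horizon = 1L, rounded = FALSE, ...) {
  horizon <- as.integer(horizon)
  if (length(horizon) != 1L || is.na(horizon) || horizon < 1L)
    stop("'horizon' must be a positive integer", call. = FALSE)
  n <- length(object$observed)
  k <- n:(n + horizon - 1L)
  x1hat <- time_response(object, c(n - 1L, k))  # prepend last in-sample point
  out <- if (object$orientation == "classic_ago") diff(x1hat) else x1hat[-1L]
  if (rounded) out <- round(out)
  annual_series(out, years = series_years(object$observed)[n] + seq_len(horizon))
}

#' @export
plot.grey_verhulst <- function(x, ...) {
  yrs <- series_years(x$observed)
  graphics::plot(yrs, as.numeric(x$observed), pch = 16,
                 xlab = "Year", ylab = "Value",
                 main = "Grey Verhulst fit", ...)
  graphics::lines(yrs, as.numeric(x$fitted), col = "steelblue", lwd = 2)
  graphics::legend("topright", legend = c("observed", "fitted"),
                   pch = c(16, NA), lty = c(NA, 1),
                   col = c("black", "steelblue"), bty = "n")
  invisible(x)
}

#' @export
simulate.grey_verhulst <- function(object, nsim = 1, seed = NULL,
                                   noise = 0.02, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$observed)
  yr1 <- series_years(object$observed)[1L]
  replicate(nsim, simulate_logistic_series(
    a = object$a, mu = object$mu, x0 = object$anchor, n = n,
    first_year = yr1, noise = noise), simplify = FALSE)
}
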