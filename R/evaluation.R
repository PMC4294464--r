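#' Per-year relative errors of a prediction
#'
#' The residual test used throughout this package: for aligned observed and
#' predicted annual series it computes the absolute error
#' \eqn{\Delta(k) = |x(k) - \hat x(k)|} and the relative error
#' \eqn{\varphi(k) = \Delta(k)/x(k) \times 100\%}.
#'
#' @param observed an [annual_series()] of nonzero observations.
#' @param predicted an [annual_series()] aligned with `observed`.
#' @return An `error_report`: a data frame with columns `year`, `observed`,
#'   `predicted`, `abs_error` and `rel_error_pct`, plus a logical
#'   `included` column used by [comprehensive_error()].
#' @examples
#' obs <- annual_series(c(104372, 99217), start = 2003)
#' prd <- annual_series(c(104176, 98859), start = 2003)
#' relative_errors(obs, prd)
#' @export
relative_errors <- function(observed, predicted) {
  observed <- as_annual_series(observed)
  predicted <- as_annual_series(predicted)
  check_aligned(observed, predicted)
  o <- as.numeric(observed); p <- as.numeric(predicted)
  if (any(o == 0))
    stop("relative error undefined: observed value of 0 at year ",
         series_years(observed)[which(o == 0)[1L]], call. = FALSE)
  out <- data.frame(year = series_years(observed),
                    observed = o, predicted = p,
                    abs_error = abs(o - p),
                    rel_error_pct = abs(o - p) / abs(o) * 100,
                    included = TRUE)
  class(out) <- c("error_report", "data.frame")
  out
}

#' Comprehensive (mean relative) error
#'
#' The single-number accuracy summary used here: the arithmetic mean of the
#' included per-year relative errors, in percent. For grey Verhulst fits
#' the first (anchor) year is exact by construction and is excluded from
#' the mean (`exclude_anchor = TRUE`, the convention behind the published
#' 9-term value 2.700); regression and combined fits average all years.
#'
#' @param report an `error_report` from [relative_errors()].
#' @param exclude_anchor drop the first year before averaging?
#' @param digits optional rounding of the returned percentage (default
#'   `NULL`, full precision).
#' @return the mean relative error in percent (scalar).
#' @export
comprehensive_error <- function(report, exclude_anchor = FALSE, digits = NULL) {
  if (!inherits(report, "error_report"))
    stop("'report' must come from relative_errors()", call. = FALSE)
  inc <- report$included
  if (isTRUE(exclude_anchor)) inc[1L] <- FALSE
  if (!any(inc)) stop("no years included in the comprehensive error",
                      call. = FALSE)
  out <- mean(report$rel_error_pct[inc])
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' @export
print.error_report <- function(x, digits = 3, ...) {
  shown <- x
  shown$predicted <- round(shown$predicted)
  shown$abs_error <- round(shown$abs_error)
  shown$rel_error_pct <- round(shown$rel_error_pct, digits)
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}
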