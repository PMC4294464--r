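#' Annual time series of counts or model values
#'
#' A light container for a year-indexed numeric vector: the observed death
#' toll, a fitted trajectory, or any other annual quantity. Years must be
#' consecutive calendar years; values must be finite.
#'
#' @param values numeric vector of observations.
#' @param years integer vector of calendar years, same length as `values`
#'   and strictly increasing by 1. Alternatively give `start`.
#' @param start first calendar year; used when `years` is missing.
#' @return An `annual_series` object: a numeric vector with a `years`
#'   attribute.
#' @examples
#' annual_series(c(109381, 104372, 99217), start = 2002)
#' @export
annual_series <- function(values, years = NULL, start = NULL) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("'values' must be non-empty", call. = FALSE)
  if (any(!is.finite(values))) stop("'values' must be finite", call. = FALSE)
  if (is.null(years)) {
    if (is.null(start)) stop("give either 'years' or 'start'", call. = FALSE)
    years <- seq.int(start, length.out = length(values))
  }
  years <- as.integer(years)
  if (length(years) != length(values))
    stop("'years' and 'values' must have the same length", call. = FALSE)
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("'years' must be consecutive calendar years (increasing by 1)",
         call. = FALSE)
  structure(values, years = years, class = "annual_series")
}

#' @export
as_annual_series <- function(x, ...) UseMethod("as_annual_series")

#' @export
as_annual_series.annual_series <- function(x, ...) x

#' @export
as_annual_series.data.frame <- function(x, value_col = NULL, ...) {
  if (!"year" %in% names(x)) stop("data frame needs a 'year' column", call. = FALSE)
  if (is.null(value_col)) {
    cand <- setdiff(names(x), "year")
    if (length(cand) != 1L)
      stop("ambiguous value column; give 'value_col'", call. = FALSE)
    value_col <- cand
  }
  annual_series(x[[value_col]], years = x[["year"]])
}

#' Years of an annual series
#' @param x an `annual_series`.
#' @return integer vector of calendar years.
#' @export
series_years <- function(x) {
  stopifnot(inherits(x, "annual_series"))
  attr(x, "years")
}

#' @export
print.annual_series <- function(x, ...) {
  cat("Annual series,", length(x), "years (",
      series_years(x)[1L], "-", series_years(x)[length(x)], ")\n", sep = "")
  v <- as.numeric(x)
  names(v) <- series_years(x)
  print(v, ...)
  invisible(x)
}

#' @export
as.data.frame.annual_series <- function(x, ..., value_name = "value") {
  out <- data.frame(year = series_years(x), value = as.numeric(x))
  names(out)[2L] <- value_name
  out
}

#' @export
`[.annual_series` <- function(x, i, ...) {
  yrs <- series_years(x)[i]
  v <- unclass(x)[i]
  if (length(yrs) > 1L && any(diff(yrs) != 1L)) return(v)  # gap: plain numeric
  annual_series(v, years = yrs)
}

# internal: check two series cover identical years
check_aligned <- function(a, b) {
  if (!identical(series_years(a), series_years(b)))
    stop("series are not aligned: years differ", call. = FALSE)
  invisible(TRUE)
}

#' Accumulated generating operation (AGO) and its inverse (IAGO)
#'
#' `ago()` forms the cumulative sum of a series; `iago()` forms first
#' differences with the first element retained, so that `ago(iago(x)) == x`
#' and `iago(ago(x)) == x` element-wise. These are the two sequence
#' operators of grey system modelling.
#'
#' @param x numeric vector or `annual_series`.
#' @return numeric vector of the same length (an `annual_series` in, an
#'   `annual_series` out).
#' @examples
#' iago(c(109381, 104372, 99217))  # 109381, -5009, -5155
#' ago(iago(1:5))                  # recovers 1:5
#' @export
ago <- function(x) {
  if (length(x) < 1L) stop("series too short", call. = FALSE)
  out <- cumsum(as.numeric(x))
  if (inherits(x, "annual_series")) out <- annual_series(out, series_years(x))
  out
}

#' @rdname ago
#' @export
iago <- function(x) {
  if (length(x) < 2L)
    stop("series too short: need at least 2 values for differencing",
         call. = FALSE)
  v <- as.numeric(x)
  out <- c(v[1L], diff(v))
  if (inherits(x, "annual_series")) out <- annual_series(out, series_years(x))
  out
}

#' Consecutive-neighbour mean sequence
#'
#' Returns the background value sequence z(k) = (x(k) + x(k-1)) / 2 for
#' k = 2..n, the regressor of the grey Verhulst least-squares system.
#'
#' @param x numeric vector or `annual_series` of length >= 2.
#' @return numeric vector of length `length(x) - 1`.
#' @examples
#' mean_sequence(c(2, 4))  # 3
#' @export
mean_sequence <- function(x) {
  if (length(x) < 2L)
    stop("series too short: need at least 2 values", call. = FALSE)
  v <- as.numeric(x)
  (v[-1L] + v[-length(v)]) / 2
}
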