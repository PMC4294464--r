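#' Simulate an annual series from logistic (Verhulst) dynamics
#'
#' Generates a deterministic trajectory from the continuous solution of the
#' whitened Verhulst equation,
#' \deqn{x(t) = \frac{a\,x_0}{\mu x_0 + (a - \mu x_0) e^{a t}},}
#' sampled at integer t = 0..n-1, optionally perturbed by multiplicative
#' relative noise. Multiplicative noise is the natural choice here because
#' relative error is the evaluation currency throughout the package.
#'
#' Defaults are the parameters estimated from the bundled Chinese
#' road-fatality series (a saturating decline from 109381 deaths in 2002).
#'
#' @param a development coefficient (1/year).
#' @param mu grey action quantity; saturation level is `a/mu`.
#' @param x0 value at t = 0 (> 0).
#' @param n number of years (>= 4).
#' @param first_year calendar year of t = 0.
#' @param noise relative noise level (>= 0); each value is multiplied by
#'   `1 + noise * N(0,1)`.
#' @param seed optional integer seed for reproducibility.
#' @return an [annual_series()].
#' @examples
#' simulate_logistic_series(noise = 0)           # the bundled-data trajectory
#' simulate_logistic_series(noise = 0.02, seed = 1)
#' @export
simulate_logistic_series <- function(a = 0.12238288, mu = 6.9e-7,
                                     x0 = 109381, n = 10,
                                     first_year = 2002,
                                     noise = 0, seed = NULL) {
  if (x0 <= 0) stop("'x0' must be positive", call. = FALSE)
  if (n < 4) stop("'n' must be at least 4", call. = FALSE)
  if (noise < 0) stop("'noise' must be nonnegative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t <- 0:(n - 1L)
  x <- a * x0 / (mu * x0 + (a - mu * x0) * exp(a * t))
  if (noise > 0) x <- x * (1 + noise * stats::rnorm(n))
  if (any(x <= 0))
    stop("noise level produced a nonpositive value; reduce 'noise'",
         call. = FALSE)
  annual_series(x, start = first_year)
}

#' Simulate a covariate panel and linear response
#'
#' Generates a six-covariate panel with smooth exponential trends (each
#' column grows at a fixed annual rate from a start level, emulating the
#' macro indicators of the bundled data: vehicle fleet, population, GDP,
#' freight, passengers, road mileage) and a response that is exactly
#' linear in the covariates plus optional Gaussian noise.
#'
#' Default start levels are the 2002 values of the bundled panel; default
#' growth rates are the observed 2002-2011 mean annual growth of each
#' indicator; default coefficients are the published regression equation's.
#'
#' @param intercept regression intercept.
#' @param slopes numeric vector of 6 slopes, in panel column order
#'   (vehicles, population, GDP, freight, passengers, road km).
#' @param starts numeric vector of 6 start levels (> 0).
#' @param growth numeric vector of 6 annual growth rates.
#' @param sigma response noise standard deviation (persons); 0 = exact.
#' @param n number of years (>= 8: 7 parameters need residual df).
#' @param first_year first calendar year.
#' @param seed optional integer seed.
#' @return list with `panel` (a [covariate_panel()]) and `response`
#'   (an [annual_series()]).
#' @examples
#' sim <- simulate_covariate_panel(sigma = 0, seed = 1)
#' coef(fatality_lm(sim$panel, sim$response))
#' @export
simulate_covariate_panel <- function(
    intercept = 779909.386,
    slopes = c(-9.153, -5.403, -0.147, 0.087, -0.028, 0.003),
    starts = c(2053.17, 128453, 120332.7, 1116324, 1475257, 1765222),
    growth = c(0.184, 0.0053, 0.164, 0.109, 0.093, 0.098),
    sigma = 0, n = 10, first_year = 2002, seed = NULL) {
  if (length(slopes) != 6L || length(starts) != 6L || length(growth) != 6L)
    stop("'slopes', 'starts' and 'growth' must each have length 6",
         call. = FALSE)
  if (any(starts <= 0)) stop("'starts' must be positive", call. = FALSE)
  if (sigma < 0) stop("'sigma' must be nonnegative", call. = FALSE)
  if (n < 8) stop("'n' must be at least 8 for a 7-parameter fit",
                  call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  t <- 0:(n - 1L)
  X <- mapply(function(s0, g) s0 * (1 + g)^t, starts, growth)
  colnames(X) <- names(.panel_cols)
  panel <- covariate_panel(cbind(data.frame(year = as.integer(first_year) + t),
                                 as.data.frame(X)))
  y <- intercept + drop(X %*% slopes)
  if (sigma > 0) y <- y + stats::rnorm(n, sd = sigma)
  list(panel = panel, response = annual_series(y, start = first_year))
}
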