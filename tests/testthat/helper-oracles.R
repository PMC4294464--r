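# Independent oracles used to cross-check the implementation.

# Shapley value by brute-force permutation enumeration: average marginal
# contribution of each member over all n! join orders. `value_fn` maps an
# integer index vector (possibly empty) to the coalition value.
shapley_permutation_oracle <- function(n, value_fn) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  shares <- numeric(n)
  all_orders <- perms(seq_len(n))
  for (ord in all_orders) {
    sofar <- integer(0)
    for (i in ord) {
      shares[i] <- shares[i] + value_fn(c(sofar, i)) - value_fn(sofar)
      sofar <- c(sofar, i)
    }
  }
  shares / length(all_orders)
}

# coalition value used throughout: mean of member errors, empty set -> 0
mean_value_fn <- function(errors) {
  function(idx) if (length(idx) == 0L) 0 else mean(errors[idx])
}

# Brute-force SSE grid search for the grey Verhulst 2-parameter problem:
# argmin over an (a, mu) grid of sum((x0 + a*z - mu*z^2)^2).
verhulst_grid_oracle <- function(series, a_range, mu_range, n_grid = 201L) {
  x1 <- as.numeric(series)
  x0 <- diff(x1)
  z <- (x1[-1] + x1[-length(x1)]) / 2
  a_grid <- seq(a_range[1], a_range[2], length.out = n_grid)
  mu_grid <- seq(mu_range[1], mu_range[2], length.out = n_grid)
  sse <- outer(a_grid, mu_grid, Vectorize(function(a, mu)
    sum((x0 + a * z - mu * z^2)^2)))
  ij <- arrayInd(which.min(sse), dim(sse))
  c(a = a_grid[ij[1]], mu = mu_grid[ij[2]],
    a_step = diff(a_grid[1:2]), mu_step = diff(mu_grid[1:2]))
}

# closed-form normal equations for a 2-covariate + intercept regression
ols2_closed_form <- function(x1, x2, y) {
  X <- cbind(1, x1, x2)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
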