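member_errs <- c(regression = 1.534, verhulst = 2.700)

test_that("coalition table takes subset means of member errors", {
  tab <- coalition_errors(member_errs)
  v <- stats::setNames(tab$value, tab$subset)
  expect_equal(unname(v["regression"]), 1.534)
  expect_equal(unname(v["verhulst"]), 2.700)
  expect_equal(unname(v["regression,verhulst"]), 2.117)
  expect_equal(nrow(tab), 3)  # 2^2 - 1 subsets

  # equal members: every coalition has the same value
  expect_true(all(coalition_errors(c(a = 4, b = 4))$value == 4))
  # three members: 2^3 - 1 rows, means as expected
  t3 <- coalition_errors(c(x = 1, y = 2, z = 3))
  v3 <- stats::setNames(t3$value, t3$subset)
  expect_equal(nrow(t3), 7)
  expect_equal(unname(v3["x,y,z"]), 2)
  expect_equal(unname(v3["y,z"]), 2.5)

  expect_error(coalition_errors(c(a = 1)), "at least 2")
  expect_error(coalition_errors(c(a = -1, b = 2)), "nonnegative")
})

test_that("Shapley shares reproduce the published allocation and sum to E", {
  shares <- shapley_shares(coalition_errors(member_errs))
  expect_equal(round(unname(shares["regression"]), 4), 0.4755)
  expect_equal(round(unname(shares["verhulst"]), 4), 1.6415)
  # efficiency at 1e-9 relative
  expect_equal(sum(shares), attr(shares, "total"), tolerance = 1e-9)
  expect_equal(attr(shares, "total"), 2.117)
})

test_that("shares obey symmetry and the n = 2 closed form", {
  sym <- shapley_shares(coalition_errors(c(a = 3.2, b = 3.2)))
  expect_equal(unname(sym["a"]), unname(sym["b"]))
  expect_equal(sum(sym), 3.2)

  set.seed(7)
  for (rep in 1:25) {
    e <- stats::setNames(stats::runif(2, 0, 10), c("m1", "m2"))
    shares <- shapley_shares(coalition_errors(e))
    E <- mean(e)
    expect_equal(unname(shares["m1"]), e[["m1"]] / 2 + (E - e[["m2"]]) / 2,
                 tolerance = 1e-12)
    expect_equal(unname(shares["m2"]), e[["m2"]] / 2 + (E - e[["m1"]]) / 2,
                 tolerance = 1e-12)
  }

  # permuting member labels permutes shares identically
  e <- c(p = 1.2, q = 4.5, r = 2.2)
  s1 <- shapley_shares(coalition_errors(e))
  s2 <- shapley_shares(coalition_errors(e[c("r", "p", "q")]))
  expect_equal(s1[names(s2)], s2, ignore_attr = TRUE)
})

test_that("shares agree with the permutation-enumeration oracle up to n = 5", {
  set.seed(19)
  for (n in 2:5) {
    for (rep in 1:3) {
      e <- stats::runif(n, 0, 8)
      names(e) <- paste0("m", seq_len(n))
      shares <- shapley_shares(coalition_errors(e))
      oracle <- shapley_permutation_oracle(n, mean_value_fn(e))
      expect_equal(unname(shares), oracle, tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_equal(sum(shares), mean(e), tolerance = 1e-9)
    }
  }
})

test_that("incomplete coalition tables are rejected with the missing subsets named", {
  tab <- coalition_errors(c(a = 1, b = 2, c = 3))
  broken <- tab[tab$subset != "a,c", ]
  attributes(broken)[c("labels", "n")] <- attributes(tab)[c("labels", "n")]
  class(broken) <- class(tab)
  expect_error(shapley_shares(broken), "missing subset.*a,c")
})

test_that("weights invert the shares, sum to 1, and flag negative members", {
  shares <- shapley_shares(coalition_errors(member_errs))
  w <- shapley_weights(shares)
  expect_equal(round(unname(w["regression"]), 4), 0.7754)
  expect_equal(round(unname(w["verhulst"]), 4), 0.2246)
  expect_equal(sum(w), 1, tolerance = 1e-12)

  # equal shares -> equal weights 1/n
  we <- shapley_weights(shapley_shares(coalition_errors(c(a = 2, b = 2))))
  expect_equal(unname(we), c(0.5, 0.5))

  # a very poor member earns a negative weight, reported not clamped
  bad <- shapley_shares(coalition_errors(c(good = 1, awful = 10)))
  expect_warning(wb <- shapley_weights(bad), "negative")
  expect_lt(wb[["awful"]], 0)
  expect_equal(sum(wb), 1, tolerance = 1e-12)

  # all-perfect members degenerate to equal weights with a warning
  perfect <- stats::setNames(c(0, 0), c("a", "b"))
  attr(perfect, "total") <- 0
  expect_warning(wp <- shapley_weights(perfect), "equal weights")
  expect_equal(unname(wp), c(0.5, 0.5))

  # weights sum to 1 for random member errors, n in 2..4
  set.seed(5)
  for (rep in 1:15) {
    n <- sample(2:4, 1)
    e <- stats::runif(n, 0.1, 6)
    names(e) <- paste0("m", seq_len(n))
    w <- suppressWarnings(shapley_weights(shapley_shares(coalition_errors(e))))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("combine_forecasts forms the year-wise weighted sum", {
  v <- annual_series(c(109381, 104176), start = 2002)
  r <- annual_series(c(110334, 105103), start = 2002)
  cf <- combine_forecasts(list(verhulst = v, regression = r),
                          c(verhulst = 0.7754, regression = 0.2246))
  expect_equal(round(as.numeric(cf$combined)), c(109595, 104384))

  # published hold-out members give the published combined forecast
  hm <- reference_holdout_predictions()
  cf2 <- combine_forecasts(
    list(verhulst = annual_series(hm$verhulst, years = hm$year),
         regression = annual_series(hm$regression, years = hm$year)),
    c(verhulst = 0.7754, regression = 0.2246))
  expect_equal(round(as.numeric(cf2$combined)), c(54437, 53762))

  # weight (1, 0) returns the first member exactly
  cf3 <- combine_forecasts(list(a = v, b = r), c(a = 1, b = 0))
  expect_equal(as.numeric(cf3$combined), as.numeric(v))

  expect_error(combine_forecasts(
    list(a = v, b = annual_series(1:2, start = 2005)), c(1, 0)),
    "align")
  expect_error(combine_forecasts(list(a = v, b = r), 1), "length")
})

test_that("shapley_combination maps weights per the published convention or consistently", {
  pub <- shapley_combination(member_errs, mapping = "published")
  expect_equal(round(unname(pub$weights["verhulst"]), 4), 0.7754)
  expect_equal(round(unname(pub$weights["regression"]), 4), 0.2246)
  con <- shapley_combination(member_errs, mapping = "consistent")
  expect_equal(round(unname(con$weights["regression"]), 4), 0.7754)
  expect_equal(round(unname(con$weights["verhulst"]), 4), 0.2246)
  expect_error(shapley_combination(c(a = 1, b = 2, c = 3),
                                   mapping = "published"),
               "exactly 2")
})
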