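test_that("bootstrap is deterministic given the seed and degenerates with zero sds", {
  spec <- bootstrap_spec(n_reps = 2000, seed = 7)
  fn <- function(w0, w1) cbind(weight_diff = w1 - w0)
  b1 <- bootstrap_outcomes(spec, fn, vectorized = TRUE)
  b2 <- bootstrap_outcomes(spec, fn, vectorized = TRUE)
  expect_identical(b1, b2)
  b3 <- bootstrap_outcomes(bootstrap_spec(n_reps = 2000, seed = 8), fn,
                           vectorized = TRUE)
  expect_false(identical(b1$ci_low, b3$ci_low))

  degen <- bootstrap_spec(n_reps = 500, seed = 7,
                          sds = c(conventional = 0, welfare_friendly = 0))
  bd <- bootstrap_outcomes(degen, fn, vectorized = TRUE)
  expect_equal(bd$ci_low, bd$point)
  expect_equal(bd$ci_high, bd$point)
  expect_equal(bd$point, 103.4 - 97.1)
})

test_that("scalar and vectorized outcome functions agree", {
  spec <- bootstrap_spec(n_reps = 300, seed = 9)
  fn_vec <- function(w0, w1) cbind(a = w1 - w0, b = w0 + w1)
  fn_sca <- function(w0, w1) c(a = w1 - w0, b = w0 + w1)
  expect_equal(bootstrap_outcomes(spec, fn_vec, vectorized = TRUE),
               bootstrap_outcomes(spec, fn_sca, vectorized = FALSE))
})

test_that("percentile deviations of a linear outcome match the analytic normal quantiles", {
  spec <- bootstrap_spec(n_reps = 1e5, seed = 10)
  b <- bootstrap_outcomes(spec, function(w0, w1) cbind(weight_diff = w1 - w0),
                          vectorized = TRUE)
  half_analytic <- qnorm(0.95) *
    sqrt(spec$sds[[1]]^2 / spec$sample_sizes[[1]] +
         spec$sds[[2]]^2 / spec$sample_sizes[[2]])
  expect_lt(abs((b$ci_high - b$point) / half_analytic - 1), 0.01)
  expect_lt(abs((b$point - b$ci_low) / half_analytic - 1), 0.01)
})

test_that("widening the percentile pair widens the interval; 2.5/97.5 matches 1.96-theory", {
  fn <- function(w0, w1) cbind(weight_diff = w1 - w0)
  narrow <- bootstrap_outcomes(bootstrap_spec(n_reps = 2e4, seed = 11),
                               fn, vectorized = TRUE)
  wide <- bootstrap_outcomes(
    bootstrap_spec(n_reps = 2e4, seed = 11,
                   lower_percentile = 2.5, upper_percentile = 97.5),
    fn, vectorized = TRUE)
  expect_lt(narrow$ci_high, wide$ci_high)
  expect_gt(narrow$ci_low, wide$ci_low)

  spec <- bootstrap_spec(n_reps = 2e4)
  half_196 <- qnorm(0.975) *
    sqrt(spec$sds[[1]]^2 / 75 + spec$sds[[2]]^2 / 77)
  expect_lt(abs((wide$ci_high - wide$point) / half_196 - 1), 0.03)
})

test_that("subsample stability: 1e5 vs 1e6 replicates agree within 0.5% on the interval", {
  fn <- function(w0, w1) cbind(weight_diff = w1 - w0)
  small <- bootstrap_outcomes(bootstrap_spec(n_reps = 1e5, seed = 12), fn,
                              vectorized = TRUE)
  large <- bootstrap_outcomes(bootstrap_spec(n_reps = 1e6, seed = 12), fn,
                              vectorized = TRUE)
  expect_lt(abs(small$ci_high / large$ci_high - 1), 0.005)
  expect_lt(abs(small$ci_low / large$ci_low - 1), 0.005)
})

test_that("non-finite outcomes are excluded, and more than 1% is an error", {
  spec <- bootstrap_spec(n_reps = 1000, seed = 13)
  # a rare non-finite outcome: fails only far in the upper tail
  rare <- function(w0, w1) {
    out <- (w1 - w0)
    out[out > 9.2] <- NaN   # ~ 1.45 sd above the mean difference
    cbind(weight_diff = out)
  }
  expect_error(bootstrap_outcomes(spec, rare, vectorized = TRUE),
               "non-finite")
  almost_never <- function(w0, w1) {
    out <- (w1 - w0)
    out[out > 13] <- NaN
    cbind(weight_diff = out)
  }
  b <- bootstrap_outcomes(spec, almost_never, vectorized = TRUE)
  expect_lte(b$n_reps_used, 1000)

  expect_error(bootstrap_spec(lower_percentile = 95, upper_percentile = 5),
               "percentile")
  expect_error(bootstrap_outcomes(spec, function(w0, w1) w1 - w0),
               "named")
})

test_that("farm outcome function feeds the bootstrap with the published farm quantities", {
  fn <- farm_outcome_fn(12000, 2.2, c(conventional = 0.2045,
                                      welfare_friendly = 0.0670))
  point <- fn(97.1, 103.4)
  expect_equal(unname(point[1, "quantity_diff"]), 12000 * 6.3)
  expect_equal(unname(point[1, "profit_diff"]),
               (2.2 - 0.067) * 12000 * 103.4 - (2.2 - 0.2045) * 12000 * 97.1)
  b <- bootstrap_outcomes(bootstrap_spec(n_reps = 5000, seed = 14), fn,
                          vectorized = TRUE)
  pd <- b[b$outcome == "profit_diff", ]
  expect_true(pd$ci_low < pd$point && pd$point < pd$ci_high)
})
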