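test_that("calibration passes through the observation and recovers the elasticities", {
  m <- market_model()
  expect_equal(predict(m$demand, m$P0), m$Q0, tolerance = 1e-12)
  expect_equal(predict(m$supply, m$P0), m$Q0, tolerance = 1e-12)
  # elasticity recovered from the calibrated slope: slope * P0 / Q0
  expect_equal(m$demand$slope * m$P0 / m$Q0, m$epsilon_d, tolerance = 1e-12)
  expect_equal(m$supply$slope * m$P0 / m$Q0, m$epsilon_s, tolerance = 1e-12)

  # published equation coefficients (Q in 1,000 t, P in $ per 1,000 t):
  # intercepts match to < 0.1%; slopes divided by 1e6
  expect_lt(abs(m$demand$intercept / 19664.182 - 1), 1e-3)
  expect_lt(abs(m$supply$intercept / 5518.525 - 1), 1e-3)
  expect_equal(m$demand$slope / 1e6, -0.005, tolerance = 0.1)

  expect_error(market_model(epsilon_d = 0.5), "negative")
  expect_error(market_model(epsilon_s = -0.4), "positive")
  expect_error(market_model(P0 = 0), "positive")
  expect_error(linear_curve(100, 2, "demand"), "slope")
})

test_that("supply shift is a parallel shift of the inverse curve", {
  m <- market_model()
  s1 <- shift_supply(m$supply, 0.1375)
  expect_equal(s1$slope, m$supply$slope)
  expect_equal(s1$intercept, m$supply$intercept + m$supply$slope * 0.1375)
  # published shifted intercept, in 1,000 t units
  expect_lt(abs(s1$intercept / 5764.72 - 1), 1e-3)

  # zero shift: identical curve; two half shifts equal one full shift
  expect_equal(shift_supply(m$supply, 0), m$supply)
  expect_equal(shift_supply(shift_supply(m$supply, 0.07), 0.0675),
               shift_supply(m$supply, 0.1375))
  expect_error(shift_supply(m$demand, 0.1), "supply")
})

test_that("equilibrium solver recovers the observation and rejects non-crossing curves", {
  m <- market_model()
  eq <- solve_equilibrium(m$demand, m$supply)
  expect_equal(eq$P, m$P0, tolerance = 1e-9)
  expect_equal(eq$Q, m$Q0, tolerance = 1e-9)
  expect_error(solve_equilibrium(m$supply, m$demand), "demand-side|demand")
})

test_that("price drop equals the closed-form pass-through of the cost saving", {
  m <- market_model()
  eq0 <- solve_equilibrium(m$demand, m$supply)
  eq1 <- solve_equilibrium(m$demand, shift_supply(m$supply, 0.1375))
  rho <- pass_through(m$epsilon_d, m$epsilon_s)
  expect_equal(eq1$P - eq0$P, -0.1375 * rho, tolerance = 1e-9)
  expect_equal(round(eq0$P - eq1$P, 3), 0.038)

  expect_equal(pass_through(-1.078, 0.417), 0.417 / 1.495, tolerance = 1e-12)
  expect_equal(pass_through(-1.078, 0.417), 0.2789, tolerance = 5e-4)
  expect_equal(pass_through(-0.7, 0.7), 0.5)
  expect_equal(pass_through(-1, 1e-12), 0, tolerance = 1e-9)
})

test_that("consumer surplus: trapezoid change, triangle level, and their identity", {
  m <- market_model()
  pc <- policy_comparison(m)
  # trapezoid equals quadrature of the inverse linear demand between prices
  inv_quantity <- function(p) predict(m$demand, p)
  quad <- stats::integrate(inv_quantity, lower = pc$P1, upper = pc$P0,
                           rel.tol = 1e-10)$value
  expect_equal(pc$delta_CS, quad, tolerance = 1e-6)
  # level difference equals the trapezoid change for linear demand
  expect_equal(pc$cs1 - pc$cs0, pc$delta_CS, tolerance = 1e-6)
  expect_equal(consumer_surplus_change(0, 100, 100), 0)
  # published baseline level ~ 9,668 million $US
  expect_lt(abs(pc$cs0 / 9668 - 1), 0.005)
  expect_error(consumer_surplus_level(m$demand, 10, 100), "choke")
})

test_that("producer surplus change is the profit difference and warns on negative margins", {
  expect_equal(producer_surplus_change(2, 100, 0.5, 2, 100, 0.5), 0)
  expect_equal(producer_surplus_change(2.2026, 9463.032, 0.2045,
                                       2.2026, 9463.032, 0.0670),
               0.1375 * 9463.032)
  expect_warning(producer_surplus_change(1, 10, 2, 1, 10, 0.5), "margin")
})

test_that("policy comparison reproduces the published market headline", {
  pc <- policy_comparison()
  expect_equal(round(pc$delta_P, 3), -0.038)
  expect_lt(abs(pc$delta_Q / 177.54 - 1), 0.005)
  expect_lt(abs(pc$delta_CS / 366 - 1), 0.005)
  expect_lt(abs(pc$delta_PS / 1311 - 1), 0.005)
  expect_lt(abs(pc$delta_W / 1676.7 - 1), 0.005)
  expect_lt(abs(pc$delta_revenue / 21.5 - 1), 0.01)
  # welfare additivity is exact by construction
  expect_identical(pc$delta_W, pc$delta_CS + pc$delta_PS)
  # signs: cost saving lowers price, raises quantity
  expect_lt(pc$delta_P, 0)
  expect_gt(pc$delta_Q, 0)
})

test_that("zero cost shift is the identity policy", {
  pc <- policy_comparison(delta_C = 0)
  expect_equal(pc$delta_P, 0, tolerance = 1e-12)
  expect_equal(pc$delta_Q, 0, tolerance = 1e-9)
  expect_equal(pc$delta_CS, 0, tolerance = 1e-9)
  expect_equal(pc$delta_PS, 0, tolerance = 1e-6)
  expect_equal(pc$delta_W, 0, tolerance = 1e-6)
})

test_that("geometric producer-surplus alternative is close to, but distinct from, the profit accounting", {
  profit <- policy_comparison(ps_method = "profit")
  geom <- policy_comparison(ps_method = "geometric")
  # same pipeline otherwise
  expect_equal(geom$delta_P, profit$delta_P)
  # geometric area: (delta_C + delta_P) * (Q0 + Q1) / 2
  expect_equal(geom$delta_PS,
               (0.1375 + geom$delta_P) * (geom$Q0 + geom$Q1) / 2)
  expect_false(isTRUE(all.equal(geom$delta_PS, profit$delta_PS)))
})

test_that("sensitivity grid composes policy comparisons and reports extremes", {
  g <- sensitivity_grid()
  expect_equal(nrow(g), 9L)
  expect_identical(g$delta_W, g$delta_CS + g$delta_PS)

  # single-cell grid at the averages equals the headline comparison exactly
  single <- sensitivity_grid(-1.078, 0.417)
  pc <- policy_comparison()
  expect_equal(single$delta_W, pc$delta_W)
  expect_equal(single$delta_P, pc$delta_P)

  s <- attr(g, "summary")
  expect_equal(s["delta_W", "min"], min(g$delta_W))
  expect_equal(s["delta_CS", "max"], max(g$delta_CS))
  expect_error(sensitivity_grid(numeric(0)), "non-empty")
})

test_that("grid monotonicity: |dP| rises with supply elasticity, falls with |demand| elasticity; dCS rises with supply elasticity", {
  g <- sensitivity_grid(demand_elasticities = c(-0.5, -1.078, -2.75),
                        supply_elasticities = c(0.2, 0.417, 0.6))
  for (ed in unique(g$epsilon_d)) {
    sub <- g[g$epsilon_d == ed, ]
    sub <- sub[order(sub$epsilon_s), ]
    expect_true(all(diff(abs(sub$delta_P)) > 0))
    expect_true(all(diff(sub$delta_CS) > 0))
  }
  for (es in unique(g$epsilon_s)) {
    sub <- g[g$epsilon_s == es, ]
    sub <- sub[order(abs(sub$epsilon_d)), ]
    expect_true(all(diff(abs(sub$delta_P)) < 0))
  }
})
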