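#' Linear demand or supply curve
#'
#' Quantity form `Q = intercept + slope * P` with quantity in million kg
#' (equivalently thousand tonnes) per year and price in $US per kg. Demand
#' curves slope down, supply curves slope up.
#'
#' @param intercept million kg.
#' @param slope million kg per ($US/kg).
#' @param side `"demand"` or `"supply"`.
#' @return an object of class `linear_curve`.
#' @export
linear_curve <- function(intercept, slope, side = c("demand", "supply")) {
  side <- match.arg(side)
  if (side == "demand" && slope >= 0) {
    stop("demand slope must be negative", call. = FALSE)
  }
  if (side == "supply" && slope <= 0) {
    stop("supply slope must be positive", call. = FALSE)
  }
  structure(list(intercept = intercept, slope = slope, side = side),
            class = "linear_curve")
}

#' @export
print.linear_curve <- function(x, ...) {
  # display in the published units: Q in 1,000 tonnes, P in $ per 1,000
  # tonnes, so the slope is divided by 1e6
  cat(sprintf("Q_%s = %s %s %.5f P   (Q in 1,000 t; P in $ per 1,000 t)\n",
              substr(x$side, 1, 1),
              formatC(x$intercept, format = "f", digits = 3, big.mark = ","),
              if (x$slope < 0) "-" else "+", abs(x$slope) / 1e6))
  invisible(x)
}

#' Quantity on a linear curve at given prices
#'
#' @param object a [linear_curve()].
#' @param price $US per kg (vectorized).
#' @param ... unused.
#' @return quantities in million kg.
#' @export
predict.linear_curve <- function(object, price, ...) {
  object$intercept + object$slope * price
}

#' Calibrate a linear partial-equilibrium model of the pork market
#'
#' Backs out linear demand and supply curves from one observed equilibrium
#' (P0, Q0) and point elasticities, assuming a linear functional form:
#' `slope = elasticity * Q0 / P0` on each side and intercepts such that both
#' curves pass through the observation. Defaults are the US pork market
#' figures used in the published analysis: Q0 = 9,463.032 million kg/yr,
#' P0 = 2.2026 $/kg (reconstructed so the published equilibrium tables
#' reproduce; the rounded $2.2 may be supplied instead), demand elasticity
#' -1.078 and supply elasticity 0.417 (literature averages).
#'
#' @param Q0 observed annual quantity, million kg.
#' @param P0 observed price, $US per kg.
#' @param epsilon_d demand elasticity (< 0).
#' @param epsilon_s supply elasticity (> 0).
#' @return an object of class `market_model`: a list with `demand` and
#'   `supply` [linear_curve()]s and the calibration inputs.
#' @examples
#' m <- market_model()
#' coef(m)
#' solve_equilibrium(m$demand, m$supply)  # recovers (P0, Q0)
#' @export
market_model <- function(Q0 = 9463.032, P0 = 2.2026,
                         epsilon_d = -1.078, epsilon_s = 0.417) {
  .check_pos(Q0, "Q0")
  .check_pos(P0, "P0")
  if (!is.numeric(epsilon_d) || epsilon_d >= 0) {
    stop("demand elasticity must be negative", call. = FALSE)
  }
  if (!is.numeric(epsilon_s) || epsilon_s <= 0) {
    stop("supply elasticity must be positive", call. = FALSE)
  }
  slope_d <- epsilon_d * Q0 / P0
  slope_s <- epsilon_s * Q0 / P0
  structure(list(
    demand = linear_curve(Q0 - slope_d * P0, slope_d, "demand"),
    supply = linear_curve(Q0 - slope_s * P0, slope_s, "supply"),
    Q0 = Q0, P0 = P0, epsilon_d = epsilon_d, epsilon_s = epsilon_s),
    class = "market_model")
}

#' @export
print.market_model <- function(x, ...) {
  cat("Calibrated linear market model\n")
  cat(sprintf("  observation: Q0 = %s million kg/yr at P0 = %.4f $/kg\n",
              formatC(x$Q0, format = "f", digits = 3, big.mark = ","), x$P0))
  cat(sprintf("  elasticities: demand %.3f, supply %.3f\n",
              x$epsilon_d, x$epsilon_s))
  cat("  ")
  print(x$demand)
  cat("  ")
  print(x$supply)
  invisible(x)
}

#' @export
coef.market_model <- function(object, ...) {
  c(demand_intercept = object$demand$intercept,
    demand_slope = object$demand$slope,
    supply_intercept = object$supply$intercept,
    supply_slope = object$supply$slope)
}

#' @export
predict.market_model <- function(object, price, side = c("demand", "supply"),
                                 ...) {
  side <- match.arg(side)
  predict(object[[side]], price)
}

#' Shift a supply curve by a per-unit cost change
#'
#' A marginal-cost reduction of `delta_C` $/kg moves the inverse supply curve
#' down by `delta_C`; in quantity form the intercept rises by
#' `slope * delta_C` while the slope is unchanged (a parallel shift).
#'
#' @param supply a supply-side [linear_curve()].
#' @param delta_C per-kg cost reduction, $US per kg.
#' @return the shifted supply curve.
#' @export
shift_supply <- function(supply, delta_C) {
  if (!inherits(supply, "linear_curve") || supply$side != "supply") {
    stop("'supply' must be a supply-side linear_curve", call. = FALSE)
  }
  linear_curve(supply$intercept + supply$slope * delta_C, supply$slope,
               "supply")
}

#' Solve the market equilibrium of two linear curves
#'
#' @param demand,supply [linear_curve()]s of the respective sides.
#' @return a list with `P` ($US/kg) and `Q` (million kg).
#' @export
solve_equilibrium <- function(demand, supply) {
  if (!inherits(demand, "linear_curve") || demand$side != "demand" ||
      !inherits(supply, "linear_curve") || supply$side != "supply") {
    stop("need one demand-side and one supply-side linear_curve",
         call. = FALSE)
  }
  denom <- supply$slope - demand$slope
  if (denom <= 0) stop("curves do not cross: no equilibrium", call. = FALSE)
  P <- (demand$intercept - supply$intercept) / denom
  Q <- predict(demand, P)
  stopifnot(abs(Q - predict(supply, P)) <= 1e-9 * max(1, abs(Q)))
  list(P = P, Q = Q)
}

#' Cost pass-through rate of linear curves
#'
#' Fraction of a per-unit cost change transmitted to the equilibrium price:
#' `epsilon_s / (epsilon_s + |epsilon_d|)`. This is the closed form the
#' equilibrium solver must agree with.
#'
#' @inheritParams market_model
#' @return a proportion in (0, 1).
#' @export
pass_through <- function(epsilon_d, epsilon_s) {
  if (epsilon_d >= 0 || epsilon_s < 0) {
    stop("need epsilon_d < 0 and epsilon_s >= 0", call. = FALSE)
  }
  epsilon_s / (epsilon_s + abs(epsilon_d))
}

#' Change in consumer surplus between two prices on a linear demand curve
#'
#' Trapezoid rule, exact for linear demand: `-delta_P * (Q0 + Q1) / 2`.
#'
#' @param delta_P price change, $US per kg (negative for a price drop).
#' @param Q0,Q1 quantities before and after, million kg.
#' @return million $US per year.
#' @export
consumer_surplus_change <- function(delta_P, Q0, Q1) {
  .check_pos(c(Q0, Q1), "quantities")
  -delta_P * (Q0 + Q1) / 2
}

#' Consumer surplus level under linear demand
#'
#' Triangle between the demand curve and the price line up to the choke
#' price `-intercept/slope`: `(choke - P) * Q / 2`.
#'
#' @param demand a demand-side [linear_curve()].
#' @param P price, $US per kg; must be below the choke price.
#' @param Q quantity, million kg.
#' @return million $US per year.
#' @export
consumer_surplus_level <- function(demand, P, Q) {
  if (!inherits(demand, "linear_curve") || demand$side != "demand") {
    stop("'demand' must be a demand-side linear_curve", call. = FALSE)
  }
  choke <- -demand$intercept / demand$slope
  if (P >= choke) stop("price at or above the choke price", call. = FALSE)
  (choke - P) * Q / 2
}

#' Change in producer surplus as sector profit excluding common costs
#'
#' `(P1 - c1) * Q1 - (P0 - c0) * Q0`, the published accounting convention
#' (profit margin times quantity, common costs cancelling between regimes).
#'
#' @param P0,Q0,c0 baseline price ($/kg), quantity (million kg) and unit cost
#'   ($/kg).
#' @param P1,Q1,c1 counterfactual price, quantity and unit cost.
#' @return million $US per year.
#' @export
producer_surplus_change <- function(P0, Q0, c0, P1, Q1, c1) {
  if ((P0 - c0) <= 0 || (P1 - c1) <= 0) {
    warning("non-positive profit margin; surplus change still computed")
  }
  (P1 - c1) * Q1 - (P0 - c0) * Q0
}

#' Full market policy comparison: welfare-friendly vs conventional rearing
#'
#' Composes the pipeline calibrate -> shift supply -> solve equilibrium ->
#' surplus and profit accounting. Consumer surplus change uses the trapezoid
#' under the calibrated linear demand; producer surplus change is the sector
#' profit difference excluding common costs (the published convention), with
#' the geometric area above the supply curve available via `ps_method`.
#'
#' @param model a [market_model()]; built from `...` defaults if missing.
#' @param c0 conventional production cost, $US per kg.
#' @param delta_C per-kg cost reduction of welfare-friendly rearing; the
#'   welfare-friendly unit cost is `c0 - delta_C`.
#' @param ps_method `"profit"` (default) or `"geometric"` for the producer
#'   surplus change.
#' @return an object of class `policy_comparison`: baseline and
#'   counterfactual price/quantity, their changes, consumer-surplus levels
#'   and change, per-regime revenue/cost/profit (million $US), the
#'   producer-surplus and total-welfare changes, and the pass-through rate.
#'   `delta_W = delta_CS + delta_PS` holds by construction.
#' @examples
#' pc <- policy_comparison()
#' round(pc$delta_P, 3)   # -0.038 $/kg
#' round(pc$delta_PS)     # about 1,311 million $US
#' @export
policy_comparison <- function(model = market_model(), c0 = 0.2045,
                              delta_C = 0.1375,
                              ps_method = c("profit", "geometric")) {
  ps_method <- match.arg(ps_method)
  if (!inherits(model, "market_model")) {
    stop("'model' must be a market_model", call. = FALSE)
  }
  .check_nonneg(c0, "c0")
  if (delta_C > c0) stop("delta_C exceeds the baseline unit cost",
                         call. = FALSE)
  c1 <- c0 - delta_C
  base <- solve_equilibrium(model$demand, model$supply)
  shifted <- shift_supply(model$supply, delta_C)
  new <- solve_equilibrium(model$demand, shifted)

  P0 <- base$P; Q0 <- base$Q; P1 <- new$P; Q1 <- new$Q
  delta_P <- P1 - P0
  delta_Q <- Q1 - Q0
  cs0 <- consumer_surplus_level(model$demand, P0, Q0)
  cs1 <- consumer_surplus_level(model$demand, P1, Q1)
  delta_CS <- consumer_surplus_change(delta_P, Q0, Q1)

  revenue0 <- P0 * Q0; revenue1 <- P1 * Q1
  cost0 <- c0 * Q0; cost1 <- c1 * Q1
  profit0 <- revenue0 - cost0; profit1 <- revenue1 - cost1
  delta_PS <- if (ps_method == "profit") {
    producer_surplus_change(P0, Q0, c0, P1, Q1, c1)
  } else {
    # area between the producer price net of the shift and the old producer
    # price: the effective producer price rises by delta_C + delta_P
    (delta_C + delta_P) * (Q0 + Q1) / 2
  }

  structure(list(P0 = P0, P1 = P1, delta_P = delta_P,
                 Q0 = Q0, Q1 = Q1, delta_Q = delta_Q,
                 c0 = c0, c1 = c1, delta_C = delta_C,
                 cs0 = cs0, cs1 = cs1, delta_CS = delta_CS,
                 revenue0 = revenue0, revenue1 = revenue1,
                 delta_revenue = revenue1 - revenue0,
                 cost0 = cost0, cost1 = cost1, delta_cost = cost1 - cost0,
                 profit0 = profit0, profit1 = profit1,
                 delta_PS = delta_PS,
                 delta_W = delta_CS + delta_PS,
                 pass_through = pass_through(model$epsilon_d,
                                             model$epsilon_s),
                 ps_method = ps_method, model = model),
            class = "policy_comparison")
}

#' @export
print.policy_comparison <- function(x, ...) {
  fmt <- function(v, d = 1) formatC(v, format = "f", digits = d,
                                    big.mark = ",")
  cat("US market equilibrium comparison (welfare-friendly vs conventional)\n")
  cat(sprintf("  price ($/kg):            %.3f -> %.3f  (%+.3f)\n",
              x$P0, x$P1, x$delta_P))
  cat(sprintf("  quantity (million kg):   %s -> %s  (%+s)\n",
              fmt(x$Q0), fmt(x$Q1), fmt(x$delta_Q, 2)))
  cat(sprintf("  revenue (million $US):   %s -> %s  (%+s)\n",
              fmt(x$revenue0), fmt(x$revenue1), fmt(x$delta_revenue)))
  cat(sprintf("  cost (million $US):      %s -> %s  (%+s)\n",
              fmt(x$cost0), fmt(x$cost1), fmt(x$delta_cost)))
  cat(sprintf("  profit (million $US):    %s -> %s  (%+s)\n",
              fmt(x$profit0), fmt(x$profit1), fmt(x$delta_PS)))
  cat(sprintf("  consumer surplus (M$US): %s -> %s  (%+s)\n",
              fmt(x$cs0), fmt(x$cs1), fmt(x$delta_CS)))
  cat(sprintf("  total welfare change:    %s million $US (%.4f billion)\n",
              fmt(x$delta_W), x$delta_W / 1000))
  invisible(x)
}

#' @rdname policy_comparison
#' @param comparison a `policy_comparison`.
#' @return `market_table` returns a data.frame in the published two-regime +
#'   difference layout.
#' @export
market_table <- function(comparison) {
  x <- comparison
  data.frame(
    item = c("price_usd_per_kg", "quantity_million_kg",
             "revenue_million_usd", "cost_million_usd",
             "profit_million_usd", "consumer_surplus_million_usd"),
    conventional = c(x$P0, x$Q0, x$revenue0, x$cost0, x$profit0, x$cs0),
    welfare_friendly = c(x$P1, x$Q1, x$revenue1, x$cost1, x$profit1, x$cs1),
    difference = c(x$delta_P, x$delta_Q, x$delta_revenue, x$delta_cost,
                   x$delta_PS, x$delta_CS),
    stringsAsFactors = FALSE)
}

#' Elasticity sensitivity grid of the policy comparison
#'
#' Runs [policy_comparison()] for every (demand, supply) elasticity pair on a
#' grid. Defaults are the literature min/average/max values, with the
#' unrounded averages (-1.078, 0.417) used throughout (the published grid is
#' consistent with the unrounded values in every "average" row and column).
#'
#' @param demand_elasticities numeric vector of demand elasticities (< 0).
#' @param supply_elasticities numeric vector of supply elasticities (> 0).
#' @param Q0,P0 market observation, as in [market_model()].
#' @param c0,delta_C unit cost and cost shift, as in [policy_comparison()].
#' @return an object of class `sensitivity_grid`: a data.frame with one row
#'   per pair (`epsilon_d`, `epsilon_s`, `delta_P`, `delta_Q`, `delta_CS`,
#'   `delta_PS`, `delta_W`, money in million $US) and a `summary` attribute
#'   with the min/max of the surplus changes over the grid.
#' @examples
#' g <- sensitivity_grid()
#' attr(g, "summary")["delta_W", "min"] / 1000  # about 1.48 billion $US
#' @export
sensitivity_grid <- function(demand_elasticities = c(-0.5, -1.078, -2.75),
                             supply_elasticities = c(0.2, 0.417, 0.6),
                             Q0 = 9463.032, P0 = 2.2026,
                             c0 = 0.2045, delta_C = 0.1375) {
  if (length(demand_elasticities) == 0 || length(supply_elasticities) == 0) {
    stop("elasticity lists must be non-empty", call. = FALSE)
  }
  rows <- list()
  for (ed in demand_elasticities) {
    for (es in supply_elasticities) {
      pc <- policy_comparison(market_model(Q0, P0, ed, es), c0, delta_C)
      rows[[length(rows) + 1L]] <- data.frame(
        epsilon_d = ed, epsilon_s = es,
        delta_P = pc$delta_P, delta_Q = pc$delta_Q,
        delta_CS = pc$delta_CS, delta_PS = pc$delta_PS,
        delta_W = pc$delta_W)
    }
  }
  grid <- do.call(rbind, rows)
  smry <- t(vapply(c("delta_CS", "delta_PS", "delta_W"),
                   function(v) c(min = min(grid[[v]]), max = max(grid[[v]])),
                   numeric(2)))
  structure(grid, summary = smry, class = c("sensitivity_grid", "data.frame"))
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat("Elasticity sensitivity grid (billion $US per year)\n")
  for (v in c("delta_PS", "delta_CS", "delta_W")) {
    m <- matrix(x[[v]] / 1000, nrow = length(unique(x$epsilon_d)),
                byrow = TRUE,
                dimnames = list(paste("eps_d", unique(x$epsilon_d)),
                                paste("eps_s", unique(x$epsilon_s))))
    cat("\n", v, ":\n", sep = "")
    print(round(m, 4))
  }
  s <- attr(x, "summary")
  cat(sprintf("\nranges (billion $US): PS [%.4f, %.4f], CS [%.4f, %.4f], W [%.4f, %.4f]\n",
              s["delta_PS", "min"] / 1000, s["delta_PS", "max"] / 1000,
              s["delta_CS", "min"] / 1000, s["delta_CS", "max"] / 1000,
              s["delta_W", "min"] / 1000, s["delta_W", "max"] / 1000))
  invisible(x)
}
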