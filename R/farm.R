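#' Fixed-price farm scenario
#'
#' Annual production plan of a single farm selling at an exogenous meat
#' price: a number of slaughtered pigs, their mean slaughter weight, the
#' price received and the per-kg production cost (excluding common costs).
#' The default head count (12,000) and price ($2.2/kg) are the published
#' small-farm scenario.
#'
#' @param heads_slaughtered pigs slaughtered per year (>= 0).
#' @param mean_slaughter_weight kg per pig.
#' @param meat_price $US per kg; held fixed across regimes.
#' @param cost_per_kg $US per kg production cost.
#' @return an object of class `farm_scenario`.
#' @export
farm_scenario <- function(heads_slaughtered = 12000,
                          mean_slaughter_weight,
                          meat_price = 2.2,
                          cost_per_kg) {
  .check_nonneg(heads_slaughtered, "heads_slaughtered")
  .check_pos(mean_slaughter_weight, "mean_slaughter_weight")
  .check_pos(meat_price, "meat_price")
  .check_nonneg(cost_per_kg, "cost_per_kg")
  structure(list(heads_slaughtered = heads_slaughtered,
                 mean_slaughter_weight = mean_slaughter_weight,
                 meat_price = meat_price,
                 cost_per_kg = cost_per_kg),
            class = "farm_scenario")
}

#' Annual farm outcome under a fixed-price scenario
#'
#' Quantity = heads x mean weight; revenue = quantity x price; cost =
#' quantity x per-kg cost; profit = revenue - cost. All values exclude
#' common costs (feed, housing) that are identical across regimes.
#'
#' @param scenario a [farm_scenario()].
#' @return an object of class `farm_outcome`: a list with `quantity_kg`,
#'   `revenue`, `cost`, `profit`, plus the scenario for consistency checks.
#' @examples
#' conv <- farm_outcome(farm_scenario(12000, 97.1, 2.2, 0.2045))
#' round(conv$cost)  # about 238,200 $US
#' @export
farm_outcome <- function(scenario) {
  if (!inherits(scenario, "farm_scenario")) {
    stop("'scenario' must be a farm_scenario", call. = FALSE)
  }
  q <- scenario$heads_slaughtered * scenario$mean_slaughter_weight
  revenue <- q * scenario$meat_price
  cost <- q * scenario$cost_per_kg
  structure(list(quantity_kg = q, revenue = revenue, cost = cost,
                 profit = revenue - cost, scenario = scenario),
            class = "farm_outcome")
}

#' @export
print.farm_outcome <- function(x, ...) {
  cat(sprintf("heads %s, quantity %.0f kg, revenue $%.0f, cost $%.0f, profit $%.0f\n",
              format(x$scenario$heads_slaughtered, big.mark = ","),
              x$quantity_kg, x$revenue, x$cost, x$profit))
  invisible(x)
}

#' Contrast two farm outcomes (welfare-friendly minus conventional)
#'
#' Element-wise differences in quantity, revenue, cost and profit between
#' two [farm_outcome()]s computed at the same head count and meat price.
#'
#' @param conventional,welfare farm outcomes for the two regimes.
#' @return an object of class `farm_comparison`: a list with the two
#'   outcomes and a `difference` component.
#' @export
compare_farm <- function(conventional, welfare) {
  for (o in list(conventional, welfare)) {
    if (!inherits(o, "farm_outcome")) {
      stop("inputs must be farm_outcome objects", call. = FALSE)
    }
  }
  if (conventional$scenario$heads_slaughtered !=
      welfare$scenario$heads_slaughtered) {
    stop("head counts differ between scenarios", call. = FALSE)
  }
  if (conventional$scenario$meat_price != welfare$scenario$meat_price) {
    stop("meat price must be held fixed across regimes", call. = FALSE)
  }
  diff <- list(quantity_kg = welfare$quantity_kg - conventional$quantity_kg,
               revenue = welfare$revenue - conventional$revenue,
               cost = welfare$cost - conventional$cost,
               profit = welfare$profit - conventional$profit)
  structure(list(conventional = conventional, welfare = welfare,
                 difference = diff),
            class = "farm_comparison")
}

#' @export
print.farm_comparison <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "f", digits = 0, big.mark = ",")
  rows <- rbind(
    quantity_kg = c(x$conventional$quantity_kg, x$welfare$quantity_kg,
                    x$difference$quantity_kg),
    revenue = c(x$conventional$revenue, x$welfare$revenue,
                x$difference$revenue),
    cost = c(x$conventional$cost, x$welfare$cost, x$difference$cost),
    profit = c(x$conventional$profit, x$welfare$profit, x$difference$profit))
  colnames(rows) <- c("conventional", "welfare_friendly", "difference")
  cat("Annual farm comparison (excluding common costs)\n")
  print(apply(rows, c(1, 2), fmt), quote = FALSE)
  invisible(x)
}

#' @rdname compare_farm
#' @param comparison a `farm_comparison`.
#' @return `farm_table` returns a data.frame in published-table layout
#'   (rows = quantity, revenue, cost, profit; columns = regimes and their
#'   difference).
#' @export
farm_table <- function(comparison) {
  data.frame(
    item = c("quantity_kg", "revenue_usd", "cost_usd", "profit_usd"),
    conventional = c(comparison$conventional$quantity_kg,
                     comparison$conventional$revenue,
                     comparison$conventional$cost,
                     comparison$conventional$profit),
    welfare_friendly = c(comparison$welfare$quantity_kg,
                         comparison$welfare$revenue,
                         comparison$welfare$cost,
                         comparison$welfare$profit),
    difference = c(comparison$difference$quantity_kg,
                   comparison$difference$revenue,
                   comparison$difference$cost,
                   comparison$difference$profit),
    stringsAsFactors = FALSE)
}
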