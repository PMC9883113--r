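#' Discount factor for a given cycle
#'
#' `(1 + r)^(-cycle * cycle_length_years)` with the annual rate `r` from
#' the settings; cycle 0 is undiscounted.
#'
#' @param settings A [model_settings()].
#' @param cycle Cycle index (vectorized), `>= 0`.
#' @return Dimensionless discount factor(s).
#' @export
discount_factor <- function(settings, cycle) {
  stopifnot(inherits(settings, "model_settings"), is.numeric(cycle))
  if (any(cycle < 0)) stop("'cycle' must be >= 0", call. = FALSE)
  r <- settings$annual_discount_rate
  if (r < 0) stop("domain error: discount rate must be >= 0", call. = FALSE)
  (1 + r)^(-cycle * settings$cycle_length_years)
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' QALYs are the discounted sum over cycles of cycle length times the
#' utility-weighted occupancy of the two alive states. Costs comprise the
#' one-time entry costs, the expected one-time toxicity cost
#' (`toxicity_cost * toxicity_incidence`), the per-cycle FFS and PS costs
#' weighted by occupancy, and monthly ADT charged against FFS occupancy
#' for the configured duration. Accrual for cycle `k` uses the occupancy
#' at the cycle start (or the average of the start and end occupancies
#' when the half-cycle correction is enabled) and the discount factor of
#' cycle `k`.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param utilities A [utility_set()].
#' @param costs A [cost_schedule()].
#' @param settings A [model_settings()]; its cycle length must match the
#'   trace.
#' @return A list with elements `cost` (discounted USD) and `qaly`
#'   (discounted QALYs).
#' @export
accumulate <- function(trace, utilities, costs, settings) {
  stopifnot(inherits(trace, "cohort_trace"),
            inherits(utilities, "utility_set"),
            inherits(costs, "cost_schedule"),
            inherits(settings, "model_settings"))
  if (abs(trace$cycle_length_years - settings$cycle_length_years) > 1e-12) {
    stop("configuration error: trace and settings cycle lengths differ",
         call. = FALSE)
  }
  n <- nrow(trace$occupancy) - 1
  if (n != n_cycles(settings)) {
    stop("configuration error: trace cycle count does not match settings",
         call. = FALSE)
  }
  cl <- settings$cycle_length_years
  occ <- trace$occupancy
  eff <- occ[seq_len(n), , drop = FALSE]
  if (settings$half_cycle_correction) {
    eff <- (eff + occ[seq_len(n) + 1, , drop = FALSE]) / 2
  }
  k <- seq_len(n) - 1
  df <- discount_factor(settings, k)

  qaly <- sum(df * cl * (eff[, "ffs"] * utilities$u_ffs +
                           eff[, "ps"] * utilities$u_ps))

  # months of ADT falling inside cycle k (cycles are 12*cl months long)
  months_per_cycle <- 12 * cl
  adt_months <- pmax(0, pmin(costs$adt_duration_months,
                             (k + 1) * months_per_cycle) -
                       k * months_per_cycle)
  cost <- sum(costs$one_time_costs) +
    costs$toxicity_cost * costs$toxicity_incidence +
    sum(df * (eff[, "ffs"] * costs$per_cycle_ffs +
                eff[, "ps"] * costs$per_cycle_ps +
                eff[, "ffs"] * costs$adt_monthly * adt_months))
  list(cost = cost, qaly = qaly)
}

#' Incremental cost-effectiveness of one strategy over another
#'
#' Computes incremental cost, incremental effectiveness, the ICER
#' `delta_cost / delta_qaly`, per-arm average cost-effectiveness, and a
#' dominance assessment. Convention: increments are `a - b`, so `a` is
#' the strategy being evaluated against comparator `b`.
#'
#' @param a,b Lists with elements `cost` (USD) and `qaly`, e.g. from
#'   [accumulate()].
#' @param labels Character vector of two arm labels.
#' @return An object of class `ce_result` with fields `cost`, `qaly`
#'   (named per-arm vectors), `incremental_cost`,
#'   `incremental_effectiveness`, `icer` (NA when effectiveness is
#'   equal), `avg_ce` (per-arm cost/QALY), and `dominance` (one of
#'   `"none"`, `"a_dominant"`, `"b_dominant"`,
#'   `"equal effectiveness, compare costs"`).
#' @export
#' @examples
#' compute_icer(list(cost = 34411.85, qaly = 2.32),
#'              list(cost = 30160.81, qaly = 2.14))
compute_icer <- function(a, b, labels = c("a", "b")) {
  stopifnot(is.numeric(a$cost), is.numeric(a$qaly),
            is.numeric(b$cost), is.numeric(b$qaly),
            length(labels) == 2L)
  d_cost <- a$cost - b$cost
  d_eff <- a$qaly - b$qaly
  dominance <- "none"
  if (d_eff == 0) {
    icer <- NA_real_
    dominance <- "equal effectiveness, compare costs"
  } else {
    icer <- d_cost / d_eff
    if (d_eff > 0 && d_cost <= 0) dominance <- "a_dominant"
    if (d_eff < 0 && d_cost >= 0) dominance <- "b_dominant"
  }
  cost <- stats::setNames(c(a$cost, b$cost), labels)
  qaly <- stats::setNames(c(a$qaly, b$qaly), labels)
  structure(list(cost = cost,
                 qaly = qaly,
                 incremental_cost = d_cost,
                 incremental_effectiveness = d_eff,
                 icer = icer,
                 avg_ce = cost / qaly,
                 dominance = dominance),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  labs <- names(x$cost)
  cat("Cost-effectiveness summary\n")
  for (i in 1:2) {
    cat(sprintf("  %-6s cost $%.2f, effectiveness %.4f QALYs, avg $%.2f/QALY\n",
                labs[i], x$cost[i], x$qaly[i], x$avg_ce[i]))
  }
  cat(sprintf("  incremental cost $%.2f, incremental effectiveness %.4f QALYs\n",
              x$incremental_cost, x$incremental_effectiveness))
  if (is.na(x$icer)) {
    cat("  ICER undefined:", x$dominance, "\n")
  } else {
    cat(sprintf("  ICER $%.2f/QALY", x$icer))
    if (x$dominance != "none") cat(" [", x$dominance, "]", sep = "")
    cat("\n")
  }
  invisible(x)
}

#' Convert a cost-effectiveness result to a Table-style data frame
#'
#' @param x A `ce_result`.
#' @param ... Unused.
#' @return A data frame with one row per arm plus incremental quantities
#'   on the first (evaluated) arm.
#' @export
as.data.frame.ce_result <- function(x, ...) {
  labs <- names(x$cost)
  data.frame(arm = labs,
             effectiveness_qalys = unname(x$qaly),
             cost_usd = unname(x$cost),
             incremental_effectiveness_qalys = c(x$incremental_effectiveness, NA),
             incremental_cost_usd = c(x$incremental_cost, NA),
             icer_usd_per_qaly = c(x$icer, NA),
             avg_cost_effectiveness_usd_per_qaly = unname(x$avg_ce))
}

#' Net monetary benefit
#'
#' `NMB = wtp * qaly - cost`. At a given willingness-to-pay threshold the
#' strategy with the higher NMB is preferred; the NMB difference between
#' two strategies changes sign exactly at their ICER.
#'
#' @param cost Discounted cost (USD).
#' @param qaly Discounted QALYs.
#' @param wtp Willingness-to-pay threshold (USD/QALY), `>= 0`.
#' @return NMB in USD (vectorized).
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  stopifnot(is.numeric(cost), is.numeric(qaly), is.numeric(wtp))
  if (any(wtp < 0)) stop("'wtp' must be >= 0", call. = FALSE)
  wtp * qaly - cost
}
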