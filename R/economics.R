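#' Discount a monetary or health flow
#'
#' Discrete annual discounting: `amount / (1 + rate)^years_from_start`.
#'
#' @param amount Flow value.
#' @param years_from_start Years after the policy start (0 = undiscounted).
#' @param rate Annual discount rate (default 3%).
#' @return The discounted value.
#' @examples
#' discount(103, 1) # 100
#' @export
discount <- function(amount, years_from_start, rate = 0.03) {
  if (any(rate < 0)) abort_input("discount rate must be nonnegative")
  amount / (1 + rate)^years_from_start
}

#' Health-state disutility weights
#'
#' Disability weights on a 0–1 scale with 95% intervals: cardiovascular
#' events (myocardial infarction or stroke) 0.28 (0.02–0.58), end-stage renal
#' disease 0.57 (0.40–0.75), diabetic neuropathy 0.10 (0.07–0.13), diabetic
#' retinopathy 0.19 (0.13–0.25). A cardiovascular event's disutility applies
#' for one year per event; the chronic states persist until death.
#'
#' @return Tibble with `state`, `weight`, `conf_low`, `conf_high`.
#' @export
default_utility_weights <- function() {
  out <- tibble(
    state = c("cvd_event", "esrd", "neuropathy", "retinopathy"),
    weight = c(0.28, 0.57, 0.10, 0.19),
    conf_low = c(0.02, 0.40, 0.07, 0.13),
    conf_high = c(0.58, 0.75, 0.13, 0.25)
  )
  if (any(out$weight < 0 | out$weight > 1)) abort_config("weights must be in [0, 1]")
  out
}

#' Cost inputs (2017 US dollars)
#'
#' Annual treatment costs, per-event and per-state management costs, and
#' food-aid material/overhead costs per recipient per month, each with a 95%
#' interval.
#'
#' @return Tibble with `item`, `cost`, `conf_low`, `conf_high`, `unit`.
#' @export
default_cost_table <- function() {
  tibble(
    item = c("bp_treatment", "diabetes_treatment", "lipid_treatment",
             "ascvd_event", "esrd_year", "neuropathy_year", "retinopathy_year",
             "parcel_food_month", "parcel_overhead_month",
             "debit_food_month", "debit_overhead_month",
             "fv_grain_cost_ratio_per_pound", "alt_parcel_extra_overhead_month"),
    cost = c(6.42, 14.14, 5.96, 11663.46, 14128.68, 995.26, 3519.97,
             37.00, 11.50, 30.00, 3.30, 0.58, 1.16),
    conf_low = c(5.69, 7.72, 4.72, 8170.22, 12896.10, 430.67, 665.95,
                 31.00, 9.64, 13.50, 2.77, 0.30, 0.90),
    conf_high = c(7.15, 35.55, 7.20, 15143.86, 15365.10, 2421.47, 6364.90,
                  43.00, 13.36, 47.00, 3.83, 1.20, 1.80),
    unit = c(rep("USD/patient/year", 3), "USD/event", rep("USD/patient/year", 3),
             rep("USD/recipient/month", 4), "ratio", "USD/recipient/month")
  )
}

cost_of <- function(table, item) {
  i <- match(item, table$item)
  if (is.na(i)) abort_config(sprintf("cost item '%s' not found", item))
  table$cost[i]
}

#' Reference remaining life expectancy
#'
#' Linear remaining-life-expectancy curve (86.6 years at birth, floor of 2),
#' a documented stand-in for an external reference table; used to convert
#' deaths into years of life lost.
#'
#' @return Tibble with `age` (0–110) and `remaining_le`.
#' @export
default_life_table <- function() {
  tibble(age = 0:110, remaining_le = pmax(86.6 - (0:110), 2))
}

remaining_le_at <- function(age, life_table) {
  idx <- findInterval(pmin(pmax(age, 0), max(life_table$age)), life_table$age)
  life_table$remaining_le[idx]
}

#' Accrue disability-adjusted life-years from a simulation ledger
#'
#' DALYs are years of life lost (YLL: each death contributes the discounted
#' reference remaining life expectancy at its age) plus utility-weighted
#' years lived with disability (YLD: state person-years times disutility,
#' cardiovascular events for one year each). Both are discounted at the
#' annual rate from the policy start (year 1 undiscounted) and normalized
#' per 100,000 baseline population. YLL is attributed to cardiovascular
#' disease for deaths in an event year and to `other_mortality` otherwise.
#'
#' @param ledger A `sim_ledger`.
#' @param weights Disutility weights ([default_utility_weights()]).
#' @param life_table Reference life table ([default_life_table()]).
#' @param discount_rate Annual discount rate.
#' @param per Population normalization (default 100,000).
#' @return Tibble with `component`, `yld`, `yll`, `daly` (one row per state
#'   plus `other_mortality`); `daly = yld + yll` exactly, and the column sums
#'   give the totals.
#' @export
accrue_dalys <- function(ledger, weights = default_utility_weights(),
                         life_table = default_life_table(),
                         discount_rate = 0.03, per = 1e5) {
  if (is.null(life_table) || !all(c("age", "remaining_le") %in% names(life_table))) {
    abort_config("a life table with age and remaining_le is required")
  }
  norm <- per / ledger$n0
  wt <- setNames(weights$weight, weights$state)
  by <- ledger$by_year
  df <- discount(1, by$year - 1, discount_rate)
  yld <- c(
    cvd_event = sum(df * by$cvd_event_py * wt[["cvd_event"]]),
    esrd = sum(df * by$esrd_py * wt[["esrd"]]),
    neuropathy = sum(df * by$neuropathy_py * wt[["neuropathy"]]),
    retinopathy = sum(df * by$retinopathy_py * wt[["retinopathy"]]),
    other_mortality = 0
  )
  dd <- ledger$deaths
  yll_all <- if (nrow(dd)) {
    discount(remaining_le_at(dd$age, life_table), dd$year - 1, discount_rate)
  } else {
    numeric(0)
  }
  yll <- c(
    cvd_event = sum(yll_all * dd$cvd_weight),
    esrd = 0, neuropathy = 0, retinopathy = 0,
    other_mortality = sum(yll_all * (dd$weight - dd$cvd_weight))
  )
  comp_names <- names(yld)
  yll_vec <- unname(yll[comp_names]) * norm
  yld_vec <- unname(yld) * norm
  tibble(component = comp_names, yld = yld_vec, yll = yll_vec) |>
    mutate(daly = .data$yld + .data$yll)
}

monthly_aid_cost <- function(scenario_kind, table, budget_multiplier = 1) {
  parcel <- cost_of(table, "parcel_food_month") + cost_of(table, "parcel_overhead_month")
  switch(scenario_kind,
    traditional = parcel,
    # the alternative parcel is budget-neutral by design (same total outlay)
    alternative_parcel = parcel,
    enhanced_parcel = parcel * budget_multiplier,
    debit_card = cost_of(table, "debit_food_month") + cost_of(table, "debit_overhead_month"),
    cash = cost_of(table, "debit_food_month") + cost_of(table, "debit_overhead_month"),
    parcel
  )
}

#' Accrue discounted costs from a simulation ledger
#'
#' Healthcare-sector costs cover treatment person-years (blood pressure,
#' diabetes, lipid therapy), cardiovascular event management, and chronic
#' complication management; the societal perspective adds food-aid material
#' and overhead outlays for aid-recipient person-years at the scenario's
#' monthly cost. All flows are discounted annually and normalized per
#' 100,000 baseline population.
#'
#' @param ledger A `sim_ledger`.
#' @param table Cost table ([default_cost_table()]).
#' @param perspective `"healthcare"` or `"societal"`.
#' @param discount_rate Annual discount rate.
#' @param per Population normalization (default 100,000).
#' @param budget_multiplier Aid-budget multiplier for enhanced-parcel runs.
#' @return Tibble with `item` and discounted `cost` (USD per 100,000); the
#'   item rows sum to the perspective total (`sum(out$cost)`).
#' @export
accrue_costs <- function(ledger, table = default_cost_table(),
                         perspective = c("healthcare", "societal"),
                         discount_rate = 0.03, per = 1e5,
                         budget_multiplier = 1) {
  perspective <- match.arg(perspective)
  norm <- per / ledger$n0
  by <- ledger$by_year
  df <- discount(1, by$year - 1, discount_rate)
  out <- tibble(
    item = c("bp_treatment", "diabetes_treatment", "lipid_treatment",
             "ascvd_event_management", "esrd_management",
             "neuropathy_management", "retinopathy_management"),
    cost = norm * c(
      sum(df * by$bp_tx_py) * cost_of(table, "bp_treatment"),
      sum(df * by$dm_tx_py) * cost_of(table, "diabetes_treatment"),
      sum(df * by$statin_py) * cost_of(table, "lipid_treatment"),
      sum(df * by$ascvd_events) * cost_of(table, "ascvd_event"),
      sum(df * by$esrd_py) * cost_of(table, "esrd_year"),
      sum(df * by$neuropathy_py) * cost_of(table, "neuropathy_year"),
      sum(df * by$retinopathy_py) * cost_of(table, "retinopathy_year")
    )
  )
  if (perspective == "societal") {
    # program outlays are per enrolled recipient over the policy horizon:
    # aid is delivered to enrolled households, so the budget is fixed by
    # enrollment, not by individual vital status — scenarios with identical
    # per-recipient budgets cancel exactly by design
    monthly <- monthly_aid_cost(ledger$scenario_kind, table, budget_multiplier)
    horizon <- ledger$config$policy_horizon_years
    in_h <- by$year <= horizon
    food <- norm * sum(df[in_h]) * ledger$n_recipients0 * 12 * monthly
    out <- bind_rows(out, tibble(item = "food_aid", cost = food))
  }
  out
}

#' Incremental cost-effectiveness ratio
#'
#' `delta_cost / dalys_averted`, with dominance labelling: an intervention
#' that both saves money and averts DALYs is dominant and reported as dollars
#' saved per DALY averted.
#'
#' @param delta_cost Incremental cost, USD (intervention minus baseline;
#'   negative = savings).
#' @param dalys_averted DALYs averted (positive = health gain); must be
#'   nonzero.
#' @return One-row tibble with `delta_cost`, `dalys_averted`, `icer`
#'   (signed), `usd_per_daly` (magnitude) and `label`.
#' @examples
#' icer(-1255370, 3034) # dominant: about $414 saved per DALY averted
#' @export
icer <- function(delta_cost, dalys_averted) {
  if (dalys_averted == 0) {
    abort_input("DALY difference is zero: ICER undefined")
  }
  value <- delta_cost / dalys_averted
  label <- if (delta_cost <= 0 && dalys_averted > 0) {
    sprintf("dominant, $%.0f saved per DALY averted", abs(value))
  } else if (delta_cost > 0 && dalys_averted > 0) {
    sprintf("$%.0f spent per DALY averted", value)
  } else if (delta_cost > 0) {
    "dominated (costlier and DALY-incurring)"
  } else {
    sprintf("$%.0f saved per DALY incurred", abs(value))
  }
  tibble(delta_cost = delta_cost, dalys_averted = dalys_averted,
         icer = value, usd_per_daly = abs(value), label = label)
}

#' Cost-effectiveness comparison of two scenario ledgers
#'
#' Convenience wrapper: accrues DALYs and costs for both ledgers, forms the
#' averted quantities (baseline minus intervention) and the ICER under the
#' chosen perspective.
#'
#' @param baseline,intervention `sim_ledger` objects.
#' @param perspective `"healthcare"` or `"societal"`.
#' @inheritParams accrue_costs
#' @param weights,life_table DALY inputs.
#' @return List with `dalys` (per-component averted), `costs` (per-item
#'   averted), and `icer` (one-row tibble).
#' @export
cea_compare <- function(baseline, intervention,
                        perspective = c("healthcare", "societal"),
                        table = default_cost_table(),
                        weights = default_utility_weights(),
                        life_table = default_life_table(),
                        discount_rate = 0.03, budget_multiplier = 1) {
  perspective <- match.arg(perspective)
  d_b <- accrue_dalys(baseline, weights, life_table, discount_rate)
  d_i <- accrue_dalys(intervention, weights, life_table, discount_rate)
  dalys <- tibble(component = d_b$component,
                  averted = d_b$daly - d_i$daly[match(d_b$component, d_i$component)])
  c_b <- accrue_costs(baseline, table, perspective, discount_rate,
                      budget_multiplier = 1)
  c_i <- accrue_costs(intervention, table, perspective, discount_rate,
                      budget_multiplier = budget_multiplier)
  costs <- tibble(item = c_b$item,
                  averted = c_b$cost - c_i$cost[match(c_b$item, c_i$item)])
  list(
    dalys = dalys, costs = costs,
    icer = icer(delta_cost = -sum(costs$averted),
                dalys_averted = sum(dalys$averted))
  )
}
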