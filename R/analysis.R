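#' Budget model for parcel composition changes
#'
#' Converts the published procurement cost ratio of fruits and vegetables to
#' grain (per pound) into per-kcal costs using configurable energy densities,
#' and records the grain content of the current parcel and the monthly
#' budget. The defaults (grain 1,652 kcal/lb, mixed fruits and vegetables
#' 168 kcal/lb, grain parcel 470.6 kcal/person/day) are calibration values
#' chosen so the default budget-neutral diversion reproduces the
#' grain −40 / fruit-and-vegetable +7 kcal/person/day exchange at an 8.5%
#' diversion fraction.
#'
#' @param cost_table Cost inputs ([default_cost_table()]).
#' @param grain_kcal_per_pound,fv_kcal_per_pound Energy densities.
#' @param grain_cost_per_pound Grain procurement cost, USD/lb.
#' @param grain_parcel_kcal Grain supplied by the current parcel,
#'   kcal/person/day.
#' @return One-row tibble of class `budget_model` with per-kcal costs,
#'   overheads and the monthly budget.
#' @export
budget_model <- function(cost_table = default_cost_table(),
                         grain_kcal_per_pound = 1652,
                         fv_kcal_per_pound = 168,
                         grain_cost_per_pound = 0.20,
                         grain_parcel_kcal = 470.6) {
  ratio <- cost_of(cost_table, "fv_grain_cost_ratio_per_pound")
  grain_cost_per_kcal <- grain_cost_per_pound / grain_kcal_per_pound
  fv_cost_per_kcal <- ratio * grain_cost_per_pound / fv_kcal_per_pound
  out <- tibble(
    grain_cost_per_kcal = grain_cost_per_kcal,
    fv_cost_per_kcal = fv_cost_per_kcal,
    overhead_base = cost_of(cost_table, "parcel_overhead_month"),
    overhead_fv_extra = cost_of(cost_table, "alt_parcel_extra_overhead_month"),
    total_budget = cost_of(cost_table, "parcel_food_month") +
      cost_of(cost_table, "parcel_overhead_month"),
    grain_parcel_kcal = grain_parcel_kcal
  )
  if (any(out$grain_cost_per_kcal <= 0 | out$fv_cost_per_kcal <= 0)) {
    abort_config("budget model costs must be positive")
  }
  class(out) <- c("budget_model", class(out))
  out
}

#' Budget-neutral parcel deltas for a grain diversion fraction
#'
#' Diverting a fraction `f` of the grain parcel removes `f * grain_parcel_kcal`
#' of grain and buys back fruits and vegetables with the freed budget:
#' `fv_delta = f * grain_parcel_kcal * grain_cost_per_kcal / fv_cost_per_kcal`,
#' so the parcel's food-material cost is unchanged to the cent.
#'
#' @param fraction Diversion fraction in `[0, 1]`.
#' @param budget A [budget_model()].
#' @return Tibble with `fraction`, `grain_delta`, `fruit_veg_delta`
#'   (kcal/person/day) and `cost_change` (USD/recipient/day, ~0 by design).
#' @export
diversion_deltas <- function(fraction, budget = budget_model()) {
  grain_delta <- -fraction * budget$grain_parcel_kcal
  fv_delta <- fraction * budget$grain_parcel_kcal *
    budget$grain_cost_per_kcal / budget$fv_cost_per_kcal
  tibble(
    fraction = fraction,
    grain_delta = grain_delta,
    fruit_veg_delta = fv_delta,
    cost_change = grain_delta * budget$grain_cost_per_kcal +
      fv_delta * budget$fv_cost_per_kcal
  )
}

#' Draw the uncertain parameter set for probabilistic sensitivity analysis
#'
#' Redraws every input carrying a 95% interval: mediator coefficients
#' (normal), nutrient densities (truncated normal), disutility weights
#' (normal truncated to `[0, 1]`), and costs (lognormal when the interval is
#' strictly positive and right-skewed, otherwise normal truncated at zero).
#'
#' @param seed Integer seed.
#' @param med_coeffs,density_table,weights,cost_table Baseline inputs.
#' @return Named list with drawn `med_coeffs`, `density_table`, `weights`,
#'   `cost_table`.
#' @export
draw_parameter_set <- function(seed, med_coeffs = default_mediator_coefficients(),
                               density_table = default_density_table(),
                               weights = default_utility_weights(),
                               cost_table = default_cost_table()) {
  z95 <- qnorm(0.975)
  med <- draw_mediator_coefficients(med_coeffs, seed = child_seed(seed, "psa-med"))
  dens <- density_table
  zd <- with_seed(child_seed(seed, "psa-dens"), rnorm(nrow(dens)))
  dens$density <- pmax(dens$density + dens$density_sd * zd, 0)
  wts <- weights
  zw <- with_seed(child_seed(seed, "psa-util"), rnorm(nrow(wts)))
  wts$weight <- pmin(pmax(wts$weight + (wts$conf_high - wts$conf_low) / (2 * z95) * zw, 0), 1)
  ct <- cost_table
  zc <- with_seed(child_seed(seed, "psa-cost"), rnorm(nrow(ct)))
  skewed <- ct$conf_low > 0 &
    (ct$conf_high / ct$cost) > 1.1 * (ct$cost / ct$conf_low)
  sd_n <- (ct$conf_high - ct$conf_low) / (2 * z95)
  sd_l <- log(pmax(ct$conf_high, 1e-12) / pmax(ct$conf_low, 1e-12)) / (2 * z95)
  ct$cost <- ifelse(skewed, ct$cost * exp(sd_l * zc - sd_l^2 / 2),
                    pmax(ct$cost + sd_n * zc, 0))
  list(med_coeffs = med, density_table = dens, weights = wts, cost_table = ct)
}

#' Percentile interval over probabilistic sensitivity draws
#'
#' Runs a model function once per parameter draw and summarizes each reported
#' quantity by its mean and percentile 95% interval. The model function
#' receives the drawn parameter set from [draw_parameter_set()] and must
#' return a tibble with columns `quantity` and `value`.
#'
#' @param model Function of one argument (the drawn parameter list).
#' @param n_draws Number of draws (desk-scale default 500; the full analysis
#'   uses 10,000).
#' @param seed Integer seed; draw `j` uses a child seed of `seed`.
#' @param params Baseline parameter inputs, passed to [draw_parameter_set()].
#' @return Tibble with `quantity`, `estimate` (mean over draws), `conf_low`,
#'   `conf_high` (2.5/97.5 percentiles), `n_draws`.
#' @export
uncertainty_run <- function(model, n_draws = 500, seed = 1L, params = list()) {
  if (n_draws < 2) abort_input("n_draws must be at least 2")
  draws <- lapply(seq_len(n_draws), function(j) {
    ps <- do.call(draw_parameter_set,
                  c(list(seed = child_seed(seed, paste0("psa-", j))), params))
    out <- model(ps)
    out$draw <- j
    out
  })
  list_rbind(draws) |>
    group_by(.data$quantity) |>
    summarise(
      estimate = mean(.data$value),
      conf_low = quantile(.data$value, 0.025, names = FALSE),
      conf_high = quantile(.data$value, 0.975, names = FALSE),
      n_draws = n_draws, .groups = "drop"
    )
}

# one full pipeline evaluation: consumption, biomarker and outcome deltas
# for each scenario vs the traditional parcel
suite_once <- function(cohort, config, scenarios, risk_coeffs, med_coeffs,
                       density_table, mds_cutpoints, mode = "expected") {
  base <- run_scenario(cohort, aid_scenario("traditional"), config,
                       risk_coeffs, med_coeffs, density_table, mds_cutpoints,
                       mode = mode)
  rows <- list()
  for (sc in scenarios) {
    scen <- if (inherits(sc, "aid_scenario")) sc else aid_scenario(sc)
    led <- run_scenario(cohort, scen, config, risk_coeffs, med_coeffs,
                        density_table, mds_cutpoints, mode = mode)
    seed_eff <- if (config$common_random_numbers) config$seed else config$seed
    sp <- scenario_person_deltas(cohort, scen, seed_eff, med_coeffs,
                                 density_table, mds_cutpoints)
    rec <- cohort$receives_aid
    d <- sp$deltas[rec, ]
    horizon <- config$policy_horizon_years
    dbmi <- bmi_change_from_energy(sp$deltas$energy, cohort, horizon = horizon,
                                   coeffs = med_coeffs)[rec]
    da1c <- a1c_change(dbmi, sp$deltas$mds[rec], med_coeffs)
    cons <- tibble(
      quantity = c("energy", "sodium", "potassium", "sfa", "mufa", "pufa", "mds"),
      value = c(mean(d$energy), mean(d$sodium), mean(d$potassium),
                mean(d$sfa), mean(d$mufa), mean(d$pufa), mean(d$mds))
    )
    biom <- tibble(
      quantity = c("bmi", "sbp", "dbp", "total_chol", "hdl_chol", "a1c"),
      value = c(mean(dbmi), mean(sp$d_sbp[rec]), mean(sp$d_dbp[rec]),
                mean(sp$d_tc[rec]), mean(sp$d_hdl[rec]), mean(da1c))
    )
    outc <- compare_scenarios(base, led) |>
      select(quantity = "outcome", value = "difference")
    rows[[scen$kind]] <- bind_rows(
      mutate(cons, table = "consumption"),
      mutate(biom, table = "biomarkers"),
      mutate(outc, table = "outcomes")
    ) |>
      mutate(scenario = scen$kind)
  }
  list_rbind(unname(rows))
}

#' Run the comparative scenario suite
#'
#' Produces the three comparative report tables — consumption deltas
#' (kcal or mg/person/day and MDS points), biomarker deltas at the policy
#' horizon, and outcome incidence-rate deltas per 1,000 person-years — for
#' each scenario versus the traditional parcel, among aid recipients. With
#' `n_draws > 0` each quantity carries a percentile 95% interval over
#' parameter draws; the engine's expectation mode is used inside the
#' uncertainty loop so intervals reflect parameter uncertainty rather than
#' simulation noise.
#'
#' @param cohort Baseline cohort.
#' @param config A [sim_config()].
#' @param scenarios Character kinds or [aid_scenario()] objects to compare.
#' @param n_draws Parameter draws for intervals (0 = point estimates only).
#' @param risk_coeffs,med_coeffs,density_table,mds_cutpoints Model inputs.
#' @return A tibble of class `aid_comparison` with columns `scenario`,
#'   `table` (`consumption` / `biomarkers` / `outcomes`), `quantity`,
#'   `estimate` and, when drawn, `conf_low` / `conf_high`.
#' @export
run_comparison_suite <- function(cohort, config,
                                 scenarios = c("debit_card", "cash", "alternative_parcel"),
                                 n_draws = 0,
                                 risk_coeffs = default_risk_coefficients(),
                                 med_coeffs = default_mediator_coefficients(),
                                 density_table = default_density_table(),
                                 mds_cutpoints = default_mds_cutpoints()) {
  point <- suite_once(cohort, config, scenarios, risk_coeffs, med_coeffs,
                      density_table, mds_cutpoints) |>
    select("scenario", "table", "quantity", estimate = "value")
  if (n_draws > 0) {
    ci <- uncertainty_run(
      model = function(ps) {
        suite_once(cohort, config, scenarios, risk_coeffs, ps$med_coeffs,
                   ps$density_table, mds_cutpoints) |>
          mutate(quantity = paste(.data$scenario, .data$table, .data$quantity,
                                  sep = "|")) |>
          select("quantity", "value")
      },
      n_draws = n_draws, seed = config$seed,
      params = list(med_coeffs = med_coeffs, density_table = density_table)
    ) |>
      tidyr::separate_wider_delim("quantity", delim = "|",
                                  names = c("scenario", "table", "quantity")) |>
      select("scenario", "table", "quantity", "conf_low", "conf_high")
    point <- left_join(point, ci, by = c("scenario", "table", "quantity"))
  }
  class(point) <- c("aid_comparison", class(point))
  point
}

#' Threshold search for the budget-neutral alternative parcel
#'
#' Finds the smallest grain-diversion fraction whose budget-neutral parcel
#' ([diversion_deltas()]) satisfies all three conditions: every outcome's
#' incidence-rate change versus the traditional parcel is negative (upper
#' 95% bound below zero when `n_draws > 0`, point estimate below zero
#' otherwise), the parcel's food-material cost is unchanged (guaranteed by
#' construction), and the resulting mean diet still clears the food-security
#' floors ([food_security_check()]) on its lower bootstrap bound. The search
#' scans a coarse grid for the first feasible fraction, then refines to the
#' requested resolution.
#'
#' @param budget A [budget_model()].
#' @param cohort Cohort used for outcome evaluation.
#' @param config A [sim_config()].
#' @param n_draws Parameter draws for the upper-bound condition (0 = point).
#' @param resolution Final grid resolution on the fraction (default 0.001).
#' @param coarse Initial scan step.
#' @param f_max Largest fraction considered.
#' @param baseline_parcel Mean intake used for the food-security check.
#' @param risk_coeffs,med_coeffs,density_table,mds_cutpoints Model inputs.
#' @return List with `fraction`, `grain_delta`, `fruit_veg_delta`,
#'   `feasible`, and a `detail` tibble of evaluated fractions.
#' @export
threshold_search <- function(budget = budget_model(), cohort, config,
                             n_draws = 0, resolution = 0.001, coarse = 0.005,
                             f_max = 1,
                             baseline_parcel = arm_mean_intake("parcel"),
                             risk_coeffs = default_risk_coefficients(),
                             med_coeffs = default_mediator_coefficients(),
                             density_table = default_density_table(),
                             mds_cutpoints = default_mds_cutpoints()) {
  if (budget$total_budget <= 0) {
    return(list(fraction = NA_real_, feasible = FALSE,
                detail = tibble(), reason = "zero aid budget"))
  }
  base_led <- run_scenario(cohort, aid_scenario("traditional"), config,
                           risk_coeffs, med_coeffs, density_table,
                           mds_cutpoints, mode = "expected")

  eval_fraction <- function(f) {
    dd <- diversion_deltas(f, budget)
    scen <- aid_scenario("alternative_parcel", grain_delta = dd$grain_delta,
                         fruit_veg_delta = dd$fruit_veg_delta)
    intake <- apply_scenario(baseline_parcel, scen)
    prof <- nutrients_from_intake(intake, density_table, bootstrap_draws = 50,
                                  seed = config$seed, cutpoints = mds_cutpoints)
    secure <- isTRUE(as.logical(food_security_check(prof)))
    if (n_draws == 0) {
      led <- run_scenario(cohort, scen, config, risk_coeffs, med_coeffs,
                          density_table, mds_cutpoints, mode = "expected")
      upper <- compare_scenarios(base_led, led)$difference
    } else {
      ci <- uncertainty_run(
        model = function(ps) {
          b <- run_scenario(cohort, aid_scenario("traditional"), config,
                            risk_coeffs, ps$med_coeffs, ps$density_table,
                            mds_cutpoints, mode = "expected")
          led <- run_scenario(cohort, scen, config, risk_coeffs, ps$med_coeffs,
                              ps$density_table, mds_cutpoints, mode = "expected")
          compare_scenarios(b, led) |>
            select(quantity = "outcome", value = "difference")
        },
        n_draws = n_draws, seed = config$seed,
        params = list(med_coeffs = med_coeffs, density_table = density_table)
      )
      upper <- ci$conf_high
    }
    tibble(fraction = f, all_outcomes_reduced = all(upper < 0),
           food_secure = secure, max_upper = max(upper))
  }

  grid <- seq(coarse, f_max, by = coarse)
  detail <- list()
  found <- NA_real_
  for (f in grid) {
    res <- eval_fraction(f)
    detail[[length(detail) + 1L]] <- res
    if (res$all_outcomes_reduced && res$food_secure) {
      found <- f
      break
    }
  }
  if (!is.na(found) && resolution < coarse) {
    fine <- seq(max(found - coarse + resolution, resolution), found,
                by = resolution)
    for (f in fine) {
      res <- eval_fraction(f)
      detail[[length(detail) + 1L]] <- res
      if (res$all_outcomes_reduced && res$food_secure) {
        found <- f
        break
      }
    }
  }
  dd <- if (!is.na(found)) diversion_deltas(found, budget) else
    tibble(grain_delta = NA_real_, fruit_veg_delta = NA_real_)
  list(fraction = found, grain_delta = dd$grain_delta,
       fruit_veg_delta = dd$fruit_veg_delta, feasible = !is.na(found),
       detail = list_rbind(detail))
}

#' Budget increase needed for a target diet-quality gain
#'
#' Monotone search over the aid-budget increase fraction: additional funds
#' (on top of the alternative parcel's food-material budget plus its extra
#' overhead) buy fruits and vegetables at the budget model's per-kcal cost,
#' and the mean Mediterranean Dietary Score gain among aid-recipient
#' households is evaluated against the target. Returns the smallest increase
#' achieving the target mean gain.
#'
#' @param target_mds_gain Target absolute MDS increase (points); 0 returns a
#'   0 increase.
#' @param budget A [budget_model()].
#' @param n_households Household draws used to evaluate the mean score gain.
#' @param seed Integer seed.
#' @param max_multiplier Upper bound on the budget multiplier (infeasibility
#'   beyond it).
#' @param base_deltas Parcel deltas the enhancement builds on (default: the
#'   standard alternative-parcel exchange).
#' @param mds_cutpoints Score cutpoints.
#' @return List with `increase_fraction`, `usd_per_person_month`,
#'   `mean_mds_gain`, `feasible`.
#' @export
enhanced_budget_search <- function(target_mds_gain, budget = budget_model(),
                                   n_households = 2000, seed = 1L,
                                   max_multiplier = 10,
                                   base_deltas = diversion_deltas(0.085),
                                   mds_cutpoints = default_mds_cutpoints()) {
  if (target_mds_gain < 0) abort_input("target_mds_gain must be nonnegative")
  # budget base for the enhancement: parcel food material plus the extra
  # fruit-and-vegetable handling overhead
  budget_base <- budget$total_budget - budget$overhead_base +
    budget$overhead_fv_extra
  hh <- generate_household_consumption("parcel", n_households,
                                       seed = child_seed(seed, "ebs"))
  base_mds <- mds_score(hh, cutpoints = mds_cutpoints)

  gain_at <- function(b) {
    fv_extra <- b * budget_base / 30.44 / budget$fv_cost_per_kcal
    scen_intake <- hh
    scen_intake$cereals <- pmax(scen_intake$cereals + base_deltas$grain_delta, 0)
    scen_intake$fruits_vegetables <- scen_intake$fruits_vegetables +
      base_deltas$fruit_veg_delta + fv_extra
    mean(mds_score(scen_intake, cutpoints = mds_cutpoints) - base_mds)
  }

  if (target_mds_gain == 0) {
    return(list(increase_fraction = 0, usd_per_person_month = 0,
                mean_mds_gain = gain_at(0), feasible = TRUE))
  }
  upper <- max_multiplier - 1
  if (gain_at(upper) < target_mds_gain) {
    return(list(increase_fraction = NA_real_, usd_per_person_month = NA_real_,
                mean_mds_gain = gain_at(upper), feasible = FALSE))
  }
  # mean score gain is monotone in the budget increase; bisect to 0.001
  lo <- 0; hi <- upper
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (gain_at(mid) >= target_mds_gain) hi <- mid else lo <- mid
  }
  list(increase_fraction = hi, usd_per_person_month = hi * budget_base,
       mean_mds_gain = gain_at(hi), feasible = TRUE)
}
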