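#' Simulation configuration
#'
#' @param policy_start_year Calendar year the policy change begins.
#' @param policy_horizon_years Length of the policy planning horizon (years).
#' @param cohort_size Expected cohort size (recorded; the cohort itself is
#'   passed to [run_scenario()]).
#' @param seed Integer master seed; all event, intake and birth streams are
#'   derived from it.
#' @param common_random_numbers If `TRUE` (default) the event uniforms depend
#'   only on the seed, person and year — not the scenario — so scenario
#'   contrasts are variance-reduced and a null scenario reproduces the
#'   baseline ledger exactly.
#' @param life_course If `TRUE`, continue simulating after the policy horizon
#'   (no further births) until the cohort is extinct or aged out, so costs
#'   and disability accrue over remaining lifetimes; incidence rates are
#'   always reported over the policy horizon only.
#' @param birth_rate Per-capita annual birth rate during the horizon.
#' @param secular_trends Biomarker drift table ([default_secular_trends()]).
#' @param adult_age_range Ages contributing to outcome denominators.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(policy_start_year = 2016, policy_horizon_years = 10,
                       cohort_size = NA_integer_, seed = 1L,
                       common_random_numbers = TRUE, life_course = FALSE,
                       birth_rate = default_birth_rate(),
                       secular_trends = default_secular_trends(),
                       adult_age_range = c(20, 79)) {
  if (policy_horizon_years < 1) abort_config("policy_horizon_years must be >= 1")
  structure(list(
    policy_start_year = policy_start_year,
    policy_horizon_years = policy_horizon_years,
    cohort_size = cohort_size, seed = as.integer(seed),
    common_random_numbers = common_random_numbers, life_course = life_course,
    birth_rate = birth_rate, secular_trends = secular_trends,
    adult_age_range = adult_age_range
  ), class = "sim_config")
}

# per-person intake deltas and static mediator responses for a scenario
scenario_person_deltas <- function(cohort, scenario, seed, med_coeffs,
                                   density_table, mds_cutpoints) {
  n <- nrow(cohort)
  base_intake <- generate_household_consumption(
    "parcel", n, seed = child_seed(seed, "intake"))[food_groups()]
  scen_intake <- base_intake
  rec <- cohort$receives_aid
  if (any(rec)) {
    scen_intake[rec, ] <- apply_scenario(base_intake[rec, , drop = FALSE],
                                         scenario,
                                         seed = child_seed(seed, "override"),
                                         truncate = TRUE)
  }
  prof_b <- nutrients_from_intake(base_intake, density_table,
                                  cutpoints = mds_cutpoints)
  prof_s <- nutrients_from_intake(scen_intake, density_table,
                                  cutpoints = mds_cutpoints)
  d <- tibble(
    energy = prof_s$energy - prof_b$energy,
    sodium = prof_s$sodium - prof_b$sodium,
    potassium = prof_s$potassium - prof_b$potassium,
    sfa = prof_s$sfa - prof_b$sfa,
    mufa = prof_s$mufa - prof_b$mufa,
    pufa = prof_s$pufa - prof_b$pufa,
    mds = prof_s$mds - prof_b$mds
  )
  bp <- sbp_dbp_change(d$sodium, d$potassium, person = cohort, coeffs = med_coeffs)
  lip <- lipid_change(d$sfa, d$mufa, d$pufa, pmax(prof_b$energy, 1), med_coeffs)
  list(deltas = d, d_sbp = bp$sbp, d_dbp = bp$dbp,
       d_tc = lip$total_chol, d_hdl = lip$hdl_chol,
       baseline_energy = prof_b$energy, baseline_mds = prof_b$mds)
}

#' Run one aid scenario through the annual microsimulation
#'
#' Executes the annual cycle over the policy horizon: intake (aid recipients
#' receive the scenario's consumption change), mediators (energy to BMI via
#' the energy-balance model, sodium/potassium to blood pressure, fatty acids
#' to cholesterol, BMI and diet quality to A1c), status classifiers and
#' calibrated incidence hazards, cardiovascular and microvascular events,
#' mortality (processed last, so a death year still contributes a full
#' person-year), then demography (ageing, secular biomarker trends, births).
#' Only persons aged 20–79 contribute to outcome numerators and denominators.
#'
#' `mode = "expected"` replaces every Bernoulli draw by its expectation and
#' propagates survival and state probabilities instead — a deterministic,
#' draw-free version of the same loop used for hazard calibration.
#'
#' @param cohort Baseline person-record tibble ([sample_refugee_cohort()]).
#' @param scenario An [aid_scenario()].
#' @param config A [sim_config()].
#' @param risk_coeffs A `risk_coefficient_set`.
#' @param med_coeffs Mediator coefficient tibble.
#' @param density_table Nutrient density table.
#' @param mds_cutpoints MDS cutpoints.
#' @param mode `"stochastic"` (default) or `"expected"`.
#' @param person_deltas Precomputed result of the internal per-person
#'   intake/mediator delta step; lets repeated runs that vary only the risk
#'   coefficients (hazard calibration) skip recomputing it.
#' @return A `sim_ledger`: per-outcome events and person-years at risk split
#'   by aid receipt (`by_outcome`), per-year economic state totals
#'   (`by_year`), expected or realized deaths with age and cardiovascular
#'   attribution (`deaths`), and the run configuration.
#' @examples
#' cohort <- sample_refugee_cohort(200, seed = 1)
#' cfg <- sim_config(policy_horizon_years = 3, seed = 1)
#' led <- run_scenario(cohort, aid_scenario("traditional"), cfg)
#' ledger_rates(led)
#' @export
run_scenario <- function(cohort, scenario, config,
                         risk_coeffs = default_risk_coefficients(),
                         med_coeffs = default_mediator_coefficients(),
                         density_table = default_density_table(),
                         mds_cutpoints = default_mds_cutpoints(),
                         mode = c("stochastic", "expected"),
                         person_deltas = NULL) {
  mode <- match.arg(mode)
  stochastic <- mode == "stochastic"
  stopifnot(inherits(scenario, "aid_scenario"), inherits(config, "sim_config"))
  validate_person_records(cohort)
  horizon <- config$policy_horizon_years
  seed <- if (config$common_random_numbers) {
    config$seed
  } else {
    child_seed(config$seed, paste0("scenario-", scenario$kind))
  }
  sp <- person_deltas %||% scenario_person_deltas(cohort, scenario, seed,
                                                  med_coeffs, density_table,
                                                  mds_cutpoints)
  d <- sp$deltas
  d_sbp <- sp$d_sbp; d_dbp <- sp$d_dbp; d_tc <- sp$d_tc; d_hdl <- sp$d_hdl

  state <- cohort
  surv <- as.numeric(cohort$alive)
  htn_free <- as.numeric(!cohort$has_hypertension)
  dm_prob <- as.numeric(cohort$has_diabetes)
  cvd_free <- as.numeric(!cohort$cvd_history)
  s_esrd <- rep(0, nrow(cohort)) # end-stage disease assumed non-prevalent at baseline
  s_neuro <- as.numeric(cohort$neuropathy)
  s_retino <- as.numeric(cohort$retinopathy)
  rec <- cohort$receives_aid

  outcomes <- sim_outcomes()
  ev_acc <- py_acc <- matrix(0, length(outcomes), 2,
                             dimnames = list(outcomes, c("aid", "no_aid")))
  by_year <- list()
  deaths <- list()
  total_years <- if (config$life_course) horizon + 95L else horizon
  micro_map <- c(esrd = "s_esrd", neuropathy = "s_neuro", retinopathy = "s_retino")

  acc <- function(mat, oc, w, x) {
    mat[oc, "aid"] <- mat[oc, "aid"] + sum(w * x * rec)
    mat[oc, "no_aid"] <- mat[oc, "no_aid"] + sum(w * x * !rec)
    mat
  }

  for (y in seq_len(total_years)) {
    n <- nrow(state)
    in_horizon <- y <= horizon
    adult <- state$age >= config$adult_age_range[1] &
      state$age <= config$adult_age_range[2]
    aw <- surv * adult

    # effective biomarkers: baseline trajectory plus scenario mediator deltas
    eff <- state
    dbmi_y <- bmi_change_from_energy(d$energy, state, horizon = y,
                                     coeffs = med_coeffs)
    da1c_y <- a1c_change(dbmi_y, d$mds, med_coeffs)
    eff$sbp <- eff$sbp + d_sbp
    eff$dbp <- eff$dbp + d_dbp
    eff$total_chol <- pmax(eff$total_chol + d_tc, 0.5)
    eff$hdl_chol <- pmax(eff$hdl_chol + d_hdl, 0.2)
    eff$bmi <- pmax(eff$bmi + dbmi_y, 10)
    eff$a1c <- pmin(pmax(eff$a1c + da1c_y, 3), 20)
    eff$has_diabetes <- dm_prob
    eff$cvd_history <- 1 - cvd_free

    if (stochastic) {
      u <- with_seed(child_seed(seed, paste0("u-", y)),
                     matrix(runif(n * 7), n, 7))
      colnames(u) <- outcomes
    }
    vals <- risk_term_values(eff)

    # hypertension incidence: classifier crossing or calibrated hazard
    p_htn <- hazard_to_prob(outcome_annual_hazard(eff, "hypertension", risk_coeffs, vals))
    cross <- as.numeric(classify_hypertension(eff$sbp, eff$dbp, state$on_bp_treatment))
    conv <- if (stochastic) {
      pmax(cross, as.numeric(u[, "hypertension"] < p_htn))
    } else {
      cross + (1 - cross) * p_htn
    }
    ev_htn <- htn_free * conv
    if (in_horizon) {
      py_acc <- acc(py_acc, "hypertension", aw, htn_free)
      ev_acc <- acc(ev_acc, "hypertension", aw, ev_htn)
    }
    htn_free <- htn_free - ev_htn

    # diabetes incidence
    dm_free <- 1 - dm_prob
    p_dm <- hazard_to_prob(outcome_annual_hazard(eff, "diabetes", risk_coeffs, vals))
    cross <- as.numeric(classify_diabetes(eff$a1c, state$on_diabetes_treatment))
    conv <- if (stochastic) {
      pmax(cross, as.numeric(u[, "diabetes"] < p_dm))
    } else {
      cross + (1 - cross) * p_dm
    }
    ev_dm <- dm_free * conv
    if (in_horizon) {
      py_acc <- acc(py_acc, "diabetes", aw, dm_free)
      ev_acc <- acc(ev_acc, "diabetes", aw, ev_dm)
    }
    dm_prob <- dm_prob + ev_dm

    # expectation mode carries fractional status probabilities; the hazard's
    # exponential link needs the exact mixture expectation
    # E[exp(b*D)] = 1 - p + p*exp(b) rather than exp(b*p) for those terms
    # (identical when p is 0/1, i.e. in stochastic mode)
    mixture_corr <- function(outcome) {
      if (stochastic) return(1)
      cf <- risk_coeffs[[outcome]]$coefficients
      corr <- 1
      if (!is.na(b <- cf["has_diabetes"]) && !is.null(b)) {
        corr <- corr * (1 - dm_prob + dm_prob * exp(b)) / exp(b * dm_prob)
      }
      p_c <- 1 - cvd_free
      if (!is.na(b <- cf["cvd_history"]) && !is.null(b)) {
        corr <- corr * (1 - p_c + p_c * exp(b)) / exp(b * p_c)
      }
      corr
    }

    # first cardiovascular events
    p_a <- hazard_to_prob(
      outcome_annual_hazard(eff, "ascvd", risk_coeffs, vals) * mixture_corr("ascvd"))
    ev_a <- cvd_free * if (stochastic) as.numeric(u[, "ascvd"] < p_a) else p_a
    if (in_horizon) {
      py_acc <- acc(py_acc, "ascvd", aw, cvd_free)
      ev_acc <- acc(ev_acc, "ascvd", aw, ev_a)
    }
    cvd_free <- cvd_free - ev_a

    # microvascular complications (diabetic pool only)
    for (m in names(micro_map)) {
      s_m <- get(micro_map[[m]])
      at_risk <- pmax(dm_prob - s_m, 0)
      p_m <- hazard_to_prob(outcome_annual_hazard(eff, m, risk_coeffs, vals))
      ev_m <- at_risk * if (stochastic) as.numeric(u[, m] < p_m) else p_m
      if (in_horizon) {
        py_acc <- acc(py_acc, m, aw, at_risk)
        ev_acc <- acc(ev_acc, m, aw, ev_m)
      }
      assign(micro_map[[m]], s_m + ev_m)
    }

    # mortality, with case-fatality elevation in an event year; processed
    # last so the death year contributes a full person-year
    h_mort <- outcome_annual_hazard(eff, "mortality", risk_coeffs, vals) *
      mixture_corr("mortality")
    pb <- hazard_to_prob(h_mort)
    pcf <- hazard_to_prob(risk_coeffs$ascvd_case_fatality_hazard)
    if (stochastic) {
      p_death <- 1 - exp(-(h_mort + risk_coeffs$ascvd_case_fatality_hazard * ev_a))
      died <- as.numeric(u[, "mortality"] < p_death) * surv
      cvd_died <- died * ev_a
    } else {
      p_death <- pb + (1 - pb) * ev_a * pcf
      died <- surv * p_death
      cvd_died <- surv * (1 - pb) * ev_a * pcf
    }
    if (in_horizon) {
      py_acc <- acc(py_acc, "mortality", aw, 1)
      ev_acc <- acc(ev_acc, "mortality", aw,
                    if (stochastic) as.numeric(u[, "mortality"] < p_death) else p_death)
    }
    keep <- died > 0
    if (any(keep)) {
      deaths[[length(deaths) + 1L]] <- tibble(
        year = y, age = state$age[keep], weight = died[keep],
        cvd_weight = cvd_died[keep]
      )
    }

    # economic state totals for the year (death year counts in full)
    by_year[[y]] <- tibble(
      year = y, alive = sum(surv), deaths = sum(died),
      ascvd_events = sum(surv * ev_a),
      cvd_event_py = sum(surv * ev_a),
      esrd_py = sum(surv * s_esrd),
      neuropathy_py = sum(surv * s_neuro),
      retinopathy_py = sum(surv * s_retino),
      bp_tx_py = sum(surv * state$on_bp_treatment),
      dm_tx_py = sum(surv * state$on_diabetes_treatment),
      statin_py = sum(surv * state$on_statin),
      aid_recipient_py = sum(surv * rec)
    )
    surv <- surv - died

    if (!in_horizon && sum(surv) < 1e-6) break
    if (config$life_course && max(state$age) > 110 && y >= horizon) break

    # demography: ageing, secular trends, births (horizon years only)
    state$age <- state$age + 1
    state <- apply_secular_trends(state, config$secular_trends, years = 1)
    if (stochastic && in_horizon && config$birth_rate > 0) {
      n_births <- with_seed(child_seed(seed, paste0("births-", y)),
                            rbinom(1, round(sum(surv)), min(config$birth_rate, 1)))
      if (n_births > 0) {
        nb <- newborn_records(n_births, max(state$person_id) + 1L,
                              child_seed(seed, paste0("newborn-", y)))
        state <- bind_rows(state, nb)
        zero <- rep(0, n_births)
        surv <- c(surv, rep(1, n_births))
        htn_free <- c(htn_free, rep(1, n_births))
        dm_prob <- c(dm_prob, zero)
        cvd_free <- c(cvd_free, rep(1, n_births))
        s_esrd <- c(s_esrd, zero); s_neuro <- c(s_neuro, zero)
        s_retino <- c(s_retino, zero)
        rec <- c(rec, rep(FALSE, n_births))
        d <- bind_rows(d, tibble(energy = zero, sodium = zero, potassium = zero,
                                 sfa = zero, mufa = zero, pufa = zero, mds = zero))
        d_sbp <- c(d_sbp, zero); d_dbp <- c(d_dbp, zero)
        d_tc <- c(d_tc, zero); d_hdl <- c(d_hdl, zero)
      }
    }
  }

  by_outcome <- tibble(
    outcome = rep(outcomes, 2),
    aid = rep(c(TRUE, FALSE), each = length(outcomes)),
    events = c(ev_acc[, "aid"], ev_acc[, "no_aid"]),
    person_years = c(py_acc[, "aid"], py_acc[, "no_aid"])
  )
  state$alive <- surv > 0.5
  structure(list(
    by_outcome = by_outcome,
    by_year = list_rbind(by_year),
    deaths = if (length(deaths)) list_rbind(deaths) else
      tibble(year = integer(), age = numeric(), weight = numeric(),
             cvd_weight = numeric()),
    final_cohort = state,
    scenario_kind = scenario$kind, mode = mode, config = config,
    n0 = nrow(cohort), n_recipients0 = sum(cohort$receives_aid)
  ), class = "sim_ledger")
}

#' @export
print.sim_ledger <- function(x, ...) {
  cat(sprintf("<sim_ledger> scenario '%s' (%s), %d persons, %d-year horizon\n",
              x$scenario_kind, x$mode, x$n0, x$config$policy_horizon_years))
  print(ledger_rates(x, among_aid = FALSE))
  invisible(x)
}

#' Incidence rate per 1,000 person-years
#'
#' @param events Event count (>= 0).
#' @param person_years Person-years at risk (> 0).
#' @return `1000 * events / person_years`.
#' @examples
#' incidence_rate(658, 100000) # 6.58
#' @export
incidence_rate <- function(events, person_years) {
  if (any(person_years <= 0)) {
    abort_input("person_years must be positive: rate undefined")
  }
  1000 * events / person_years
}

#' Outcome rates from a simulation ledger
#'
#' @param ledger A `sim_ledger`.
#' @param among_aid If `TRUE`, restrict to aid recipients (the population the
#'   comparative results are reported for); if `FALSE`, the whole adult
#'   population.
#' @return Tibble with `outcome`, `events`, `person_years`, `rate` (per 1,000
#'   person-years).
#' @export
ledger_rates <- function(ledger, among_aid = TRUE) {
  tab <- ledger$by_outcome
  if (among_aid) tab <- filter(tab, .data$aid)
  tab |>
    group_by(.data$outcome) |>
    summarise(events = sum(.data$events),
              person_years = sum(.data$person_years), .groups = "drop") |>
    mutate(rate = incidence_rate(.data$events, .data$person_years)) |>
    arrange(match(.data$outcome, sim_outcomes()))
}

#' Compare two scenario ledgers
#'
#' Per-outcome incidence-rate differences (intervention minus baseline, per
#' 1,000 person-years) among aid recipients, the contrast the comparative
#' analyses report. Both ledgers must come from the same cohort and
#' configuration.
#'
#' @param baseline,intervention `sim_ledger` objects from [run_scenario()].
#' @return Tibble with `outcome`, `rate_baseline`, `rate_intervention`,
#'   `difference`.
#' @export
compare_scenarios <- function(baseline, intervention) {
  same <- baseline$n0 == intervention$n0 &&
    baseline$config$policy_horizon_years == intervention$config$policy_horizon_years &&
    baseline$config$seed == intervention$config$seed
  if (!same) abort_input("ledgers come from different cohorts or configurations")
  rb <- ledger_rates(baseline, among_aid = TRUE)
  ri <- ledger_rates(intervention, among_aid = TRUE)
  tibble(
    outcome = rb$outcome,
    rate_baseline = rb$rate,
    rate_intervention = ri$rate[match(rb$outcome, ri$outcome)]
  ) |>
    mutate(difference = .data$rate_intervention - .data$rate_baseline)
}

#' Serialize a ledger to JSON
#' @param ledger A `sim_ledger`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger_json <- function(ledger, path) {
  jsonlite::write_json(
    list(scenario = ledger$scenario_kind, mode = ledger$mode,
         n0 = ledger$n0, horizon = ledger$config$policy_horizon_years,
         seed = ledger$config$seed,
         by_outcome = ledger$by_outcome, by_year = ledger$by_year),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
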