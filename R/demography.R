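#' Default secular trends in biomarkers
#'
#' Annual linear drifts applied per age/sex stratum while the simulation
#' advances. The source cites national estimates without printing values;
#' these defaults are modest upward adult drifts consistent with regional
#' cardiometabolic surveillance, and are fully overridable.
#'
#' @return Tibble with columns `variable`, `sex` (`"male"`, `"female"` or
#'   `"all"`), `age_min`, `age_max`, `slope` (native units per year).
#' @export
default_secular_trends <- function() {
  tibble(
    variable = c("sbp", "dbp", "bmi", "a1c", "total_chol"),
    sex = "all",
    age_min = 20, age_max = 110,
    slope = c(0.20, 0.10, 0.05, 0.010, 0.005)
  )
}

#' Crude birth rate default
#'
#' Per-capita annual birth rate; regional UN estimates for this population
#' are near 28 per 1,000.
#' @return A single number (births per person-year).
#' @export
default_birth_rate <- function() 0.028

# a newborn record: reference pediatric physiology, no diagnoses
newborn_records <- function(n_births, id_start, seed) {
  female <- with_seed(seed, runif(n_births) < 0.488)
  height <- 0.50
  bmi <- 13.5
  tibble(
    person_id = id_start + seq_len(n_births) - 1L,
    age = 0, sex = ifelse(female, "female", "male"),
    location = "Jordan", receives_aid = FALSE,
    height = height, weight = bmi * height^2, bmi = bmi,
    sbp = 90, dbp = 55, total_chol = 3.0, hdl_chol = 1.2, a1c = 5.0,
    smoker = FALSE, serum_creatinine = 30, urine_acr = 1,
    on_bp_treatment = FALSE, on_diabetes_treatment = FALSE,
    on_statin = FALSE, on_anticoagulant = FALSE,
    has_diabetes = FALSE, has_hypertension = FALSE, cvd_history = FALSE,
    nephropathy = FALSE, neuropathy = FALSE, retinopathy = FALSE,
    alive = TRUE, frequency_weight = 1
  )
}

apply_secular_trends <- function(cohort, trends, years = 1) {
  if (is.null(trends) || nrow(trends) == 0 || years == 0) {
    return(cohort)
  }
  for (i in seq_len(nrow(trends))) {
    tr <- trends[i, ]
    idx <- cohort$alive &
      cohort$age >= tr$age_min & cohort$age <= tr$age_max &
      (tr$sex == "all" | cohort$sex == tr$sex)
    cohort[[tr$variable]][idx] <- cohort[[tr$variable]][idx] + tr$slope * years
  }
  if ("bmi" %in% trends$variable) {
    cohort$weight <- cohort$bmi * cohort$height^2
  }
  cohort
}

#' Advance cohort demography
#'
#' Ages the cohort year by year, applies secular biomarker trends to matching
#' age/sex strata, and adds new births at the configured per-capita rate
#' (binomial draws against the alive population each year).
#'
#' @param cohort Person-record tibble.
#' @param birth_rate Per-capita annual birth rate (>= 0).
#' @param secular_trends Trend table as in [default_secular_trends()]; `NULL`
#'   for none.
#' @param years Number of annual steps (`0` returns the cohort unchanged).
#' @param seed Integer seed for the birth draws.
#' @return The advanced cohort tibble (newborns appended at age reflecting
#'   their birth year).
#' @examples
#' cohort <- sample_refugee_cohort(50, seed = 1)
#' aged <- advance_demography(cohort, birth_rate = 0, secular_trends = NULL,
#'                            years = 1, seed = 1)
#' all(aged$age == cohort$age + 1)
#' @export
advance_demography <- function(cohort, birth_rate = default_birth_rate(),
                               secular_trends = default_secular_trends(),
                               years = 1, seed = 1L) {
  if (birth_rate < 0) abort_config("birth rate must be nonnegative")
  stopifnot_scalar_number(years, "years", min = 0)
  if (years == 0) {
    return(cohort)
  }
  for (y in seq_len(years)) {
    cohort$age[cohort$alive] <- cohort$age[cohort$alive] + 1
    cohort <- apply_secular_trends(cohort, secular_trends, years = 1)
    n_alive <- sum(cohort$alive)
    n_births <- with_seed(child_seed(seed, paste0("births-", y)),
                          rbinom(1, n_alive, min(birth_rate, 1)))
    if (n_births > 0) {
      nb <- newborn_records(n_births, max(cohort$person_id) + 1L,
                            child_seed(seed, paste0("newborn-", y)))
      nb$age <- years - y # age at the end of the advancement window
      cohort <- bind_rows(cohort, nb)
    }
  }
  cohort
}
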