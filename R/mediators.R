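#' Default mediator coefficients
#'
#' Point estimates with 95% intervals for every diet-to-biomarker pathway,
#' shipped as a tibble so each entry can be drawn in probabilistic
#' sensitivity analysis and overridden from YAML. Sources (documented per
#' entry in `provenance`):
#'
#' * Energy-balance constants for the two-compartment body-weight model:
#'   tissue energy densities 9,441 (fat) and 1,816 (lean) kcal/kg, marginal
#'   expenditure 3.2 (fat) and 22 (lean) kcal/kg/day, Forbes partition
#'   constant 10.4 kg, diet-induced/adaptive fraction 0.14 of the intake
#'   change, physical-activity cost 7 kcal/kg/day; quasi-static fallback
#'   steady-state cost 17.5 kcal/day per kg.
#' * Blood pressure: +2.11 mmHg per g/day sodium, −0.75 mmHg per g/day
#'   potassium (large prospective epidemiological study); DBP responds at
#'   half the SBP response (ratio of the reported DBP/SBP changes).
#' * Lipids, per 1% of energy substituted toward each fatty-acid class
#'   (meta-analysis of randomized feeding trials): total cholesterol +0.052
#'   (SFA), −0.006 (MUFA), −0.021 (PUFA) mmol/L; HDL +0.012, +0.008, +0.006.
#' * Glycemia: +0.10 A1c percentage points per kg/m² BMI; −0.05 per MDS
#'   point (meta-analyses of prospective studies).
#'
#' @return Tibble with columns `coefficient`, `estimate`, `conf_low`,
#'   `conf_high`, `provenance`. Constants have degenerate intervals.
#' @export
default_mediator_coefficients <- function() {
  tribble_row <- function(coefficient, estimate, conf_low, conf_high, provenance) {
    tibble(coefficient = coefficient, estimate = estimate,
           conf_low = conf_low, conf_high = conf_high, provenance = provenance)
  }
  out <- bind_rows(
    tribble_row("hall_rho_fat", 9441, 9441, 9441, "energy density of fat tissue, kcal/kg"),
    tribble_row("hall_rho_lean", 1816, 1816, 1816, "energy density of lean tissue, kcal/kg"),
    tribble_row("hall_gamma_fat", 3.2, 3.2, 3.2, "marginal expenditure of fat mass, kcal/kg/day"),
    tribble_row("hall_gamma_lean", 22, 22, 22, "marginal expenditure of lean mass, kcal/kg/day"),
    tribble_row("hall_forbes_c", 10.4, 10.4, 10.4, "Forbes lean/fat partition constant, kg"),
    tribble_row("hall_at_beta", 0.14, 0.14, 0.14, "adaptive/diet-induced fraction of intake change"),
    tribble_row("hall_activity_coef", 7, 7, 7, "weight-proportional activity cost, kcal/kg/day"),
    tribble_row("hall_rho_eff", 17.5, 17.5, 17.5, "quasi-static steady-state cost, kcal/day per kg"),
    tribble_row("na_sbp_slope", 2.11, 1.40, 2.82, "SBP change per g/day sodium, mmHg"),
    tribble_row("k_sbp_slope", -0.75, -1.29, -0.21, "SBP change per g/day potassium, mmHg"),
    tribble_row("sbp_interaction", 0, 0, 0, "extra sodium slope per 10 mmHg baseline SBP above 120"),
    tribble_row("dbp_fraction", 0.5, 0.5, 0.5, "DBP response as a fraction of SBP response"),
    tribble_row("tc_per_pctE_sfa", 0.052, 0.036, 0.068, "total cholesterol per %E SFA, mmol/L"),
    tribble_row("tc_per_pctE_mufa", -0.006, -0.012, 0.000, "total cholesterol per %E MUFA, mmol/L"),
    tribble_row("tc_per_pctE_pufa", -0.021, -0.030, -0.012, "total cholesterol per %E PUFA, mmol/L"),
    tribble_row("hdl_per_pctE_sfa", 0.012, 0.008, 0.016, "HDL per %E SFA, mmol/L"),
    tribble_row("hdl_per_pctE_mufa", 0.008, 0.004, 0.012, "HDL per %E MUFA, mmol/L"),
    tribble_row("hdl_per_pctE_pufa", 0.006, 0.002, 0.010, "HDL per %E PUFA, mmol/L"),
    tribble_row("a1c_per_bmi", 0.10, 0.05, 0.15, "A1c %-points per kg/m2 BMI"),
    tribble_row("a1c_per_mds", -0.05, -0.08, -0.02, "A1c %-points per MDS point")
  )
  validate_mediator_coefficients(out)
  out
}

#' Validate a mediator coefficient set
#'
#' Checks the structural constraints: intervals contain their point
#' estimates, the sodium slope is nonnegative, the potassium slope and the
#' diet-quality A1c coefficient are nonpositive.
#'
#' @param coeffs Coefficient tibble.
#' @return `coeffs` invisibly; aborts otherwise.
#' @export
validate_mediator_coefficients <- function(coeffs) {
  stopifnot(all(c("coefficient", "estimate", "conf_low", "conf_high") %in% names(coeffs)))
  if (any(coeffs$conf_low > coeffs$estimate | coeffs$estimate > coeffs$conf_high)) {
    abort_config("mediator coefficient intervals must contain their point estimates")
  }
  if (coef_value(coeffs, "na_sbp_slope") < 0) abort_config("na_sbp_slope must be >= 0")
  if (coef_value(coeffs, "k_sbp_slope") > 0) abort_config("k_sbp_slope must be <= 0")
  if (coef_value(coeffs, "a1c_per_mds") > 0) abort_config("a1c_per_mds must be <= 0")
  invisible(coeffs)
}

coef_value <- function(coeffs, name) {
  i <- match(name, coeffs$coefficient)
  if (is.na(i)) abort_config(sprintf("coefficient '%s' not found", name))
  coeffs$estimate[i]
}

#' Draw mediator coefficients from their uncertainty distributions
#'
#' Each coefficient with a non-degenerate interval is redrawn from a normal
#' with `sd = (conf_high - conf_low) / (2 * 1.96)`; constants pass through.
#' Over many draws the empirical 2.5/97.5 percentiles reproduce the
#' configured intervals.
#'
#' @param coeffs Coefficient tibble ([default_mediator_coefficients()]).
#' @param seed Integer seed.
#' @return The tibble with redrawn `estimate` values.
#' @export
draw_mediator_coefficients <- function(coeffs = default_mediator_coefficients(),
                                       seed = 1L) {
  sd <- (coeffs$conf_high - coeffs$conf_low) / (2 * qnorm(0.975))
  z <- with_seed(seed, rnorm(nrow(coeffs)))
  coeffs$estimate <- coeffs$estimate + sd * z
  coeffs
}

#' Read / write mediator coefficients as YAML
#' @param path File path.
#' @return A coefficient tibble / `path` invisibly.
#' @export
read_mediator_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list_rbind(imap(raw, function(e, nm) {
    tibble(coefficient = nm, estimate = e$estimate,
           conf_low = e$conf_low %||% e$estimate,
           conf_high = e$conf_high %||% e$estimate,
           provenance = e$provenance %||% "")
  }))
  validate_mediator_coefficients(out)
  out
}

#' @rdname read_mediator_yaml
#' @param coeffs Coefficient tibble.
#' @export
write_mediator_yaml <- function(coeffs, path) {
  entries <- lapply(seq_len(nrow(coeffs)), function(i) {
    list(estimate = coeffs$estimate[i], conf_low = coeffs$conf_low[i],
         conf_high = coeffs$conf_high[i], provenance = coeffs$provenance[i])
  })
  yaml::write_yaml(setNames(entries, coeffs$coefficient), path)
  invisible(path)
}

# Deurenberg estimate of body-fat fraction from BMI, age, sex
body_fat_fraction <- function(bmi, age, male) {
  pmin(pmax((1.20 * bmi + 0.23 * age - 10.8 * male - 5.4) / 100, 0.05), 0.60)
}

#' Body-weight dynamics parameters for a person
#'
#' Linearizes the two-compartment energy-balance model at the person's
#' initial body composition (fat mass from a BMI/age/sex regression, lean/fat
#' partition from the Forbes relationship held at its initial value). The
#' weight response to a sustained intake change `dI` is then a single
#' exponential: `dw(t) = dw_ss * (1 - exp(-t / tau))` with
#' `dw_ss = (1 - beta) * dI / lambda`, `tau = rho_bar / lambda`, where
#' `lambda` is the marginal energy expenditure per kg of weight change and
#' `rho_bar` the composition-weighted tissue energy density.
#'
#' @param person Person tibble (needs `age`, `sex`, `height`, `weight`).
#' @param coeffs Mediator coefficients.
#' @return Tibble with `lambda` (kcal/day/kg), `rho_bar` (kcal/kg),
#'   `tau_days`, and `fat_fraction`.
#' @export
hall_dynamics <- function(person, coeffs = default_mediator_coefficients()) {
  if (any(person$height <= 0)) abort_input("height must be positive")
  male <- as.numeric(person$sex == "male")
  bmi <- person$weight / person$height^2
  ff <- body_fat_fraction(bmi, person$age, male)
  fat_mass <- ff * person$weight
  cc <- coef_value(coeffs, "hall_forbes_c")
  p_lean <- cc / (cc + fat_mass) # share of a weight change going to lean mass
  lambda <- p_lean * coef_value(coeffs, "hall_gamma_lean") +
    (1 - p_lean) * coef_value(coeffs, "hall_gamma_fat") +
    coef_value(coeffs, "hall_activity_coef")
  rho_bar <- p_lean * coef_value(coeffs, "hall_rho_lean") +
    (1 - p_lean) * coef_value(coeffs, "hall_rho_fat")
  tibble(lambda = lambda, rho_bar = rho_bar, tau_days = rho_bar / lambda,
         fat_fraction = ff)
}

#' BMI change from a sustained energy-intake change
#'
#' The dynamic method evaluates the linearized energy-balance trajectory at
#' the horizon (saturating toward its steady state); the quasi-static method
#' applies the configured steady-state energy cost per kg directly
#' (`dw = delta_energy / hall_rho_eff`), which is the model's equilibrium
#' reduction and is useful for fast approximate runs.
#'
#' @param delta_energy Sustained intake change, kcal/day (vector or scalar).
#' @param person Person tibble (`age`, `sex`, `height`, `weight`).
#' @param horizon Years since the intake change began (> 0).
#' @param coeffs Mediator coefficients.
#' @param method `"dynamic"` (default) or `"quasistatic"`.
#' @return Numeric vector of BMI changes, kg/m².
#' @examples
#' p <- tibble::tibble(age = 40, sex = "female", height = 1.6, weight = 75)
#' bmi_change_from_energy(-33, p, horizon = 10)
#' @export
bmi_change_from_energy <- function(delta_energy, person, horizon = 10,
                                   coeffs = default_mediator_coefficients(),
                                   method = c("dynamic", "quasistatic")) {
  method <- match.arg(method)
  if (any(horizon <= 0)) abort_input("horizon must be positive")
  if (any(person$height <= 0)) abort_input("height must be positive")
  if (method == "quasistatic") {
    dw <- delta_energy / coef_value(coeffs, "hall_rho_eff")
  } else {
    dyn <- hall_dynamics(person, coeffs)
    dw_ss <- (1 - coef_value(coeffs, "hall_at_beta")) * delta_energy / dyn$lambda
    dw <- dw_ss * (1 - exp(-(horizon * 365.25) / dyn$tau_days))
  }
  dw / person$height^2
}

#' Blood-pressure change from sodium and potassium changes
#'
#' `dSBP = na_sbp_slope * dNa(g) + k_sbp_slope * dK(g)`, plus an optional
#' baseline-SBP interaction (`sbp_interaction` per 10 mmHg above 120);
#' `dDBP = dbp_fraction * dSBP`.
#'
#' @param delta_na,delta_k Intake changes in mg/day.
#' @param person Optional person tibble with baseline `sbp` (needed only when
#'   `sbp_interaction` is nonzero).
#' @param coeffs Mediator coefficients.
#' @return Tibble with columns `sbp` and `dbp` (mmHg changes).
#' @examples
#' sbp_dbp_change(1000, 0) # +2.11 mmHg SBP at the default slope
#' @export
sbp_dbp_change <- function(delta_na, delta_k, person = NULL,
                           coeffs = default_mediator_coefficients()) {
  na_g <- delta_na / 1000
  k_g <- delta_k / 1000
  slope <- coef_value(coeffs, "na_sbp_slope")
  inter <- coef_value(coeffs, "sbp_interaction")
  if (inter != 0) {
    if (is.null(person)) abort_input("person with baseline sbp required for interaction term")
    slope <- slope + inter * (person$sbp - 120) / 10
  }
  dsbp <- slope * na_g + coef_value(coeffs, "k_sbp_slope") * k_g
  tibble(sbp = dsbp, dbp = coef_value(coeffs, "dbp_fraction") * dsbp)
}

#' Cholesterol change from fatty-acid intake changes
#'
#' Fatty-acid changes (mg/day) are converted to percent of energy at 9 kcal/g
#' against the person's current total energy, then passed through the linear
#' substitution matrix.
#'
#' @param delta_sfa,delta_mufa,delta_pufa Changes in mg/day.
#' @param total_energy Current total energy intake, kcal/day (> 0).
#' @param coeffs Mediator coefficients.
#' @return Tibble with columns `total_chol` and `hdl_chol` (mmol/L changes).
#' @export
lipid_change <- function(delta_sfa, delta_mufa, delta_pufa, total_energy,
                         coeffs = default_mediator_coefficients()) {
  if (any(total_energy <= 0)) abort_input("total_energy must be positive")
  pctE <- function(mg) 100 * (mg / 1000 * 9) / total_energy
  e_sfa <- pctE(delta_sfa); e_mufa <- pctE(delta_mufa); e_pufa <- pctE(delta_pufa)
  tibble(
    total_chol = coef_value(coeffs, "tc_per_pctE_sfa") * e_sfa +
      coef_value(coeffs, "tc_per_pctE_mufa") * e_mufa +
      coef_value(coeffs, "tc_per_pctE_pufa") * e_pufa,
    hdl_chol = coef_value(coeffs, "hdl_per_pctE_sfa") * e_sfa +
      coef_value(coeffs, "hdl_per_pctE_mufa") * e_mufa +
      coef_value(coeffs, "hdl_per_pctE_pufa") * e_pufa
  )
}

#' Hemoglobin A1c change from BMI and diet-quality changes
#'
#' `a1c_per_bmi * dBMI + a1c_per_mds * dMDS`; the MDS coefficient is
#' constrained nonpositive (better diet quality lowers A1c).
#'
#' @param delta_bmi BMI change, kg/m².
#' @param delta_mds MDS change, points.
#' @param coeffs Mediator coefficients.
#' @return Numeric vector of A1c changes, percentage points.
#' @export
a1c_change <- function(delta_bmi, delta_mds,
                       coeffs = default_mediator_coefficients()) {
  coef_value(coeffs, "a1c_per_bmi") * delta_bmi +
    coef_value(coeffs, "a1c_per_mds") * delta_mds
}
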