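# shared fixtures: small cohorts and fast configurations used across files

tiny_cohort <- function(n = 300, seed = 11) {
  sample_refugee_cohort(n, seed = seed)
}

fast_config <- function(years = 5, seed = 7, ...) {
  sim_config(policy_horizon_years = years, seed = seed, birth_rate = 0, ...)
}

# a single middle-aged reference person for mediator checks
ref_person <- function() {
  tibble::tibble(age = 45, sex = "female", height = 1.60, weight = 75,
                 sbp = 125, dbp = 78)
}

# person deltas with a single nonzero pathway, for engine-level mediation
# checks (shape matches the engine's internal per-person delta structure)
pure_delta_set <- function(cohort, sodium = 0, energy = 0) {
  n <- nrow(cohort)
  rec <- cohort$receives_aid
  zero <- rep(0, n)
  d <- tibble::tibble(energy = zero + energy * rec, sodium = zero + sodium * rec,
                      potassium = zero, sfa = zero, mufa = zero, pufa = zero,
                      mds = zero)
  bp <- sbp_dbp_change(d$sodium, d$potassium)
  lip <- lipid_change(d$sfa, d$mufa, d$pufa, rep(2296, n))
  list(deltas = d, d_sbp = bp$sbp, d_dbp = bp$dbp,
       d_tc = lip$total_chol, d_hdl = lip$hdl_chol,
       baseline_energy = rep(2296, n), baseline_mds = rep(8, n))
}
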