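# foodaidsim

Individual-level microsimulation of how the *delivery mechanism* of food aid
— a traditional in-kind parcel, a restricted electronic debit card
(e-voucher), unrestricted cash, or an alternative parcel with less grain and
more fruits and vegetables — shapes nutrient intake, cardiometabolic
biomarkers, chronic-disease incidence, mortality, and cost-effectiveness in a
long-term refugee population. It is written for epidemiologists and
health-economics modellers who want to interrogate or extend the model:
every input (marginal summaries, correlation structure, nutrient densities,
mediator coefficients, risk equations, costs, utilities) is a tibble or YAML
config that can be replaced.

## The model

The simulation has three linked components:

1. **Synthetic population.** No individual-level microdata are shipped;
   cohorts are generated by Gaussian-copula sampling from published summary
   statistics (means, IQRs, prevalences, by sex where published). For a
   rank-correlation matrix R and fitted marginals F_j, draws are
   z ~ N(0, Σ) with Σ = 2 sin(π R / 6), x_j = F_j⁻¹(Φ(z_j)), which
   reproduces each marginal and the rank-correlation structure.
2. **Diet → biomarkers.** An aid scenario perturbs household food-group
   intake (kcal/person/day over six FAO groups). Four mediators carry the
   change to biomarkers: total energy → BMI through a linearized
   two-compartment energy-balance model (Δw(t) = Δw_ss (1 − e^(−t/τ)));
   sodium and potassium → systolic/diastolic pressure through linear slopes
   (mmHg per g/day); fatty-acid classes → total and HDL cholesterol through
   a per-%-energy substitution matrix; and BMI plus a 0–14 Mediterranean
   Dietary Score → HbA1c.
3. **Risk engine and economics.** Annual probabilities come from
   proportional-hazards equations (p = 1 − e^(−s·h₀·e^(βᵀx))) whose baseline
   hazards are recalibrated so the simulated baseline matches observed rates
   (hypertension 35.06, diabetes 12.24, ASCVD 6.58, ESRD 1.56, neuropathy
   4.41, retinopathy 4.53, mortality 3.50 per 1,000 person-years). Events,
   person-years, deaths, costs and disability accumulate in a ledger;
   discounted (3%/yr) costs and DALYs give ICERs; probabilistic sensitivity
   analysis redraws every parameter with a 95% interval.

## Worked example

```r
library(foodaidsim)

cohort <- sample_refugee_cohort(5000, seed = 1)
round(100 * mean(cohort$has_diabetes), 1)     # 12.7  (% with type 2 diabetes)
round(100 * mean(cohort$sex == "female"), 1)  # 60.8  (% female)

coeffs <- recalibrate_baseline_hazard(default_risk_coefficients(),
                                      default_calibration_targets(), cohort,
                                      seed = 1, years = 10)
cfg  <- sim_config(policy_horizon_years = 10, seed = 1)
base <- run_scenario(cohort, aid_scenario("traditional"), cfg, risk_coeffs = coeffs)
alt  <- run_scenario(cohort, aid_scenario("alternative_parcel"), cfg, risk_coeffs = coeffs)
compare_scenarios(base, alt)
#>        outcome rate_baseline rate_intervention difference
#> 1 hypertension         33.85             32.05     -1.798
#> 2     diabetes         12.01              9.24     -2.771
#> 3        ascvd          7.56              6.57     -0.992
#> 4         esrd          1.52              0.55     -0.974
#> 5   neuropathy          8.53              5.33     -3.205
#> 6  retinopathy          6.69              6.06     -0.625
#> 7    mortality          3.83              3.40     -0.438

cea_compare(base, alt, perspective = "societal")$icer
#>   delta_cost dalys_averted icer usd_per_daly                                 label
#> 1   -2971567          6460 -460          460 dominant, $460 saved per DALY averted
```

Rates are incidence per 1,000 person-years among aid recipients; the
comparison says the alternative parcel (grain −40, fruits and vegetables +7
kcal/person/day, budget-neutral) lowers every outcome at this cohort size,
and the cost-effectiveness comparison labels it dominant — it both saves
money (negative incremental cost) and averts DALYs. Magnitudes at a
5,000-person desk run carry Monte Carlo and stand-in-coefficient
uncertainty; see the methods vignette for what is and is not identifiable
from published summaries.

Other entry points: `generate_household_consumption()` (per-arm intake
distributions), `nutrients_from_intake()` (nutrient profiles with bootstrap
intervals), `mds_score()`, `threshold_search()` (smallest budget-neutral
grain diversion that lowers every outcome), `enhanced_budget_search()`
(budget increase for a +1.0 diet-score gain), `run_comparison_suite()`
(consumption/biomarker/outcome contrast tables with PSA intervals), and
`uncertainty_run()`.

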