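---
title: "Model and methods: food-aid delivery and cardiometabolic disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: food-aid delivery and cardiometabolic disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodaidsim)
```

`foodaidsim` is a discrete-time, individual-level microsimulation of a
long-settled refugee population in which grain-based food aid coexists with a
high burden of type 2 diabetes and cardiovascular disease. It asks what
happens to nutrient intake, biomarkers, chronic-disease incidence, mortality
and costs when the aid delivery mechanism changes — to a restricted
electronic debit card, to cash, or to an alternative parcel that trades grain
for fruits and vegetables at equal budget. This vignette documents the model,
its assumptions, the calibration choices, and what the shipped defaults can
and cannot claim.

## 1. Synthetic population

No individual-level records are shipped or required. Cohorts come from a
Gaussian copula over published summary statistics: each variable gets a
parametric marginal fitted to its published mean and IQR (or prevalence),
a Spearman rank-correlation matrix describes dependence, latent normal draws
with Pearson correlation $2\sin(\pi\rho_s/6)$ are transformed through each
marginal's quantile function.

**Marginal families.** Blood pressures, cholesterol and heights are normal
(mean exact, sd from the IQR width). Right-skewed quantities — intake,
creatinine, albumin/creatinine ratio, BMI, age, A1c among the diagnosed —
are lognormal. Two lognormal fitting strategies exist because published
mean/IQR pairs are often not jointly attainable:

* *quartile-ratio* (default): spread from $\log(q_{75}/q_{25})$, location
  set so the arithmetic mean is exact; the achieved IQR deviates when the
  pair is non-lognormal and the deviation is recorded (`iqr_rel_err`).
* *lower-anchored* (used for household intake): mean and lower quartile
  exact. The intake summaries are extremely dispersed (cereals mean 1,239
  with IQR 147–2,331 kcal/person/day); a quartile-ratio fit puts ~25% of
  households below 40 kcal/day of cereals, which would let a −40 kcal parcel
  change truncate heavily. Anchoring the lower quartile keeps the left tail
  honest where scenario deltas and food-security floors act.

Age is additionally capped at 105 years with its location parameter solved
so the capped mean still equals the published mean (an uncapped lognormal
fit puts several percent of mass above the cap).

**Sex- and status-conditional structure.** Biomarkers published separately
by sex (BMI, pressures, cholesterol) enter the copula as standard-normal
scores and are transformed conditional on sex, preserving the correlation
structure. A1c uses the published distribution among persons with diagnosed
diabetes and a narrower normoglycemic distribution (mean 5.4, IQR 5.1–5.7, a
stand-in — undiagnosed-population A1c is unpublished) otherwise; because the
A1c score correlates with diabetes status, its uniform is taken as the
within-group rank so the diagnosed-group marginal is exact. Treatment flags
are conditional (diabetes treatment 86% of the diagnosed; antihypertensives
84.9% of those meeting the hypertension criteria), as are complication
prevalences among the diagnosed.

**The correlation matrix is a stand-in.** The source's empirical covariance
is unpublished; the default uses modest physiological correlations (age with
blood pressure and diabetes, adiposity with glycemia, SBP with DBP, renal
markers with each other) and is repaired to positive semidefiniteness by
eigenvalue clipping at 1e-8. Every test that passes on this cohort therefore
validates the *machinery* (marginal recovery, rank-correlation recovery,
determinism) — not the claim that the joint distribution matches the real
population.

## 2. Diet: intake, nutrients, diet quality

Intake is kcal/person/day over the six FAO food groups (cereals;
tubers/pulses/legumes/nuts; fruits and vegetables; animal products; added
oils and fats; sugars). The nutrient-density table (mg/kcal for sodium,
potassium, SFA, MUFA, PUFA; energy-share fractions for protein and fat)
starts from typical food-composition values and is rescaled per nutrient so
the traditional-arm mean intake reproduces the published population
baselines exactly (Na 4,288; K 3,834; SFA 26,124; MUFA 28,567; PUFA 26,871
mg/day). This makes the published baselines — not any specific database
release — the ground truth; bootstrap intervals redraw densities from their
configured variation.

**Mediterranean Dietary Score.** The score is 0–14 with 14 binary
components over the six groups (tiered fruit/vegetable and legume adequacy,
staple, animal and energy adequacy; moderation limits on sugars, oils,
refined cereals and the sugar share of energy), each worth 1 point and 0.5
within 10% of its cutpoint, so scores move on a half-point grid and an empty
diet scores zero. The component definitions used by the source are
unpublished, so the cutpoints are declared calibration values with two
anchors: the traditional-arm mean intake scores 8.0 (the grid point nearest
the arm-level baseline of 7.9) and the mean score over sampled
traditional-arm households equals 7.9. The energy-adequacy cutpoint (900
kcal/day) was the final closing knob. The classic 9-point score is
deliberately not used. The score is monotone nondecreasing in fruits and
vegetables, which is what the scenario analyses exercise.

**Scenarios.** Additive scenarios shift grain and fruit/vegetable kcal;
override scenarios replace the intake draw with one from an empirical arm
distribution. The cash arm has no published food-group table, only nutrient
deltas; it is modelled as the debit-card distribution shifted by +93
kcal/day (the published cash-minus-debit energy difference) allocated across
groups proportional to debit-card means. The debit-card group means follow
the results-section component breakdown, whose sum (2,441) matches the
published total; the summary table's debit rows sum differently and supply
only dispersion. At the household level, additive deltas are truncated at
zero (a low-reporting household cannot shed the full grain reduction), which
costs about 1 kcal of the −33 kcal/day mean alternative-parcel change;
misreporting corrections (e.g. fruit/vegetable overreporting of 257.5
kcal/day) truncate the same way.

## 3. Mediators

Four pathways translate sustained intake changes into biomarker changes,
re-evaluated annually against the scenario's sustained delta (the source
does not state once-versus-annually; annual re-evaluation is the documented
choice and matters only for the saturating weight pathway):

* **Energy → BMI.** A two-compartment (fat/lean) energy-balance model
  linearized at the person's initial composition: fat mass from a
  BMI/age/sex regression, the lean/fat partition from the Forbes
  relationship held at its initial value. The response to a sustained
  change $\Delta I$ is $\Delta w(t) = \Delta w_{ss}(1 - e^{-t/\tau})$ with
  $\Delta w_{ss} = (1-\beta)\Delta I/\lambda$ and $\tau = \bar\rho/\lambda$,
  where $\lambda$ (kcal/day per kg) collects tissue maintenance and
  weight-proportional activity costs and $\bar\rho$ is the
  composition-weighted tissue energy density. Defaults give time constants
  around 1.3–1.5 years and steady states near $\Delta I/17.5$ kg. The
  linearization is what makes the closed form exact; the test suite checks
  it against numerical integration (deSolve) and its analytic steady state
  to 0.1% at ten time constants. A quasi-static variant applies the
  steady-state cost directly. Conditioning is on age, sex, height and
  starting weight, as the underlying model family requires.
* **Na/K → blood pressure.** +2.11 mmHg SBP per g/day sodium, −0.75 per
  g/day potassium (point estimates with 95% CIs from the large prospective
  epidemiology literature); DBP responds at half the SBP response, the
  ratio of the published DBP/SBP changes. An optional baseline-SBP
  interaction slope ships disabled.
* **Fatty acids → cholesterol.** Deltas in mg/day are converted to percent
  of energy at 9 kcal/g against the person's current total energy, then
  multiplied through a substitution matrix (total cholesterol +0.052 /
  −0.006 / −0.021 mmol/L per %E for SFA/MUFA/PUFA; HDL +0.012 / +0.008 /
  +0.006), the meta-analytic feeding-trial values.
* **BMI + MDS → A1c.** +0.10 %-points per kg/m² and −0.05 per MDS point,
  with CIs.

All four return exactly zero for zero input, so a null scenario propagates
to zero outcome difference. Every coefficient carries a 95% interval and is
redrawn in probabilistic sensitivity analysis (normal, sd = CI width /
3.92); constants have degenerate intervals.

## 4. Risk engine

Seven outcomes: hypertension and type 2 diabetes incidence, first
atherosclerotic cardiovascular events, three microvascular complications
(ESRD, neuropathy, retinopathy), and all-cause mortality. All are
proportional-hazards forms $p = 1 - \exp(-s\,h_0 e^{\beta^\top x})$ with
per-outcome calibration scale $s$; cardiovascular events use a per-location
baseline hazard and the classic covariate set (age, sex, smoking, diabetes,
SBP, total cholesterol); the complication and mortality equations use the
diabetes-complication covariates (A1c, pressure, renal markers, treatment
flags). The exact transcribed coefficient values from the relevant
supplements are not republished; the shipped defaults carry the sources'
signs and plausible magnitudes, are fully overridable from YAML, and the
baseline *level* is always recalibrated, so results lean on the calibration
targets rather than the coefficient stand-ins.

**Status versus hazard incidence.** Hypertension and diabetes status are
classifier-defined (SBP ≥ 130 or DBP ≥ 80 or treatment; A1c ≥ 6.5 or
treatment — plasma-glucose criteria are out of the data model). Incidence
counts a previously negative person the first year the classifier trips
(biomarker drift plus scenario effects) *or* a calibrated incidence hazard
fires; the hazard covariates include the distance of the biomarkers from
the thresholds, so diet-mediated changes propagate. A pure
classifier-crossing model cannot be recalibrated to the observed incidence
(secular drift alone fixes its level), which is why the hazard channel
exists.

**Microvascular risks apply only to the diabetic pool** (the equations
derive from type 2 diabetes cohorts); non-diabetics contribute zero.
Reported rates use the at-risk denominator (diabetic and complication-free
person-years); whole-population person-years are also on the ledger.
Baseline ESRD prevalence is taken as zero (the summary reports nephropathy,
a milder state, which seeds the *risk* covariates, not the ESRD state).

**Recalibration.** `recalibrate_baseline_hazard()` matches each outcome's
simulated baseline rate to its target by a monotone proportional search on
the calibration scale (the achieved rate is increasing and near-proportional
in the scale; tolerance 1e-3 on the rate ratio, bounds 1e-4 to 1e4, an
unreachable target aborts naming the outcome). The objective is evaluated
with the *expectation mode* of the same annual engine: Bernoulli draws
replaced by their expectations, survival and state probabilities propagated
per person. Because outcomes interact (the cardiovascular scale feeds
event-year case fatality into mortality; the diabetes scale shapes the
microvascular pools), the search makes two Gauss–Seidel sweeps over the
outcome list, mortality first. In expectation mode, hazard terms over
fractional status probabilities use the exact mixture expectation
$E[e^{bD}] = 1-p+pe^{b}$ rather than $e^{bp}$ — without it the stochastic
engine sits a few percent above the expectation-calibrated targets.

## 5. Simulation engine

Annual cycle, fixed order: intake → mediators → biomarkers → incidence
classifiers → events → mortality → demography. Conventions, each a
documented choice where the source is silent:

* Deaths are processed last, so the death year contributes a full
  person-year.
* Only persons aged 20–79 contribute to outcome numerators and
  denominators; births enter at age 0 (binomial at the configured crude
  birth rate, 28/1,000 by default) and age forward.
* Secular biomarker trends (per age/sex stratum, modest upward adult drifts
  by default; the cited national estimates are unpublished) apply to
  everyone each year.
* Common random numbers: event uniforms are indexed by (seed, person, year,
  outcome) and are scenario-independent by default, so a null scenario
  reproduces the baseline ledger bit for bit and scenario contrasts are
  variance-reduced. Comparative results are reported among aid recipients.
* Horizon-average rates are reported (per-year trajectories are on the
  ledger).

## 6. Economics

Costs (2017 USD) and DALYs are discounted at 3%/year at annual boundaries
(year 1 undiscounted) and normalized per 100,000 baseline population. YLD
applies the published disutilities (cardiovascular event 0.28 for one year
per event; ESRD 0.57, neuropathy 0.10, retinopathy 0.19 persisting until
death). YLL converts each death into discounted remaining life expectancy
from a reference table; the source cites no table, so the default is a
linear stand-in (86.6 years at birth, floor 2) and configurable. YLL is
attributed to cardiovascular disease for deaths in an event year. Healthcare
costs price treatment person-years and event/state management at the
published unit costs; the societal perspective adds food-aid outlays accrued
per *enrolled* recipient over the policy horizon (program size is fixed by
enrollment, not vital status), which is what makes equal-budget scenarios
cancel exactly. Post-horizon accrual is analytic through the YLL table
rather than simulated person-by-person; within-horizon YLD therefore
understates lifetime YLD for chronic states — a known limitation that
affects level, not scenario contrasts, much less.

## 7. Scenario analyses

**Budget model.** The published input is a procurement cost *ratio* (fruits
and vegetables 0.58 per pound of grain-equivalent spending). Converting to
per-kcal costs needs energy densities; the defaults (grain 1,652 kcal/lb —
wheat flour; mixed fruits and vegetables 168 kcal/lb; grain parcel 470.6
kcal/person/day) are calibration values chosen so the default budget-neutral
diversion reproduces the published exchange: diverting 8.5% of the grain
parcel removes 40 and adds 7 kcal/person/day. Whether the published 8.5%
means a kcal, mass or budget share is ambiguous; here the diversion fraction
is defined on the grain parcel's budget (equivalently kcal, since grain is
homogeneous in the model), and fruit/vegetable buy-back is exactly
cost-neutral, so the parcel cost identity holds to well under a cent per
month at every fraction.

**Threshold search** scans diversion fractions (coarse grid, then
refinement to 0.001) for the smallest fraction at which every outcome's
rate change versus the traditional parcel is negative (upper 95% bound with
parameter draws, point estimate without), and the mean diet still clears
the WHO/FAO floors — strictly above 2,100 kcal/person/day, 10% protein and
17% fat energy, tested on the lower bootstrap bound. The outcome conditions
are evaluated with the expectation engine so the search is deterministic at
a given draw set.

**Enhanced budget search** bisects the budget-increase fraction until the
mean household MDS gain reaches the target (+1.0 by default); extra funds
buy fruits and vegetables at the budget model's per-kcal cost, on top of
the alternative-parcel exchange. The budget base is parcel food material
plus the published extra fruit-and-vegetable handling overhead, excluding
base overhead — the base against which the published percentage increase is
expressed. Infeasibility beyond a 10× multiplier is reported, not forced.

**Uncertainty.** `uncertainty_run()` redraws every parameter carrying a 95%
interval — mediator coefficients (normal), nutrient densities (truncated
normal), disutilities (normal truncated to [0,1]), costs (lognormal when the
interval is strictly positive and right-skewed, otherwise truncated normal)
— and summarizes percentile intervals. The desk-scale default is 500 draws;
the full analysis uses 10,000.

## 8. Numerical choices and problem sizes

Copula uniforms are clamped to [1e-12, 1 − 1e-12] before quantile
transforms; non-PSD correlation inputs are repaired by eigenvalue clipping
at 1e-8 with renormalized diagonal; calibration tolerance is 1e-3 on the
rate ratio; the threshold grid refines to 0.001; ICER with a zero DALY
difference is an error, and cost-saving DALY-averting results are labelled
dominant. Degenerate inputs (empty intake, zero person-years, zero aid
budget, zero calibration target) error or report infeasibility explicitly.

The test suite exercises the generator at up to 50,000 persons (marginal and
correlation recovery, calibration closure over a 10-year horizon) and uses
cohorts of 300–8,000 for behavioural and property tests; the acceptance
script simulates 50,000 persons for 10 years. These sizes make the
statistical checks (3 Monte Carlo SEs; 5% calibration closure) sharp while
keeping a full run near a minute on one CPU.

## 9. What passing tests do and do not show

The generator reproduces published *marginals* and a plausible dependence
structure — not the unpublished joint distribution; the comparative debit
and cash results inherit the very wide published intake dispersion and are
dominated by it, as the wide published intervals for those arms suggest
they should be. Risk-equation coefficients are stand-ins pending the exact
transcribed values, with levels pinned by calibration. The alternative-
parcel analyses are the most identifiable from published inputs: the parcel
exchange, its nutrient and compensatory arithmetic, budget neutrality and
the direction of every outcome change follow from quantities that are fully
specified here.
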