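# a hand-built ledger at n0 = 100,000 so per-100,000 normalization is the
# identity: one ESRD person-year in year 1, one cardiovascular event, one
# death at age 60 in year 1, one treated person-year of each therapy
unit_ledger <- function() {
  structure(list(
    by_year = tibble::tibble(
      year = 1, alive = 100000, deaths = 1, ascvd_events = 1,
      cvd_event_py = 1, esrd_py = 1, neuropathy_py = 1, retinopathy_py = 1,
      bp_tx_py = 1, dm_tx_py = 1, statin_py = 1, aid_recipient_py = 43000
    ),
    deaths = tibble::tibble(year = 1, age = 60, weight = 1, cvd_weight = 1),
    by_outcome = tibble::tibble(),
    scenario_kind = "traditional", mode = "expected",
    config = sim_config(policy_horizon_years = 1), n0 = 100000,
    n_recipients0 = 43000
  ), class = "sim_ledger")
}

test_that("discounting follows the closed form and composes multiplicatively", {
  expect_equal(discount(100, 0, 0.03), 100)
  expect_equal(discount(103, 1, 0.03), 100)
  expect_equal(discount(100, 2, 0.03), 94.2596, tolerance = 1e-4)
  set.seed(1)
  for (i in 1:20) {
    a <- runif(1, 1, 1000); t1 <- runif(1, 0, 20); t2 <- runif(1, 0, 20)
    expect_equal(discount(a, t1 + t2), discount(discount(a, t1), t2),
                 tolerance = 1e-9)
  }
})

test_that("DALY accrual applies disutility weights and reference life expectancy", {
  led <- unit_ledger()
  d <- accrue_dalys(led, discount_rate = 0) # year 1 undiscounted
  expect_equal(d$yld[d$component == "esrd"], 0.57)
  expect_equal(d$yld[d$component == "cvd_event"], 0.28)
  expect_equal(d$yld[d$component == "neuropathy"], 0.10)
  expect_equal(d$yld[d$component == "retinopathy"], 0.19)
  # the age-60 cardiovascular death contributes its remaining life expectancy
  expect_equal(d$yll[d$component == "cvd_event"], 86.6 - 60)
  # component additivity: daly = yld + yll row-wise
  expect_equal(d$daly, d$yld + d$yll)
  # empty ledger accrues nothing
  empty <- unit_ledger()
  empty$by_year[, -1] <- 0
  empty$deaths <- empty$deaths[0, ]
  d0 <- accrue_dalys(empty)
  expect_equal(sum(d0$daly), 0)
})

test_that("cost accrual prices states and events at the published unit costs", {
  led <- unit_ledger()
  hc <- accrue_costs(led, discount_rate = 0)
  expect_equal(hc$cost[hc$item == "esrd_management"], 14128.68)
  expect_equal(hc$cost[hc$item == "ascvd_event_management"], 11663.46)
  expect_equal(hc$cost[hc$item == "bp_treatment"], 6.42)
  expect_equal(hc$cost[hc$item == "diabetes_treatment"], 14.14)
  expect_equal(hc$cost[hc$item == "lipid_treatment"], 5.96)
  # societal nests healthcare whenever food-aid costs are nonnegative
  soc <- accrue_costs(led, perspective = "societal", discount_rate = 0)
  expect_gte(sum(soc$cost), sum(hc$cost))
  expect_equal(sum(soc$cost) - sum(hc$cost),
               43000 * 12 * (37 + 11.5), tolerance = 1e-6)
})

test_that("ICER reports ratio and dominance labels per the worked examples", {
  r <- icer(-1255370, 3034)
  expect_equal(r$usd_per_daly, 1255370 / 3034, tolerance = 1e-9)
  expect_equal(round(r$usd_per_daly), 414)
  expect_match(r$label, "dominant")
  expect_match(r$label, "saved per DALY averted")
  expect_equal(icer(0, 5)$icer, 0)
  r2 <- icer(70223, 1)
  expect_equal(r2$usd_per_daly, 70223)
  expect_match(r2$label, "spent per DALY averted")
  expect_error(icer(100, 0), class = "foodaidsim_input_error")
})

test_that("scenarios with identical aid budgets cancel food costs in comparison", {
  co <- tiny_cohort(300)
  cfg <- fast_config(years = 3)
  base <- run_scenario(co, aid_scenario("traditional"), cfg, mode = "expected")
  alt <- run_scenario(co, aid_scenario("alternative_parcel"), cfg,
                      mode = "expected")
  cea <- cea_compare(base, alt, perspective = "societal")
  food <- cea$costs$averted[cea$costs$item == "food_aid"]
  expect_equal(food, 0, tolerance = 1e-6) # budget-neutral by design
})
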