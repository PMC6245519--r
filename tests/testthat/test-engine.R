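test_that("a zero-delta scenario under common random numbers reproduces the baseline exactly", {
  co <- tiny_cohort(400)
  cfg <- fast_config(years = 4)
  base <- run_scenario(co, aid_scenario("traditional"), cfg)
  null_scen <- aid_scenario("alternative_parcel", grain_delta = 0,
                            fruit_veg_delta = 0)
  null_led <- run_scenario(co, null_scen, cfg)
  expect_identical(base$by_outcome, null_led$by_outcome)
  expect_identical(base$by_year, null_led$by_year)
  cmp <- compare_scenarios(base, null_led)
  expect_equal(cmp$difference, rep(0, nrow(cmp)))
  # without common random numbers the streams differ
  cfg2 <- fast_config(years = 4, common_random_numbers = FALSE)
  led_a <- run_scenario(co, aid_scenario("traditional"), cfg2)
  led_b <- run_scenario(co, null_scen, cfg2)
  expect_false(identical(led_a$by_outcome, led_b$by_outcome))
})

test_that("certain first-year mortality yields one person-year and one death", {
  co <- tiny_cohort(5)
  co$age <- 50 # adults, so they count in denominators
  rc <- default_risk_coefficients()
  rc$mortality$baseline_hazard <- 1e6
  cfg <- fast_config(years = 3)
  led <- run_scenario(co, aid_scenario("traditional"), cfg, risk_coeffs = rc)
  rates <- ledger_rates(led, among_aid = FALSE)
  expect_equal(rates$person_years[rates$outcome == "mortality"], 5)
  expect_equal(rates$events[rates$outcome == "mortality"], 5)
  expect_equal(sum(led$deaths$weight), 5)
  expect_false(any(led$final_cohort$alive))
})

test_that("person-year accounting is exact and no events accrue to the dead", {
  co <- tiny_cohort(600)
  cfg <- fast_config(years = 6)
  led <- run_scenario(co, aid_scenario("traditional"), cfg)
  by <- led$by_outcome
  expect_true(all(by$events >= 0))
  expect_true(all(by$person_years <= 600 * 6))
  # mortality denominator equals total adult alive-time, which shrinks by
  # exactly the deaths recorded
  expect_lte(sum(led$by_year$deaths), 600)
  expect_equal(nrow(led$by_year), 6)
  # aid split covers the whole cohort
  mort <- by[by$outcome == "mortality", ]
  adult0 <- sum(co$age >= 20 & co$age <= 79)
  expect_lte(sum(mort$person_years), 600 * 6)
  expect_gt(sum(mort$person_years), adult0 * 0.8 * 6)
})

test_that("aid-recipient person-years reflect the enrollment share", {
  co <- sample_refugee_cohort(4000, seed = 17)
  cfg <- fast_config(years = 2)
  led <- run_scenario(co, aid_scenario("traditional"), cfg, mode = "expected")
  mort <- led$by_outcome[led$by_outcome$outcome == "mortality", ]
  share <- mort$person_years[mort$aid] / sum(mort$person_years)
  expect_lt(abs(share - 0.43), 3 * sqrt(0.43 * 0.57 / 4000))
})

test_that("expected-mode rates are invariant to exact cohort duplication", {
  co <- tiny_cohort(300)
  dup <- dplyr::bind_rows(co, co)
  dup$person_id <- seq_len(nrow(dup))
  cfg <- fast_config(years = 3)
  r1 <- ledger_rates(run_scenario(co, aid_scenario("traditional"), cfg,
                                  mode = "expected"), among_aid = FALSE)
  r2 <- ledger_rates(run_scenario(dup, aid_scenario("traditional"), cfg,
                                  mode = "expected"), among_aid = FALSE)
  expect_equal(r1$rate, r2$rate, tolerance = 1e-9)
})

test_that("incidence_rate is the per-1,000 ratio with guarded denominator", {
  expect_equal(incidence_rate(12, 1000), 12)
  expect_equal(incidence_rate(0, 500), 0)
  expect_equal(incidence_rate(658, 100000), 6.58)
  expect_error(incidence_rate(1, 0), class = "foodaidsim_input_error")
})

test_that("mismatched ledgers refuse comparison", {
  co <- tiny_cohort(100)
  led1 <- run_scenario(co, aid_scenario("traditional"), fast_config(years = 2))
  led2 <- run_scenario(co, aid_scenario("traditional"), fast_config(years = 3))
  expect_error(compare_scenarios(led1, led2), class = "foodaidsim_input_error")
})

test_that("a sustained intervention that lowers biomarkers lowers expected incidence", {
  co <- sample_refugee_cohort(1500, seed = 23)
  cfg <- fast_config(years = 5)
  base <- run_scenario(co, aid_scenario("traditional"), cfg, mode = "expected")
  sodium_cut <- run_scenario(co, aid_scenario("traditional"), cfg,
                             mode = "expected",
                             person_deltas = pure_delta_set(co, sodium = -1000))
  cmp <- compare_scenarios(base, sodium_cut)
  expect_lte(cmp$difference[cmp$outcome == "hypertension"], 0)
})

test_that("stochastic and expected modes agree on baseline rates", {
  co <- sample_refugee_cohort(5000, seed = 29)
  cfg <- fast_config(years = 5)
  re <- ledger_rates(run_scenario(co, aid_scenario("traditional"), cfg,
                                  mode = "expected"), among_aid = FALSE)
  rs <- ledger_rates(run_scenario(co, aid_scenario("traditional"), cfg,
                                  mode = "stochastic"), among_aid = FALSE)
  for (oc in re$outcome) {
    e <- re[re$outcome == oc, ]; s <- rs[rs$outcome == oc, ]
    mc_se <- sqrt(pmax(e$events, 1)) / e$person_years * 1000
    expect_lt(abs(s$rate - e$rate), 4 * mc_se + 0.02 * e$rate)
  }
})

test_that("ledgers serialize to JSON and tidy/glance methods work", {
  co <- tiny_cohort(150)
  led <- run_scenario(co, aid_scenario("traditional"), fast_config(years = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_ledger_json(led, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n0, 150)
  td <- tidy(led)
  expect_true(all(c("outcome", "rate") %in% names(td)))
  gl <- glance(led)
  expect_equal(gl$n, 150)
})
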