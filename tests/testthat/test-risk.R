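test_that("status classifiers implement the diagnostic criteria and are pure", {
  expect_true(classify_hypertension(131.7, 74.0, FALSE))
  expect_false(classify_hypertension(120, 70, FALSE))
  expect_true(classify_hypertension(110, 60, TRUE))
  expect_true(classify_hypertension(120, 80, FALSE)) # diastolic criterion
  expect_true(classify_diabetes(8.2, FALSE))
  expect_false(classify_diabetes(6.49, FALSE))
  expect_true(classify_diabetes(6.5, FALSE))
  expect_true(classify_diabetes(5.0, TRUE))
  # repeated calls are identical (no hidden state)
  x <- replicate(5, classify_hypertension(c(131, 120), c(70, 85), c(FALSE, FALSE)))
  expect_true(all(x == x[, 1]))
})

test_that("annual probabilities stay in [0, 1] under covariate fuzzing", {
  set.seed(13)
  n <- 500
  wild <- tiny_cohort(n)
  wild$age <- runif(n, 0, 120); wild$sbp <- runif(n, 60, 260)
  wild$a1c <- runif(n, 3, 20); wild$total_chol <- runif(n, 1, 15)
  wild$urine_acr <- runif(n, 0.1, 400); wild$serum_creatinine <- runif(n, 20, 900)
  coeffs <- default_risk_coefficients()
  probs <- c(ascvd_annual_prob(wild, coeffs),
             microvascular_annual_prob(wild, "esrd", coeffs),
             microvascular_annual_prob(wild, "neuropathy", coeffs),
             microvascular_annual_prob(wild, "retinopathy", coeffs),
             mortality_annual_prob(wild, coeffs))
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("risk gradients are monotone in their established directions", {
  co <- tiny_cohort(2)
  co <- co[c(1, 1), ]
  co$cvd_history <- FALSE
  co$smoker <- c(FALSE, TRUE)
  p <- ascvd_annual_prob(co)
  expect_gte(p[2], p[1])
  # higher A1c never lowers any microvascular probability
  dm <- co[c(1, 1), ]
  dm$has_diabetes <- TRUE
  dm$smoker <- FALSE
  dm$a1c <- c(7, 12)
  for (m in c("esrd", "neuropathy", "retinopathy")) {
    pm <- microvascular_annual_prob(dm, m)
    expect_gte(pm[2], pm[1])
  }
  # age gradient for mortality, bounded at 1
  old <- co[c(1, 1), ]; old$age <- c(50, 10000)
  pmort <- mortality_annual_prob(old)
  expect_gte(pmort[2], pmort[1]); expect_lte(pmort[2], 1)
})

test_that("persons without diabetes contribute zero microvascular risk", {
  co <- tiny_cohort(50)
  co$has_diabetes <- FALSE
  expect_equal(microvascular_annual_prob(co, "esrd"), rep(0, 50))
  expect_error(microvascular_annual_prob(co, "stroke"),
               class = "foodaidsim_input_error")
})

test_that("scaling the hazard composes through the exponential link", {
  co <- tiny_cohort(100)
  co$cvd_history <- FALSE
  c1 <- default_risk_coefficients()
  c2 <- default_risk_coefficients()
  c2$ascvd$calibration_scale <- 2
  p1 <- ascvd_annual_prob(co, c1)
  p2 <- ascvd_annual_prob(co, c2)
  # oracle: p2 = 1 - (1 - p1)^2, the brute-force hazard-doubling identity
  expect_equal(p2, 1 - (1 - p1)^2, tolerance = 1e-12)
})

test_that("rare-event hazards and probabilities agree within 1%", {
  h <- runif(200, 0, 0.02)
  expect_true(all(abs(hazard_to_prob(h) - h) / pmax(h, 1e-12) < 0.01))
})

test_that("missing location coefficients are a configuration error", {
  co <- tiny_cohort(10)
  co$location <- "Atlantis"
  expect_error(ascvd_annual_prob(co), class = "foodaidsim_config_error")
})

test_that("recalibration is a fixed point at the current rate and scales proportionally", {
  co <- tiny_cohort(2500, seed = 31)
  # current simulated rate as its own target: scale stays near 1
  base_rates <- ledger_rates(
    run_scenario(co, aid_scenario("traditional"), fast_config(years = 5),
                 mode = "expected"),
    among_aid = FALSE
  )
  esrd_now <- base_rates$rate[base_rates$outcome == "esrd"]
  tg <- default_calibration_targets()
  tg$target_rate[tg$outcome == "esrd"] <- esrd_now
  cal <- recalibrate_baseline_hazard(default_risk_coefficients(), tg, co,
                                     seed = 1, years = 5, outcomes = "esrd")
  expect_equal(cal$esrd$calibration_scale, 1, tolerance = 0.02)
  # doubling a rare-event target roughly doubles the scale
  tg$target_rate[tg$outcome == "esrd"] <- 2 * esrd_now
  cal2 <- recalibrate_baseline_hazard(default_risk_coefficients(), tg, co,
                                      seed = 1, years = 5, outcomes = "esrd")
  expect_equal(cal2$esrd$calibration_scale, 2, tolerance = 0.1)
  # a zero target is unreachable with a positive hazard
  tg$target_rate[tg$outcome == "esrd"] <- 0
  expect_error(recalibrate_baseline_hazard(default_risk_coefficients(), tg, co,
                                           seed = 1, years = 5,
                                           outcomes = "esrd"),
               class = "foodaidsim_config_error")
})

test_that("calibration reports serialize to JSON", {
  co <- tiny_cohort(800, seed = 2)
  tg <- default_calibration_targets()
  cal <- recalibrate_baseline_hazard(default_risk_coefficients(), tg, co,
                                     seed = 1, years = 3,
                                     outcomes = "mortality")
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_report(cal, path)
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rep$outcome, "mortality")
  expect_equal(rep$achieved, rep$target, tolerance = 2e-3)
})
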