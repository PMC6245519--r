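test_that("sampled cohorts satisfy the person-record invariants", {
  co <- sample_refugee_cohort(4000, seed = 21)
  expect_silent(validate_person_records(co))
  expect_true(all(abs(co$bmi - co$weight / co$height^2) < 1e-6))
  expect_true(all(co$a1c >= 0 & co$a1c <= 20))
  expect_true(all(co$has_diabetes[co$on_diabetes_treatment]))
  expect_true(all(co$alive))
  expect_true(all(co$frequency_weight == 1))
})

test_that("conditional structure matches the published summaries", {
  co <- sample_refugee_cohort(8000, seed = 22)
  se <- function(p, n) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(co$sex == "female") - 0.601), 3 * se(0.601, 8000))
  expect_lt(abs(mean(co$has_diabetes) - 0.122), 3 * se(0.122, 8000))
  expect_lt(abs(mean(co$receives_aid) - 0.430), 3 * se(0.430, 8000))
  expect_lt(abs(mean(co$smoker) - 0.251), 3 * se(0.251, 8000))
  # treatment coverage among the diagnosed
  dm <- co[co$has_diabetes, ]
  expect_lt(abs(mean(dm$on_diabetes_treatment) - 0.86), 3 * se(0.86, nrow(dm)))
  # sex-specific biomarker locations
  men <- co[co$sex == "male", ]; women <- co[co$sex == "female", ]
  expect_lt(abs(mean(men$sbp) - 131.7), 3 * sd(men$sbp) / sqrt(nrow(men)))
  expect_lt(abs(mean(women$sbp) - 120.1), 3 * sd(women$sbp) / sqrt(nrow(women)))
  expect_lt(abs(mean(men$bmi) - 27.1), 3 * sd(men$bmi) / sqrt(nrow(men)))
  # A1c among persons with diabetes reproduces the diagnosed-group mean
  expect_lt(abs(mean(dm$a1c) - 8.2), 3 * sd(dm$a1c) / sqrt(nrow(dm)))
  # smoking is concentrated among men (negative latent correlation)
  expect_gt(mean(men$smoker), mean(women$smoker))
})

test_that("cohorts are bitwise reproducible per seed at the CSV level", {
  path1 <- withr::local_tempfile(fileext = ".csv")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(sample_refugee_cohort(500, seed = 33), path1, seed = 33)
  write_cohort_csv(sample_refugee_cohort(500, seed = 33), path2, seed = 33)
  expect_identical(readLines(path1), readLines(path2))
  expect_true(file.exists(paste0(path1, ".provenance.json")))
  back <- read_cohort_csv(path1)
  expect_equal(nrow(back), 500)
})

test_that("reweighting matches target sex and location margins", {
  co <- sample_refugee_cohort(5000, seed = 9)
  rw <- reweight_cohort(co)
  wshare <- sum(rw$frequency_weight[rw$sex == "female"]) / sum(rw$frequency_weight)
  expect_equal(wshare, 0.601, tolerance = 1e-6)
  jordan <- sum(rw$frequency_weight[rw$location == "Jordan"]) / sum(rw$frequency_weight)
  expect_equal(jordan, 0.407, tolerance = 1e-6)
})

test_that("demography advancement ages, drifts and bears children correctly", {
  co <- sample_refugee_cohort(400, seed = 5)
  expect_identical(advance_demography(co, years = 0), co)
  aged <- advance_demography(co, birth_rate = 0, secular_trends = NULL,
                             years = 1, seed = 1)
  expect_equal(aged$age, co$age + 1)
  expect_equal(nrow(aged), nrow(co))
  # a pure SBP trend of +0.5 mmHg/yr for 2 years shifts the stratum mean by +1
  tr <- tibble::tibble(variable = "sbp", sex = "all", age_min = 0,
                       age_max = 200, slope = 0.5)
  drifted <- advance_demography(co, birth_rate = 0, secular_trends = tr,
                                years = 2, seed = 1)
  expect_equal(mean(drifted$sbp) - mean(co$sbp), 1.0, tolerance = 1e-9)
  # births accrue at the per-capita rate within Monte Carlo error
  big <- sample_refugee_cohort(3000, seed = 6)
  grown <- advance_demography(big, birth_rate = 0.03, secular_trends = NULL,
                              years = 2, seed = 2)
  births <- nrow(grown) - nrow(big)
  expected <- 3000 * 0.03 * 2
  expect_lt(abs(births - expected) / sqrt(expected), 4)
  expect_error(advance_demography(co, birth_rate = -1, years = 1),
               class = "foodaidsim_config_error")
})
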