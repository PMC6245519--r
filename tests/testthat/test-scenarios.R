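test_that("scenario deltas conserve energy additively", {
  base <- arm_mean_intake("parcel")
  alt <- apply_scenario(base, aid_scenario("alternative_parcel"))
  expect_equal(total_energy(alt), 2296 - 40 + 7) # 2,263: net -33 kcal/day
  # energy conservation property for random additive scenarios
  set.seed(3)
  for (i in 1:25) {
    g <- runif(1, -100, 100); f <- runif(1, 0, 100)
    sc <- aid_scenario("alternative_parcel", grain_delta = g, fruit_veg_delta = f)
    expect_equal(total_energy(apply_scenario(base, sc)),
                 total_energy(base) + g + f, tolerance = 1e-9)
  }
  # null scenario is the identity
  expect_equal(apply_scenario(base, aid_scenario("traditional")), base)
  # infeasible (negative group) scenarios abort
  expect_error(apply_scenario(base, aid_scenario("alternative_parcel",
                                                 grain_delta = -2000)),
               class = "foodaidsim_input_error")
})

test_that("the debit-card override replaces draws with that arm's distribution", {
  base <- generate_household_consumption("parcel", 4000, seed = 2)[food_groups()]
  over <- apply_scenario(base, aid_scenario("debit_card"), seed = 10)
  m <- mean(total_energy(over))
  se <- sd(total_energy(over)) / sqrt(nrow(over))
  expect_lt(abs(m - 2441), 3 * se)
  # the cash arm adds its configured shift on top of the debit distribution
  cash <- apply_scenario(base, aid_scenario("cash"), seed = 10)
  expect_equal(mean(total_energy(cash)) - mean(total_energy(over)), 93,
               tolerance = 1e-9)
})

test_that("misreporting corrections shift, truncate and vanish correctly", {
  base <- arm_mean_intake("parcel")
  zero_bias <- default_misreporting_bias()
  zero_bias$bias_mean <- 0; zero_bias$bias_se <- 0
  expect_equal(apply_misreporting_correction(base, zero_bias), base)
  point <- default_misreporting_bias()
  point$bias_se <- 0
  corrected <- apply_misreporting_correction(base, point, seed = 1)
  expect_equal(corrected$cereals, 1239 + 47.6)
  # fruit/vegetable overreporting exceeds the reported level: truncated at 0
  expect_equal(corrected$fruits_vegetables, 0)
  expect_equal(corrected$oils_fats, 163 + 20.4)
  # stochastic corrections are deterministic per seed and nonnegative
  a <- apply_misreporting_correction(base, seed = 5)
  b <- apply_misreporting_correction(base, seed = 5)
  expect_identical(a, b)
  expect_true(all(as.matrix(a[food_groups()]) >= 0))
})

test_that("compensatory neutralization fraction is the direct energy ratio", {
  base <- arm_mean_intake("parcel")
  f <- compensatory_neutralization_fraction(base, -33)
  expect_equal(f, 33 / (1239 + 163 + 184), tolerance = 1e-12)
  expect_equal(compensatory_neutralization_fraction(base, 0), 0)
  d100 <- food_group_intake(cereals = 50, oils_fats = 30, sugars = 20,
                            fruits_vegetables = 10)
  expect_equal(compensatory_neutralization_fraction(d100, -1), 0.01)
  # linearity in |delta| and inverse proportionality to the denominator
  expect_equal(compensatory_neutralization_fraction(base, -66), 2 * f)
  empty <- food_group_intake(fruits_vegetables = 100)
  expect_error(compensatory_neutralization_fraction(empty, -1),
               class = "foodaidsim_input_error")
})

test_that("food-security floors are strict and use lower bounds when present", {
  ok <- tibble::tibble(energy = 2296, protein_pct = 12, fat_pct = 20)
  expect_true(as.logical(food_security_check(ok)))
  low_e <- ok; low_e$energy <- 2099
  expect_false(as.logical(food_security_check(low_e)))
  boundary <- ok; boundary$energy <- 2100
  expect_false(as.logical(food_security_check(boundary))) # strict inequality
  with_ci <- ok
  with_ci$energy_lo <- 2000; with_ci$protein_pct_lo <- 11; with_ci$fat_pct_lo <- 18
  expect_false(as.logical(food_security_check(with_ci))) # lower bound governs
  detail <- attr(food_security_check(with_ci), "detail")
  expect_false(detail[["energy"]]); expect_true(detail[["protein"]])
})
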