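test_that("all four mediator maps are exactly zero at zero input", {
  p <- ref_person()
  expect_equal(bmi_change_from_energy(0, p, horizon = 10), 0)
  expect_equal(sbp_dbp_change(0, 0), tibble::tibble(sbp = 0, dbp = 0))
  expect_equal(lipid_change(0, 0, 0, 2296),
               tibble::tibble(total_chol = 0, hdl_chol = 0))
  expect_equal(a1c_change(0, 0), 0)
})

test_that("quasi-static weight change is the configured steady-state reduction", {
  p <- ref_person()
  dbmi <- bmi_change_from_energy(-33, p, horizon = 10, method = "quasistatic")
  expect_equal(dbmi, (-33 / 17.5) / 1.6^2, tolerance = 1e-12)
})

test_that("dynamic trajectory matches numerical integration and its steady state", {
  skip_if_not_installed("deSolve")
  p <- ref_person()
  coeffs <- default_mediator_coefficients()
  dyn <- hall_dynamics(p, coeffs)
  dI <- -250
  beta <- 0.14
  # numerical oracle: integrate the linearized energy-balance equation
  ode_fn <- function(t, w, parms) {
    list(((1 - beta) * dI - dyn$lambda * w) / dyn$rho_bar)
  }
  for (t_days in c(90, 365, 3652)) {
    num <- deSolve::ode(c(w = 0), c(0, t_days), ode_fn, NULL)[2, "w"]
    got <- bmi_change_from_energy(dI, p, horizon = t_days / 365.25, coeffs) * p$height^2
    expect_equal(got, unname(num), tolerance = 1e-6)
  }
  # convergence to the analytic steady state within 0.1% at 10 time constants
  ss <- (1 - beta) * dI / dyn$lambda
  num10 <- deSolve::ode(c(w = 0), c(0, 10 * dyn$tau_days), ode_fn, NULL)[2, "w"]
  expect_equal(unname(num10) / ss, 1, tolerance = 1e-3)
  # sign follows the intake change and magnitude saturates with horizon
  expect_lt(bmi_change_from_energy(-100, p, horizon = 1), 0)
  expect_gt(bmi_change_from_energy(100, p, horizon = 1), 0)
  expect_lt(abs(bmi_change_from_energy(-100, p, horizon = 1)),
            abs(bmi_change_from_energy(-100, p, horizon = 30)))
})

test_that("weight response is locally linear at short horizons", {
  p <- ref_person()
  d1 <- bmi_change_from_energy(-100, p, horizon = 90 / 365.25)
  d2 <- bmi_change_from_energy(-200, p, horizon = 90 / 365.25)
  expect_equal(d2 / d1, 2, tolerance = 0.05)
})

test_that("blood-pressure response follows the configured slopes", {
  r <- sbp_dbp_change(1000, 0)
  expect_equal(r$sbp, 2.11, tolerance = 1e-12)
  expect_equal(r$dbp, 0.5 * 2.11, tolerance = 1e-12)
  # monotonicity: more sodium never lowers SBP
  grid <- seq(-2000, 2000, by = 250)
  resp <- sbp_dbp_change(grid, 0)$sbp
  expect_true(all(diff(resp) >= 0))
  # potassium lowers pressure
  expect_lt(sbp_dbp_change(0, 1000)$sbp, 0)
})

test_that("lipid response converts mass to energy share then applies the matrix", {
  # +2,551 mg SFA/day at 2,296 kcal/day is +1% of energy (9 kcal/g)
  r <- lipid_change(2551, 0, 0, 2296)
  pct <- 100 * 2551 / 1000 * 9 / 2296
  expect_equal(pct, 1.0, tolerance = 1e-3)
  expect_equal(r$total_chol, 0.052 * pct, tolerance = 1e-9)
  # linearity: response to a sum equals the sum of responses
  a <- lipid_change(1000, 500, 200, 2296)
  b <- lipid_change(300, 800, 900, 2296)
  ab <- lipid_change(1300, 1300, 1100, 2296)
  expect_equal(ab$total_chol, a$total_chol + b$total_chol, tolerance = 1e-12)
  expect_equal(ab$hdl_chol, a$hdl_chol + b$hdl_chol, tolerance = 1e-12)
  expect_error(lipid_change(100, 0, 0, 0), class = "foodaidsim_input_error")
})

test_that("glycemic response applies both coefficients with their signs", {
  expect_equal(a1c_change(1, 0), 0.1, tolerance = 1e-12)
  expect_equal(a1c_change(0, 1), -0.05, tolerance = 1e-12)
  expect_equal(a1c_change(2, 3), 0.2 - 0.15, tolerance = 1e-12)
})

test_that("coefficient draws reproduce the configured intervals empirically", {
  coeffs <- default_mediator_coefficients()
  draws <- vapply(1:10000, function(j) {
    coef_drawn <- draw_mediator_coefficients(coeffs, seed = j)
    coef_drawn$estimate[coef_drawn$coefficient == "na_sbp_slope"]
  }, numeric(1))
  coverage <- mean(draws >= 1.40 & draws <= 2.82)
  expect_gt(coverage, 0.93); expect_lt(coverage, 0.97)
  # constants never move
  d <- draw_mediator_coefficients(coeffs, seed = 1)
  expect_equal(d$estimate[d$coefficient == "hall_rho_fat"], 9441)
})

test_that("mediator coefficients survive a YAML round trip", {
  coeffs <- default_mediator_coefficients()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_mediator_yaml(coeffs, path)
  back <- read_mediator_yaml(path)
  expect_equal(back$estimate, coeffs$estimate, tolerance = 1e-12)
  expect_equal(back$coefficient, coeffs$coefficient)
})

test_that("invalid coefficient sets are rejected", {
  bad <- default_mediator_coefficients()
  bad$estimate[bad$coefficient == "k_sbp_slope"] <- 0.5
  bad$conf_high[bad$coefficient == "k_sbp_slope"] <- 0.6
  expect_error(validate_mediator_coefficients(bad),
               class = "foodaidsim_config_error")
})
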