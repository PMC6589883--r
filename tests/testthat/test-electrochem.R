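test_that("current and power density follow the cathode-normalized formulas", {
  expect_equal(current_density(0.036, 100, 0.0036), 100)
  expect_equal(current_density(0, 100, 0.0036), 0)
  # inversion at the tetracycline maximum: 136 mA m^-2 needs 48.96 mV
  expect_equal(current_density(0.04896, 100, 0.0036), 136)
  expect_equal(power_density(0.06, 100, 0.0036), 10)
  expect_equal(power_density(0, 100, 0.0036), 0)
  expect_error(current_density(0.1, -1, 0.0036), "resistance")
  expect_error(power_density(0.1, 100, 0), "area")
})

test_that("power density equals current density times voltage over area", {
  set.seed(42)
  for (i in 1:20) {
    u <- runif(1, 0, 0.6); r <- runif(1, 10, 10000); a <- runif(1, 1e-4, 0.1)
    expect_equal(power_density(u, r, a), current_density(u, r, a) * u)
  }
})

test_that("charge accumulation matches the closed form on constant traces", {
  t <- seq(0, 5011200, by = 1800)  # 58 days
  tr <- voltage_trace(t, rep(0.01, length(t)), 100)
  expect_equal(accumulate_charge(tr), 0.01 * 5011200 / 100)  # 501.12 C
  expect_equal(accumulate_charge(voltage_trace(t, rep(0, length(t)), 100)), 0)
})

test_that("charge is additive over concatenation and scales in U and R", {
  t <- seq(0, 86400, by = 1800)
  u <- runif(length(t), 0, 0.1)
  whole <- voltage_trace(t, u, 50)
  cut <- 25
  left <- voltage_trace(t[1:cut], u[1:cut], 50)
  right <- voltage_trace(t[cut:length(t)], u[cut:length(t)], 50)
  expect_equal(accumulate_charge(left) + accumulate_charge(right),
               accumulate_charge(whole))
  expect_equal(accumulate_charge(voltage_trace(t, 2 * u, 50)),
               2 * accumulate_charge(whole))
  expect_equal(accumulate_charge(voltage_trace(t, u, 100)),
               accumulate_charge(whole) / 2)
})

test_that("trapezoid and rectangle rules differ by the analytic half-step on a ramp", {
  # U(t) = c t: rectangle (left) underestimates by c * dt * T / 2 / R
  t <- seq(0, 3600, by = 100)
  cc <- 1e-5
  tr <- voltage_trace(t, cc * t, 10)
  rect <- accumulate_charge(tr, "rectangle")
  trap <- accumulate_charge(tr, "trapezoid")
  expect_equal(trap - rect, cc * 100 * 3600 / 2 / 10)
  expect_equal(trap, cc * 3600^2 / 2 / 10)  # exact for a linear ramp
})

test_that("start-up time is the first crossing of the 1 mV threshold", {
  t <- seq(0, 36000, by = 1800)
  u <- ifelse(t >= 18000, 0.01, 0)
  expect_equal(startup_time(voltage_trace(t, u, 100)), 5)
  expect_equal(startup_time(voltage_trace(t, rep(0.02, length(t)), 100)), 0)
  expect_true(is.na(startup_time(voltage_trace(t, rep(0, length(t)), 100))))
})

test_that("polarization fit recovers divider parameters from noiseless sweeps", {
  cfg <- sim_config(seed = 3)
  for (trt in c("TC", "SC", "CC")) {
    truth <- cfg$polarization[cfg$polarization$treatment == trt, ]
    fit <- fit_polarization(gen_polarization(cfg, trt))
    expect_equal(fit$ocv_V, truth$ocv_V, tolerance = 1e-9)
    expect_equal(fit$internal_resistance_ohm, truth$rint_ohm, tolerance = 1e-9)
  }
})

test_that("divider model gives OCV/2 at matched load and OCV in the open limit", {
  cfg <- sim_config(seed = 1,
                    polarization = data.frame(treatment = "X", ocv_V = 0.37,
                                              rint_ohm = 262),
                    resistance_ladder_ohm = c(1e7, 262, 100))
  sw <- gen_polarization(cfg, "X")
  expect_equal(sw$voltage_V[sw$resistance_ohm == 262], 0.185)
  expect_equal(sw$voltage_V[sw$resistance_ohm == 1e7], 0.37, tolerance = 1e-4)
  # max of the fitted power curve sits at R ~ Rint (matched load)
  cfg2 <- sim_config(seed = 1, resistance_ladder_ohm =
                       round(exp(seq(log(10000), log(100), length.out = 30))))
  sw2 <- gen_polarization(cfg2, "TC")
  pc <- fit_polarization(sw2)$power_curve
  r_at_max <- pc$resistance_ohm[which.max(pc$power_density_mW_m2)]
  expect_lt(abs(log(r_at_max / 262)), log(1.5))
})

test_that("degenerate polarization sweeps are rejected", {
  expect_error(fit_polarization(polarization_sweep(c(100, 200, 300),
                                                   c(0.1, 0.2, 0.3))),
               "degenerate")  # identical currents
  expect_error(fit_polarization(polarization_sweep(c(100, 200), c(0.1, 0.15))),
               ">= 3")
})

test_that("two-point exact line is reproduced through the fit machinery", {
  # three collinear points, no tail exclusion ambiguity
  ocv <- 0.25; rint <- 500
  r <- c(5000, 1000, 300)
  u <- ocv * r / (r + rint)
  fit <- fit_polarization(polarization_sweep(r, u))
  expect_equal(fit$ocv_V, ocv, tolerance = 1e-12)
  expect_equal(fit$internal_resistance_ohm, rint, tolerance = 1e-12)
})

test_that("percent increase reproduces the reported comparisons", {
  expect_equal(percent_increase(65, 53, digits = 0), 23)
  expect_equal(percent_increase(136, 109, digits = 0), 25)
  expect_equal(percent_increase(7, 7), 0)
  expect_error(percent_increase(1, 0), "nonzero")
})

test_that("voltage trace validation rejects malformed inputs", {
  expect_error(voltage_trace(c(0, 0), c(1, 1), 100), "increasing")
  expect_error(voltage_trace(1:3, 1:2, 100), "length")
  expect_error(voltage_trace(1:3, 1:3, -5), "resistance")
})
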