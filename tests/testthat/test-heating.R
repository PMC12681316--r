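test_that("thermometry scaling recovers relative heating", {
  ref <- generate_thermometry(2, 0.4, duration = 139, baseline = 60,
                              seed = 1)
  # identical series: scale 1, peak equals the reference peak
  out <- process_thermometry(ref, ref)
  expect_equal(out$scale, 1)
  expect_equal(out$dt_peak, out$peak_reference)
  # quarter-amplitude series with a baseline offset: scale 0.25
  shifted <- ref
  shifted$temperature <- 0.25 * ref$temperature + 1
  out <- process_thermometry(shifted, ref)
  expect_equal(out$scale, 0.25, tolerance = 1e-12)
  # halving the current quarters the scale (quadratic heating)
  half <- generate_thermometry(2, 0.2, duration = 139, baseline = 60,
                               seed = 2)
  out <- process_thermometry(half, ref)
  expect_equal(out$scale, 0.25, tolerance = 1e-9)
})

test_that("thermometry scaling is robust to drift and noise", {
  cc <- 30
  ref <- generate_thermometry(cc, 0.5, duration = 139, baseline = 120,
                              drift = 0, noise_sd = 0, seed = 1)
  noisy <- generate_thermometry(cc, 0.25, duration = 139, baseline = 120,
                                drift = 2e-4, noise_sd = 0.01, seed = 7)
  out <- process_thermometry(noisy, ref)
  expect_equal(out$scale, 0.25, tolerance = 0.05)
  expect_error(process_thermometry(
    generate_thermometry(cc, 0.5, duration = 21, baseline = 10, seed = 1),
    ref), NA)
})

test_that("generated thermometry has the quadratic exposure slope", {
  a <- generate_thermometry(2, 0.1, duration = 100, baseline = 50, seed = 3)
  b <- generate_thermometry(2, 0.2, duration = 100, baseline = 50, seed = 3)
  slope <- function(s) {
    sel <- s$time >= s$exposure_start
    stats::coef(stats::lm(s$temperature[sel] ~ s$time[sel]))[2]
  }
  expect_equal(unname(slope(b) / slope(a)), 4, tolerance = 1e-9)
  flat <- generate_thermometry(2, 0, duration = 100, baseline = 50,
                               drift = 0, noise_sd = 0, seed = 4)
  expect_equal(stats::sd(flat$temperature), 0)
})

test_that("the heating constant is fitted exactly on proportional data", {
  obs <- data.frame(i_mri = c(1, 2), dt_thermo = c(2, 8))
  cal <- fit_cimplant(obs)
  expect_equal(cal$c_implant, 2)
  expect_equal(cal$r_squared, 1)
  single <- fit_cimplant(data.frame(i_mri = 0.1, dt_thermo = 0.5))
  expect_equal(single$c_implant, 50)
  expect_error(fit_cimplant(data.frame(i_mri = c(0, 0),
                                       dt_thermo = c(1, 2))), "zero")
})

test_that("c fitting is scale-equivariant and noise-tolerant", {
  set.seed(21)
  i <- seq(0.05, 0.3, length.out = 9)
  cc <- 40
  dt <- cc * i^2 * (1 + rnorm(9, 0, 0.05))
  cal <- fit_cimplant(data.frame(i_mri = i, dt_thermo = dt))
  expect_lt(abs(cal$c_implant - cc) / cc, 0.05)
  expect_gt(cal$r_squared, 0.9)
  cal_scaled <- fit_cimplant(data.frame(i_mri = 3 * i, dt_thermo = dt))
  expect_equal(cal_scaled$c_implant, cal$c_implant / 9, tolerance = 1e-12)
})

test_that("heating prediction is quadratic in the current", {
  cal <- implant_calibration(2)
  expect_equal(predict_dt(cal, 0), 0)
  expect_equal(predict_dt(cal, 0.5), 0.5)
  expect_equal(predict_dt(cal, 1), 4 * predict_dt(cal, 0.5))
})

test_that("the exposure limit closes the loop exactly", {
  cal <- implant_calibration(35)
  b1_seq <- 0.84
  for (i in c(0.03, 0.1, 0.24)) {
    b1 <- b1_threshold(cal, i, b1_seq, dt_thresh = 2)
    # predicted heating at the current rescaled to the threshold exposure
    expect_equal(predict_dt(cal, i * b1 / b1_seq), 2, tolerance = 1e-12)
  }
  # unit-ratio special cases
  i_unit <- sqrt(2 / 35)
  expect_equal(b1_threshold(cal, i_unit, b1_seq, 2), b1_seq)
  i_quad <- sqrt(8 / 35)
  expect_equal(b1_threshold(cal, i_quad, b1_seq, 2), b1_seq / 2)
  expect_identical(b1_threshold(cal, 0, b1_seq, 2), Inf)
  expect_error(b1_threshold(cal, 0.1, b1_seq, -1), "positive")
})

test_that("leave-one-out isolates corrupted observations", {
  i <- c(0.05, 0.1, 0.15, 0.2, 0.25)
  cc <- 40
  obs <- data.frame(i_mri = i, dt_thermo = cc * i^2)
  loo <- loo_evaluate(obs)
  expect_equal(loo$summary$median_err_current, 0, tolerance = 1e-12)
  expect_equal(loo$summary$median_err_dt, 0, tolerance = 1e-12)
  # corrupt one observation in a larger set: its held-out error dominates
  # (the other folds keep the corrupted pair in their calibration, so their
  # errors rise too, but diluted by the clean pairs)
  i9 <- seq(0.05, 0.3, length.out = 9)
  obs9 <- data.frame(i_mri = i9, dt_thermo = cc * i9^2)
  obs9$dt_thermo[5] <- obs9$dt_thermo[5] * 2
  loo <- loo_evaluate(obs9)
  expect_equal(which.max(loo$per_observation$err_dt), 5L)
  expect_gt(loo$per_observation$err_dt[5],
            3 * median(loo$per_observation$err_dt[-5]))
  expect_error(loo_evaluate(obs[1:2, ]), "3")
})

test_that("LOO current errors stay small under multiplicative noise", {
  set.seed(31)
  errs <- replicate(20, {
    i <- seq(0.05, 0.3, length.out = 9)
    dt <- 40 * i^2 * (1 + rnorm(9, 0, 0.05))
    loo_evaluate(data.frame(i_mri = i, dt_thermo = dt))$summary$median_err_current
  })
  # median LOO current error a few percent of the current scale
  expect_lt(median(errs), 0.01)
})

test_that("current re-referencing is linear in B1rms", {
  expect_equal(reference_current(0.1, 0.84, 2.29), 0.1 * 2.29 / 0.84)
  expect_equal(reference_current(reference_current(0.1, 0.84, 2.29),
                                 2.29, 0.84), 0.1)
})
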