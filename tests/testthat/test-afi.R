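test_that("AFI signal equations have the analytic limits", {
  sp <- nominal_seq
  # no excitation, no signal
  s <- afi_signals(0, 1000, sp, "a")
  expect_equal(c(s$s1, s$s2), c(0, 0))
  # symmetric exchange: equal flip angles and TRs give equal signals
  sym <- sequence_params(30, 30, 50, 50, 21.9, 39, 26.5, 188.5)
  s <- afi_signals(c(0.4, 1, 2.5), 800, sym, "a")
  expect_equal(s$s1, s$s2)
  # fully relaxed limit (TR >> T1): S -> sin(lambda alpha)
  s <- afi_signals(1, 1e-3, sp, "a")
  expect_equal(s$s1, sin(45.2 * pi / 180), tolerance = 1e-9)
  expect_equal(s$s2, sin(69.3 * pi / 180), tolerance = 1e-9)
})

test_that("signals reproduce the classic AFI flip-angle estimator", {
  # single flip angle, two TRs, TR1/T1 = 0.01: the ratio r = S2/S1 and
  # n = TR2/TR1 recover cos(flip) via (r n - 1)/(n - r) within 1%
  alpha <- 40
  t1 <- 1000
  spc <- sequence_params(alpha, alpha, 10, 50, 21.9, 39, 26.5, 188.5)
  lam_alpha <- seq(5, 85, by = 2.5)           # degrees
  lam <- lam_alpha / alpha
  s <- afi_signals(lam, t1, spc, "a")
  ratio <- s$s2 / s$s1
  n <- 50 / 10
  est <- (ratio * n - 1) / (n - ratio)
  expect_true(all(abs(est - cos(lam_alpha * pi / 180)) < 0.01))
})

test_that("dictionary equals direct through-plane averaging", {
  # the dictionary is a cache: at grid nodes it must equal recomputing the
  # signal equations over the simulated profile
  d <- shared_dict
  prof <- d$profile_meta$profile
  for (lam in c(0.5, 1, 3.7, 12)) {
    sa <- afi_signals(lam * prof, 1000, nominal_seq, "a")
    sb <- afi_signals(lam * prof, 1000, nominal_seq, "b")
    direct <- c(mean(sa$s1), mean(sa$s2), mean(sb$s1), mean(sb$s2))
    expect_equal(as.numeric(lookup_signals(d, lam)), direct,
                 tolerance = 1e-12)
  }
  # lambda = 0 row is all zeros
  expect_equal(as.numeric(lookup_signals(d, 0)), rep(0, 4))
})

test_that("boxcar profile collapses to the in-slice closed form", {
  # degenerate rectangular profile over +-2 slice thicknesses: 1 inside the
  # slice (a 1/4 fraction of positions), 0 outside, where signals vanish
  d <- build_slice_dictionary(nominal_seq, pulse_spec("boxcar"), t1 = 1000,
                              lambda_grid = seq(0, 3, by = 0.01),
                              n_positions = 201, z_extent = 2)
  z <- d$profile_meta$z_rel
  frac <- mean(abs(z) <= 0.5)
  sa <- afi_signals(1.4, 1000, nominal_seq, "a")
  expect_equal(lookup_signals(d, 1.4)[1, "s_a1"], unname(sa$s1 * frac),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("dictionary interpolation is linear and range-guarded", {
  d <- shared_dict
  node <- d$lambda_grid[500]
  expect_equal(as.numeric(lookup_signals(d, node)),
               unname(d$signals[500, ]))
  mid <- (d$lambda_grid[500] + d$lambda_grid[501]) / 2
  expect_equal(as.numeric(lookup_signals(d, mid)),
               unname((d$signals[500, ] + d$signals[501, ]) / 2),
               tolerance = 1e-12)
  expect_error(lookup_signals(d, -0.1), "range")
  expect_error(lookup_signals(d, max(d$lambda_grid) + 1), "range")
})

test_that("grid resolution keeps interpolation error negligible", {
  # random lambdas: interpolated vs directly recomputed signals agree to
  # well below the noise floor, validating the 0.01 grid step
  d <- shared_dict
  prof <- d$profile_meta$profile
  set.seed(11)
  lam <- runif(50, 0.1, 25)
  interp <- lookup_signals(d, lam)
  for (k in seq_along(lam)) {
    sa <- afi_signals(lam[k] * prof, 1000, nominal_seq, "a")
    sb <- afi_signals(lam[k] * prof, 1000, nominal_seq, "b")
    direct <- c(mean(sa$s1), mean(sa$s2), mean(sb$s1), mean(sb$s2))
    expect_lt(max(abs(interp[k, ] - direct)), 2e-4)
  }
})

test_that("voxel normalization has unit norm and scale invariance", {
  expect_equal(normalize_voxel(c(1, 1, 1, 1)), rep(0.5, 4))
  expect_equal(normalize_voxel(c(3, 4, 0, 0)), c(0.6, 0.8, 0, 0))
  set.seed(3)
  for (i in 1:20) {
    v <- runif(4, 0, 2)
    k <- runif(1, 1e-3, 1e3)
    expect_equal(sum(normalize_voxel(v)^2), 1, tolerance = 1e-12)
    expect_equal(normalize_voxel(k * v), normalize_voxel(v),
                 tolerance = 1e-12)
  }
  m <- rbind(c(1, 1, 1, 1), c(3, 4, 0, 0))
  expect_equal(normalize_voxel(m), rbind(rep(0.5, 4), c(0.6, 0.8, 0, 0)))
  expect_error(normalize_voxel(c(0, 0, 0, 0)), "degenerate")
})

test_that("normalized signal vectors are robust to T1 mismatch", {
  # weak-form robustness: normalized 4-vectors at T1 and 1.3 T1 stay close
  # over the working lambda range
  d13 <- build_slice_dictionary(nominal_seq, t1 = 1300,
                                lambda_grid = seq(0, 4, by = 0.01))
  for (lam in seq(0.2, 3, by = 0.4)) {
    v1 <- normalize_voxel(abs(as.numeric(lookup_signals(shared_dict, lam))))
    v2 <- normalize_voxel(abs(as.numeric(lookup_signals(d13, lam))))
    expect_lt(sqrt(sum((v1 - v2)^2)), 0.12)
  }
})

test_that("dictionary round-trips through its text serialization", {
  d <- build_slice_dictionary(nominal_seq, t1 = 900,
                              lambda_grid = seq(0, 2, by = 0.05),
                              n_positions = 51)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dictionary(d, path)
  d2 <- read_dictionary(path)
  expect_equal(d2$lambda_grid, d$lambda_grid)
  expect_equal(d2$signals, d$signals, tolerance = 1e-12)
  expect_equal(d2$seq_par, d$seq_par)
  expect_equal(d2$profile_meta$t1, 900)
})
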