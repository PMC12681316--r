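test_that("wire field magnitude matches the Ampere closed form", {
  g0 <- wire_geometry(xi = 0)
  # parallel wire: mu0 I / (2 pi r), independent of azimuth
  expect_equal(wire_field_magnitude(10, 0, g0, 0.1), 2e-6, tolerance = 1e-12)
  expect_equal(wire_field_magnitude(10, 1.3, g0, 0.1),
               wire_field_magnitude(10, -2.0, g0, 0.1))
  # transverse field at the point where the geometric factor is 1
  g45 <- wire_geometry(xi = pi / 4, theta = 0)
  expect_equal(wire_field_magnitude(10, pi / 2, g45, 0.1),
               2e-6 * cos(pi / 4), tolerance = 1e-12)
  # field strictly decreasing in r
  r <- seq(1, 20, by = 0.5)
  expect_true(all(diff(wire_field_magnitude(r, 0.7, g45, 0.1)) < 0))
  # singularity guarded
  expect_error(wire_field_magnitude(0, 0, g0, 0.1), "singular")
  # perpendicular wire is rejected at construction
  expect_error(wire_geometry(xi = pi / 2), "blind spot")
})

test_that("Biot-Savart oracle confirms the infinite-wire transverse field", {
  # +-1 m segment is >= 100x the largest evaluation radius (12 mm); the
  # in-plane projection of the numerically integrated field must match the
  # closed form within 0.5% at all tested angulations and azimuths
  for (xi_deg in c(0, 20, 45)) {
    xi <- xi_deg * pi / 180
    geo <- wire_geometry(xi = xi, theta = 0)
    u <- c(sin(xi), 0, cos(xi))
    for (r in c(2, 6, 12)) {
      for (th in seq(0, 2 * pi, length.out = 9)[-9]) {
        pt <- c(r * cos(th), r * sin(th), 0)
        b <- biot_savart_field(-1000 * u, 1000 * u, 0.1, pt)
        b_transverse <- sqrt(b[1]^2 + b[2]^2)
        expect_equal(b_transverse,
                     wire_field_magnitude(r, th, geo, 0.1),
                     tolerance = 5e-3)
      }
    }
  }
})

test_that("Biot-Savart oracle behaves at its own edge cases", {
  expect_equal(biot_savart_field(c(0, 0, -1000), c(0, 0, 1000), 0, c(10, 0, 0)),
               c(0, 0, 0))
  expect_error(biot_savart_field(c(0, 0, -10), c(0, 0, 10), 0.1, c(0, 0, 0)),
               "on the segment")
})

test_that("lambda_total reduces to the background without current", {
  p <- wire_model_params(0, 0, wire_geometry(0),
                         background_field(0.8, 0.005, -0.002))
  # gradients expand about the patch origin (the wire position itself is
  # singular and guarded)
  expect_equal(lambda_total(1, 0, p, 0.84), 0.8 + 0.005)
  expect_equal(lambda_total(4, -2, p, 0.84), 0.8 + 0.005 * 4 - 0.002 * -2)
  expect_error(lambda_total(0, 0, p, 0.84), "singular")
})

test_that("a perpendicular-regime wire leaves the background unperturbed", {
  # xi just inside the blind-spot guard: cos(xi) ~ 1e-9
  p <- wire_model_params(0.2, 1.0, wire_geometry(pi / 2 - 1e-9),
                         background_field(0.8))
  xs <- c(3, -5, 1); ys <- c(2, 0.5, -4)
  expect_equal(lambda_total(xs, ys, p, 0.84), rep(0.8, 3), tolerance = 1e-6)
  expect_false(wire_identifiable(wire_geometry(1.48), cos_xi_floor = 0.1))
  expect_true(wire_identifiable(wire_geometry(0.5)))
})

test_that("the wire artifact is symmetric along the current-phase axis", {
  # at equal radius, lambda is equal at theta_r - phi_j' = 0 and pi and
  # maximally split at +-pi/2 (null vs hotspot) - computed by brute-force
  # evaluation of the field model at xi = 0
  phi <- 0.3
  p <- wire_model_params(0.1, phi, wire_geometry(0), background_field(1))
  r <- 8
  lam_at <- function(a) lambda_total(r * cos(a + phi), r * sin(a + phi),
                                     p, 0.84)
  expect_equal(lam_at(0), lam_at(pi), tolerance = 1e-12)
  w <- 100 * 0.1 / (r * 0.84)
  expect_equal(lam_at(-pi / 2), 1 + w, tolerance = 1e-12)   # hotspot
  expect_equal(lam_at(pi / 2), abs(1 - w), tolerance = 1e-12) # null side
  expect_lt(lam_at(pi / 2), lam_at(0))
  expect_gt(lam_at(-pi / 2), lam_at(0))
})

test_that("lambda_total is continuous, nonnegative, and has the far limit", {
  p <- wire_model_params(0.001, 1.1, wire_geometry(0.3, 0.2, 0.5, -0.3),
                         background_field(1.0))
  th <- seq(-pi, pi, length.out = 721)
  for (r in c(0.5, 2, 10)) {
    lam <- lambda_total(p$geometry$x0 + r * cos(th),
                        p$geometry$y0 + r * sin(th), p, 0.84)
    expect_true(all(is.finite(lam)), info = paste("r =", r))
    expect_true(all(lam >= 0))
    expect_true(all(abs(diff(lam)) < 0.1 * max(lam)))
  }
  # far-field limit: lambda -> lambda_b (1/r decay; at r = 2 m the residual
  # perturbation of a 1 mA current is < 1e-4)
  expect_equal(lambda_total(2e3, 0, p, 0.84), 1.0, tolerance = 1e-4)
})

test_that("lambda_total is invariant under joint current/field scaling", {
  p1 <- wire_model_params(0.08, 0.5, wire_geometry(0.4, 1.0),
                          background_field(1.1))
  p2 <- p1; p2$i_rms <- 3 * p1$i_rms
  xs <- c(4, -3, 7); ys <- c(1, 5, -2)
  expect_equal(lambda_total(xs, ys, p1, 0.84),
               lambda_total(xs, ys, p2, 3 * 0.84), tolerance = 1e-12)
})

test_that("current sensitivity of lambda scales with cos(xi)", {
  # d lambda / d I at the hotspot azimuth, fixed position
  sens <- function(xi) {
    pa <- wire_model_params(0.100, 0, wire_geometry(xi), background_field(1))
    pb <- wire_model_params(0.101, 0, wire_geometry(xi), background_field(1))
    (lambda_total(0, -6, pb, 0.84) - lambda_total(0, -6, pa, 0.84)) / 0.001
  }
  s0 <- sens(0)
  for (xi in c(0.3, 0.6, 1.0))
    expect_equal(sens(xi) / s0, cos(xi), tolerance = 0.02)
})
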