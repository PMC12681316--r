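#' Wire geometry
#'
#' Describes the orientation and in-plane position of a straight wire-like
#' conductor relative to the imaging slice. The slice is axial (perpendicular
#' to B0). The patch coordinate system has its origin at the geometric center
#' of the patch, `x` along image columns increasing rightward, `y` along rows
#' increasing upward, distances in mm, and the in-plane azimuth measured
#' counterclockwise from +x.
#'
#' @param xi angle between the wire and B0, radians. Must satisfy
#'   `abs(xi) < pi/2`: a wire exactly perpendicular to B0 produces no
#'   transverse field perturbation and its current is unobservable.
#' @param theta azimuthal angle of the wire's in-plane projection, radians.
#' @param x0,y0 offsets of the wire's slice crossing point from the patch
#'   origin, mm.
#' @return An object of class `wire_geometry`.
#' @export
wire_geometry <- function(xi = 0, theta = 0, x0 = 0, y0 = 0) {
  stopifnot(is.finite(xi), is.finite(theta), is.finite(x0), is.finite(y0))
  if (abs(xi) >= pi / 2)
    stop("abs(xi) must be < pi/2: a wire perpendicular to B0 is a model blind spot")
  structure(list(xi = xi, theta = theta, x0 = x0, y0 = y0),
            class = "wire_geometry")
}

#' Background transmit field
#'
#' Smooth background B1+ over the patch, expressed relative to the nominal
#' transmit field, with an optional first-order spatial expansion about the
#' patch center.
#'
#' @param lambda_b background B1+ in units of the nominal B1+ (dimensionless,
#'   > 0).
#' @param lambda_b_dx,lambda_b_dy linear spatial gradients of `lambda_b`,
#'   per mm, expanded about the patch center.
#' @param phi_b phase of the background B1+, radians. Stored for completeness;
#'   only the phase of the wire current relative to `phi_b` affects magnitude
#'   signals.
#' @return An object of class `background_field`.
#' @export
background_field <- function(lambda_b = 1, lambda_b_dx = 0, lambda_b_dy = 0,
                             phi_b = 0) {
  stopifnot(is.finite(lambda_b), lambda_b > 0,
            is.finite(lambda_b_dx), is.finite(lambda_b_dy), is.finite(phi_b))
  structure(list(lambda_b = lambda_b, lambda_b_dx = lambda_b_dx,
                 lambda_b_dy = lambda_b_dy, phi_b = phi_b),
            class = "background_field")
}

#' Sample-dependent parameters of the forward field model
#'
#' Bundles the ten sample-dependent parameters describing the RF current in
#' the wire and the background transmit field: current amplitude, current
#' phase, background amplitude and its two in-plane gradients, the two wire
#' angles, the two wire offsets, and the background phase. Only the phase
#' difference between wire current and background (`phi_j_prime`) is
#' identifiable from magnitude images; the absolute background phase is kept
#' as an inert field.
#'
#' @param i_rms RMS RF current in the wire, amperes, referenced to the
#'   sequence's background B1rms. Must be >= 0.
#' @param phi_j_prime phase of the wire current relative to the background
#'   B1+ phase, radians.
#' @param geometry a [wire_geometry()].
#' @param background a [background_field()].
#' @return An object of class `wire_model_params`.
#' @export
wire_model_params <- function(i_rms = 0, phi_j_prime = 0,
                              geometry = wire_geometry(),
                              background = background_field()) {
  stopifnot(is.finite(i_rms), i_rms >= 0, is.finite(phi_j_prime),
            inherits(geometry, "wire_geometry"),
            inherits(background, "background_field"))
  structure(list(i_rms = i_rms, phi_j_prime = phi_j_prime,
                 geometry = geometry, background = background),
            class = "wire_model_params")
}

# Squared geometric factor g^2 = 1 - sin^2(xi) cos^2(theta_r - theta_j).
# (r * g) is the perpendicular distance from a point at in-plane cylindrical
# coordinates (r, theta_r) to the tilted wire line.
.geom_factor2 <- function(theta_r, xi, theta_j) {
  1 - sin(xi)^2 * cos(theta_r - theta_j)^2
}

#' Transverse field magnitude of a straight current-carrying wire
#'
#' Magnitude of the in-plane (transverse to B0) component of the quasi-static
#' magnetic field generated by an RF current on an infinite straight wire at
#' angle `xi` to B0, evaluated in the axial plane at cylindrical coordinates
#' `(r, theta_r)` about the wire's crossing point. Derived from Ampere's law:
#' the transverse component is purely azimuthal with magnitude
#'
#'   mu0 * mu_r * I * cos(xi) / (2 * pi * r * g^2),
#'
#' where `g^2 = 1 - sin(xi)^2 * cos(theta_r - theta_j)^2` and `r * g` is the
#' perpendicular distance to the wire. For `xi = 0` this reduces to the
#' textbook `mu0 I / (2 pi r)`; for `xi = pi/2` (wire perpendicular to B0)
#' the transverse component vanishes everywhere off the wire.
#'
#' @param r radial distance from the wire crossing point in the axial plane,
#'   mm; must be > 0 (the wire position is singular).
#' @param theta_r azimuthal coordinate in the axial plane, radians.
#' @param geometry a [wire_geometry()].
#' @param i_rms RMS current, amperes.
#' @param mu_r relative permeability of the medium (1 for tissue and gel).
#' @return Field magnitude in tesla, vectorized over `r` and `theta_r`.
#' @export
wire_field_magnitude <- function(r, theta_r, geometry, i_rms, mu_r = 1) {
  if (any(r <= 0)) stop("r must be > 0: the wire position is singular")
  g2 <- .geom_factor2(theta_r, geometry$xi, geometry$theta)
  MU0 * mu_r * i_rms * cos(geometry$xi) / (2 * pi * (r * 1e-3) * g2)
}

#' Relative total transmit field around the wire
#'
#' Total B1+ magnitude relative to the nominal transmit field at in-plane
#' position `(x, y)` (mm, patch-centered coordinates). The background B1+
#' (amplitude `lambda_b` with first-order spatial gradients) is superposed
#' with the left-circularly polarized half of the linearly polarized wire
#' field, giving
#'
#'   lambda = lambda_b * sqrt(1 + W^2 - 2 W sin(theta_r - phi_j')),
#'
#' with `W = mu0 mu_r I_rms cos(xi) / (4 pi r g^2 lambda_b B1rms)` the wire
#' field's circular component in units of the local background field. Because
#' the current is induced by the same excitation that produces the background
#' field, the ratio of instantaneous current to nominal field equals the
#' ratio of their RMS values, so RMS quantities are used throughout.
#'
#' @param x,y in-plane coordinates, mm, relative to the patch center;
#'   vectorized. Must not coincide with the wire crossing point.
#' @param params a [wire_model_params()].
#' @param b1_rms nominal B1rms of the acquisition sequence, microtesla.
#' @param mu_r relative permeability (default 1).
#' @return Dimensionless relative field `lambda >= 0`, same length as `x`.
#' @export
lambda_total <- function(x, y, params, b1_rms, mu_r = 1) {
  geo <- params$geometry
  bg <- params$background
  dx <- x - geo$x0
  dy <- y - geo$y0
  r <- sqrt(dx^2 + dy^2)
  if (any(r == 0)) stop("field requested at the wire position (singular)")
  theta_r <- atan2(dy, dx)
  # background expanded about the patch center (not the wire)
  lb <- bg$lambda_b + bg$lambda_b_dx * x + bg$lambda_b_dy * y
  g2 <- .geom_factor2(theta_r, geo$xi, geo$theta)
  # mu0/(4 pi) = 1e-7; r in mm, b1_rms in uT -> W = 100 I cos(xi)/(r g^2 lb b1)
  w <- 100 * mu_r * params$i_rms * cos(geo$xi) / (r * g2 * lb * b1_rms)
  lb * sqrt(pmax(1 + w^2 - 2 * w * sin(theta_r - params$phi_j_prime), 0))
}

#' Check identifiability of the wire current
#'
#' The wire field scales with `cos(xi)`; as the wire approaches a
#' perpendicular orientation to B0 the current becomes unobservable. Below a
#' configurable floor on `abs(cos(xi))` a fit is flagged unidentifiable.
#'
#' @param geometry a [wire_geometry()].
#' @param cos_xi_floor identifiability threshold on `abs(cos(xi))`.
#' @return Logical.
#' @export
wire_identifiable <- function(geometry, cos_xi_floor = 0.1) {
  abs(cos(geometry$xi)) >= cos_xi_floor
}

#' Biot-Savart field of a finite straight segment
#'
#' Numerically integrated magnetic field of a constant current on a straight
#' finite segment. This is an independent oracle used to validate the
#' closed-form infinite-wire model in the long-segment limit; it is not used
#' in the fitting pipeline.
#'
#' @param p1,p2 segment endpoints, length-3 numeric vectors, mm.
#' @param i_rms current, amperes.
#' @param point evaluation point, length-3 numeric vector, mm; must not lie
#'   on the segment.
#' @param mu_r relative permeability.
#' @param rel_tol relative tolerance of the numeric quadrature.
#' @return Length-3 field vector, tesla.
#' @export
biot_savart_field <- function(p1, p2, i_rms, point, mu_r = 1,
                              rel_tol = 1e-10) {
  stopifnot(length(p1) == 3, length(p2) == 3, length(point) == 3)
  if (i_rms == 0) return(c(0, 0, 0))
  a <- p1 * 1e-3; b <- p2 * 1e-3; p <- point * 1e-3
  dl <- b - a
  # distance from point to the segment line; reject on-segment evaluation
  t0 <- sum((p - a) * dl) / sum(dl * dl)
  d <- p - (a + pmin(pmax(t0, 0), 1) * dl)
  if (sqrt(sum(d * d)) < 1e-12) stop("evaluation point lies on the segment")
  integrand <- function(t, comp) {
    # cross(dl, R) / |R|^3 with R = p - (a + t dl), vectorized over t
    rx <- p[1] - (a[1] + t * dl[1])
    ry <- p[2] - (a[2] + t * dl[2])
    rz <- p[3] - (a[3] + t * dl[3])
    r3 <- (rx^2 + ry^2 + rz^2)^1.5
    switch(comp,
           x = (dl[2] * rz - dl[3] * ry) / r3,
           y = (dl[3] * rx - dl[1] * rz) / r3,
           z = (dl[1] * ry - dl[2] * rx) / r3)
  }
  pref <- MU0 * mu_r * i_rms / (4 * pi)
  vapply(c("x", "y", "z"), function(comp) {
    pref * stats::integrate(integrand, 0, 1, comp = comp,
                            rel.tol = rel_tol, subdivisions = 2000L)$value
  }, numeric(1), USE.NAMES = FALSE)
}
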