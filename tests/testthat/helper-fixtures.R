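# Shared fixtures: the nominal sequence, a default-geometry patch, and one
# slice dictionary built once per test run (the Bloch simulation plus
# 3001-row dictionary takes well under a second).

nominal_seq <- sequence_params()
default_geom <- patch_geometry()
shared_dict <- build_slice_dictionary(nominal_seq, t1 = 1000)

# A representative tilted-wire scene used by several suites.
example_truth <- function(i_rms = 0.12) {
  wire_model_params(
    i_rms = i_rms, phi_j_prime = 0.7,
    geometry = wire_geometry(xi = 20 * pi / 180, theta = 0.4,
                             x0 = 0.6, y0 = -0.8),
    background = background_field(1.05, 0.004, -0.003))
}

# Distance of fitted to true wire position, mm.
position_error <- function(fit, truth) {
  sqrt((fit$params$geometry$x0 - truth$geometry$x0)^2 +
       (fit$params$geometry$y0 - truth$geometry$y0)^2)
}
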