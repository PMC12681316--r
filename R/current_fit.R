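# Fitted parameter vector layout used by the optimizer.
.PAR_NAMES <- c("i_rms", "phi_j_prime", "lambda_b", "lambda_b_dx",
                "lambda_b_dy", "xi", "theta", "x0", "y0")
.CIRCULAR <- c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)

.vec_to_params <- function(v) {
  wire_model_params(
    i_rms = v[1], phi_j_prime = v[2],
    geometry = wire_geometry(xi = v[6], theta = v[7], x0 = v[8], y0 = v[9]),
    background = background_field(lambda_b = v[3], lambda_b_dx = v[4],
                                  lambda_b_dy = v[5]))
}

.params_to_vec <- function(p) {
  c(p$i_rms, p$phi_j_prime, p$background$lambda_b, p$background$lambda_b_dx,
    p$background$lambda_b_dy, p$geometry$xi, p$geometry$theta,
    p$geometry$x0, p$geometry$y0)
}

#' Fit configuration for the current inversion
#'
#' Settings of the differential-evolution (DE) inversion of the patch
#' forward model. Defaults follow the reference inversion budget: a
#' population of 61 parameter sets evolved over 122 iterations, with
#' signals within a 4 mm radius of the candidate wire position masked from
#' the cost.
#'
#' @param bounds a 2-row matrix (rows `lower`, `upper`), columns named as in
#'   [default_fit_bounds()]. Use `default_fit_bounds()` to center the
#'   position bounds on an approximate wire location.
#' @param population_size DE population size (>= number of parameters + 1).
#' @param n_iterations DE generations.
#' @param mask_radius radius (mm) around the candidate wire position within
#'   which voxels are excluded from the cost. The mask is dynamic: it is
#'   recomputed from each candidate's wire position.
#' @param seed RNG seed recorded in the result; the fit is deterministic
#'   given data, config, and seed.
#' @param cos_xi_floor identifiability floor on `abs(cos(xi))`; below it the
#'   fitted current is flagged unidentifiable.
#' @param polish run a bounded local refinement (L-BFGS-B) from the DE
#'   optimum; reported in diagnostics.
#' @param f_range DE mutation factor, dithered uniformly per mutant within
#'   this range.
#' @param cr DE crossover probability.
#' @param strategy DE mutation strategy: `"best1bin"` (default; mutants are
#'   built around the current best member, which reaches the basin floor
#'   within the fixed population/iteration budget) or `"rand1bin"`.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(bounds = default_fit_bounds(),
                       population_size = 61L, n_iterations = 122L,
                       mask_radius = 4, seed = NULL, cos_xi_floor = 0.1,
                       polish = TRUE, f_range = c(0.5, 1), cr = 0.7,
                       strategy = c("best1bin", "rand1bin")) {
  strategy <- match.arg(strategy)
  stopifnot(is.matrix(bounds), nrow(bounds) == 2,
            ncol(bounds) == length(.PAR_NAMES),
            all(bounds[1, ] <= bounds[2, ]),
            population_size >= length(.PAR_NAMES) + 1,
            n_iterations >= 1, mask_radius >= 0,
            length(f_range) == 2, f_range[1] > 0, f_range[2] <= 2,
            cr > 0, cr <= 1)
  structure(list(bounds = bounds,
                 population_size = as.integer(population_size),
                 n_iterations = as.integer(n_iterations),
                 mask_radius = mask_radius, seed = seed,
                 cos_xi_floor = cos_xi_floor, polish = polish,
                 f_range = f_range, cr = cr, strategy = strategy),
            class = "fit_config")
}

#' Default search bounds for the model parameters
#'
#' Generous bounds spanning the phantom regime while excluding the
#' perpendicular-wire blind spot: current 0-1 A, background field 0.3-2
#' times nominal, wire angle within 60 degrees of B0, and the wire crossing
#' point within 1.5 voxel pitches of a user-supplied position hint.
#'
#' @param hint approximate in-plane wire position `c(x, y)`, mm,
#'   patch-centered coordinates.
#' @param voxel_size voxel pitch used to scale the position bounds, mm.
#' @return A 2 x 9 bounds matrix (rows `lower`, `upper`).
#' @export
default_fit_bounds <- function(hint = c(0, 0), voxel_size = 2) {
  half <- 1.5 * voxel_size
  b <- rbind(
    lower = c(0,   -pi, 0.3, -0.02, -0.02, -pi / 3, -pi,
              hint[1] - half, hint[2] - half),
    upper = c(1,    pi, 2,    0.02,  0.02,  pi / 3,  pi,
              hint[1] + half, hint[2] + half))
  colnames(b) <- .PAR_NAMES
  b
}

# Internal cost: RMS residual between model and data over unmasked,
# nondegenerate voxels. Returns Inf when nothing remains. `grids` and the
# flattened data are precomputed by the caller.
.cost_eval <- function(v, data_sig, data_degen, seq_par, dict, geom, grids,
                       mask_radius) {
  params <- .vec_to_params_fast(v)
  fw <- .forward_raw(params, seq_par, dict, geom, grids)
  raw_mag <- abs(fw$raw)
  nrm <- sqrt(rowSums(raw_mag^2))
  model <- raw_mag / nrm
  d2 <- (grids$vx - v[8])^2 + (grids$vy - v[9])^2
  keep <- !(fw$degenerate | data_degen) & d2 >= mask_radius^2
  if (!any(keep)) return(Inf)
  res <- model[keep, , drop = FALSE] - data_sig[keep, , drop = FALSE]
  sqrt(mean(res * res))
}

# Validation-free construction for the optimizer's inner loop.
.vec_to_params_fast <- function(v) {
  structure(list(
    i_rms = v[1], phi_j_prime = v[2],
    geometry = structure(list(xi = v[6], theta = v[7], x0 = v[8], y0 = v[9]),
                         class = "wire_geometry"),
    background = structure(list(lambda_b = v[3], lambda_b_dx = v[4],
                                lambda_b_dy = v[5], phi_b = 0),
                           class = "background_field")),
    class = "wire_model_params")
}

#' RMS cost of a candidate parameter set against measured signals
#'
#' Root-mean-square difference between the normalized signals simulated by
#' the forward model at `params` and the normalized data, over all voxels
#' that are not degenerate (in data or model) and whose center lies at
#' least `mask_radius` from the candidate wire position. The mask follows
#' the candidate's wire position, not a fixed location.
#'
#' @param params a [wire_model_params()].
#' @param data a `signal_patch` with normalized signals.
#' @param seq_par a [sequence_params()].
#' @param dict a slice dictionary.
#' @param geom a [patch_geometry()].
#' @param mask_radius mask radius, mm.
#' @return The RMS residual (dimensionless). Errors if every voxel is
#'   masked.
#' @export
patch_cost <- function(params, data, seq_par, dict, geom = data$geometry,
                       mask_radius = 4) {
  stopifnot(inherits(data, "signal_patch"))
  grids <- .patch_grids(geom)
  data_sig <- .flatten_patch(data)
  cost <- .cost_eval(.params_to_vec(params), data_sig$signals,
                     data_sig$degenerate, seq_par, dict, geom, grids,
                     mask_radius)
  if (!is.finite(cost)) stop("all voxels masked or degenerate: cost undefined")
  cost
}

# signal_patch -> (n_vox x 4 matrix, degenerate vector), column-major order
# matching .patch_grids().
.flatten_patch <- function(patch) {
  n <- patch$geometry$n_voxels
  m <- matrix(NA_real_, n * n, 4)
  for (k in 1:4) m[, k] <- as.vector(patch$signals[, , k])
  list(signals = m, degenerate = as.vector(patch$degenerate))
}

#' Fit the wire current and model parameters to a signal patch
#'
#' Inverts the forward model by global stochastic optimization: a
#' rand/1/bin differential-evolution search (Latin-hypercube initialization,
#' dithered mutation factor, greedy selection) over the nine identifiable
#' model parameters, minimizing the RMS difference between modeled and
#' measured normalized signals. Signals within `mask_radius` of each
#' candidate's wire position are masked dynamically. Angular parameters
#' (current phase and in-plane wire azimuth) wrap circularly; other
#' parameters reflect at the bounds. An optional bounded local polish
#' refines the DE optimum.
#'
#' The sign degeneracy of the wire orientation (the field is invariant
#' under `xi -> -xi` and `theta -> theta + pi`) is resolved by reporting
#' the representative with `xi >= 0`. When the fitted wire is close to
#' perpendicular to B0 (`abs(cos(xi))` below the configured floor) the
#' current is unobservable and the result is flagged unidentifiable.
#'
#' @param data a `signal_patch` of normalized measured (or synthetic)
#'   signals.
#' @param seq_par a [sequence_params()].
#' @param dict a slice dictionary covering the field range of the scene.
#' @param geom a [patch_geometry()] (defaults to the data's geometry).
#' @param config a [fit_config()].
#' @return An object of class `fit_result`: fitted [wire_model_params()],
#'   `rms_residual`, `n_masked_voxels` at the fitted position, `converged`
#'   and `identifiable` flags, and diagnostics (cost trace, evaluation
#'   count, seed, bounds, polish report).
#' @export
fit_patch <- function(data, seq_par, dict, geom = data$geometry,
                      config = fit_config()) {
  stopifnot(inherits(data, "signal_patch"), inherits(config, "fit_config"))
  if (!is.null(config$seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(config$seed)
  }
  lo <- config$bounds[1, ]; hi <- config$bounds[2, ]
  d <- length(lo)
  np <- config$population_size
  grids <- .patch_grids(geom)
  flat <- .flatten_patch(data)
  cost_fn <- function(v) .cost_eval(v, flat$signals, flat$degenerate,
                                    seq_par, dict, geom, grids,
                                    config$mask_radius)
  # Latin-hypercube initialization over the box
  pop <- t(lo + t(lhs::randomLHS(np, d)) * (hi - lo))
  costs <- apply(pop, 1, cost_fn)
  n_eval <- np
  trace <- numeric(config$n_iterations)
  use_best <- config$strategy == "best1bin"
  for (g in seq_len(config$n_iterations)) {
    f <- stats::runif(np, config$f_range[1], config$f_range[2])
    i_best <- which.min(costs)
    for (i in seq_len(np)) {
      idx <- sample.int(np, 3)
      while (any(idx == i)) idx <- sample.int(np, 3)
      v <- if (use_best)
        pop[i_best, ] + f[i] * (pop[idx[1], ] - pop[idx[2], ])
      else
        pop[idx[1], ] + f[i] * (pop[idx[2], ] - pop[idx[3], ])
      # circular parameters wrap; others reflect into the box
      v[.CIRCULAR] <- .wrap_angle(v[.CIRCULAR])
      below <- !.CIRCULAR & v < lo; v[below] <- (2 * lo - v)[below]
      above <- !.CIRCULAR & v > hi; v[above] <- (2 * hi - v)[above]
      v <- pmin(pmax(v, lo), hi)
      cross <- stats::runif(d) < config$cr
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, v, pop[i, ])
      ct <- cost_fn(trial)
      n_eval <- n_eval + 1
      if (ct <= costs[i]) {
        pop[i, ] <- trial
        costs[i] <- ct
        if (ct < costs[i_best]) i_best <- i
      }
    }
    trace[g] <- min(costs)
  }
  ord <- order(costs)
  best <- pop[ord[1], ]
  best_cost <- costs[ord[1]]
  polish_info <- NULL
  if (isTRUE(config$polish)) {
    # finite-difference steps scaled to each parameter's search interval;
    # the default step is far too coarse for the mm- and rad-scale parameters
    ndeps <- pmax((hi - lo) * 1e-7, 1e-9)
    improvement <- 0
    for (s in seq_len(min(3L, np))) {
      start <- pop[ord[s], ]
      # the cost is 2*pi-periodic in the circular parameters: center their
      # polish bounds on the start point so the optimum is never blocked by
      # the wrap point
      plo <- lo; phi_ <- hi
      plo[.CIRCULAR] <- start[.CIRCULAR] - pi
      phi_[.CIRCULAR] <- start[.CIRCULAR] + pi
      opt <- try(stats::optim(start, cost_fn, method = "L-BFGS-B",
                              lower = plo, upper = phi_,
                              control = list(maxit = 500, factr = 10,
                                             ndeps = ndeps)),
                 silent = TRUE)
      if (inherits(opt, "try-error") || !is.finite(opt$value)) next
      n_eval <- n_eval + sum(opt$counts, na.rm = TRUE)
      if (opt$value <= best_cost) {
        improvement <- improvement + best_cost - opt$value
        best <- opt$par
        best[.CIRCULAR] <- .wrap_angle(best[.CIRCULAR])
        best_cost <- opt$value
      }
    }
    polish_info <- list(applied = TRUE, improvement = improvement)
  }
  # canonical orientation representative
  if (best[6] < 0) best[6] <- -best[6]
  best[c(2, 7)] <- .wrap_angle(best[c(2, 7)])
  params <- .vec_to_params(best)
  d2 <- (grids$vx - best[8])^2 + (grids$vy - best[9])^2
  masked <- d2 < config$mask_radius^2 | flat$degenerate
  structure(list(params = params,
                 rms_residual = best_cost,
                 n_masked_voxels = sum(masked),
                 converged = is.finite(best_cost),
                 identifiable = abs(cos(best[6])) >= config$cos_xi_floor,
                 diagnostics = list(cost_trace = trace, n_eval = n_eval,
                                    seed = config$seed,
                                    bounds = config$bounds,
                                    polish = polish_info)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  p <- x$params
  cat("Wire-current fit\n")
  cat(sprintf("  I_rms       : %.1f mA%s\n", 1000 * p$i_rms,
              if (!x$identifiable) "  [UNIDENTIFIABLE: wire near perpendicular]" else ""))
  cat(sprintf("  wire angle  : %.1f deg to B0, azimuth %.1f deg\n",
              p$geometry$xi * 180 / pi, p$geometry$theta * 180 / pi))
  cat(sprintf("  position    : (%.2f, %.2f) mm\n", p$geometry$x0, p$geometry$y0))
  cat(sprintf("  lambda_b    : %.3f (grad %.4f, %.4f /mm)\n",
              p$background$lambda_b, p$background$lambda_b_dx,
              p$background$lambda_b_dy))
  cat(sprintf("  RMS residual: %.3g  (%d voxels masked)\n",
              x$rms_residual, x$n_masked_voxels))
  invisible(x)
}
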