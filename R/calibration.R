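#' RMS marker-position error
#'
#' Root-mean-square coordinate difference between simulated and reference
#' marker positions, over all markers, samples and components.
#'
#' @param simulated,reference Arrays of identical shape (any of: m x 3
#'   matrices or n x m x 3 arrays).
#' @return RMS error in mm; zero iff the inputs are identical.
#' @export
rms_marker_error <- function(simulated, reference) {
  if (!identical(dim(simulated), dim(reference)))
    stop("marker arrays must have identical shape")
  sqrt(mean((simulated - reference)^2))
}

# Forward model: marker trajectories for a given parameter set under the
# record's load protocol (warm-started staircase of solves). The marker
# interpolation operator and unit force pattern are built once; an optional
# cache environment carries per-level solutions between calls so that
# successive parameter sets (as in an optimizer) warm-start each level.
forward_markers <- function(mesh, fiber_field, params, record,
                            control = list(), cache = NULL) {
  forces <- record$applied_force
  traj <- array(0, dim(record$marker_trajectories))
  S <- point_interp_matrix(mesh, record$markers_ref)
  funit <- proximal_force_matrix(mesh, 1)
  u <- NULL
  u_levels <- vector("list", length(forces))
  ctl <- utils::modifyList(list(n_steps = 4), control)
  use_cache <- !is.null(cache) && !is.null(cache$u_levels) &&
    length(cache$u_levels) == length(forces)
  for (i in seq_along(forces)) {
    bc <- boundary_conditions(fixed_nodes = mesh$distal_nodes,
                              forces = funit * forces[i])
    warm <- if (use_cache) cache$u_levels[[i]] else u
    rf <- if (i > 2) forces[i - 1] / forces[i] else 0
    ctl$u0 <- warm
    ctl$n_steps <- if (i > 1 || !is.null(warm)) 1 else 4
    ctl$ramp_from <- if (use_cache) 1 else rf
    # a stale cached start cannot be rescued by load bisection
    ctl$max_bisect <- if (use_cache) 0 else solve_control()$max_bisect
    res <- solve_static(mesh, fiber_field, params, bc, control = ctl)
    if (!res$converged && use_cache) {
      # cached solutions too stale for these parameters: drop the cache
      # and continue on the fresh staircase path
      use_cache <- FALSE
      ctl$u0 <- u
      ctl$n_steps <- if (i > 1) 1 else 4
      ctl$ramp_from <- rf
      ctl$max_bisect <- solve_control()$max_bisect
      res <- solve_static(mesh, fiber_field, params, bc, control = ctl)
    }
    if (!res$converged) return(NULL)
    u <- res$nodal_displacements
    u_levels[[i]] <- u
    traj[i, , ] <- record$markers_ref + as.matrix(S %*% u)
  }
  if (!is.null(cache)) cache$u_levels <- u_levels
  traj
}

#' Estimate the straightened-collagen modulus from the stress-strain curve
#'
#' Converts the record to an axial Cauchy stress-stretch curve (nominal
#' stress `F/CSA_ref` times the stretch, with the stretch measured between
#' the two end markers), fits a least-squares line through the upper 30% of
#' the force range, and subtracts the linearized ground-substance
#' contribution `c1 (2 lam + lam^-2)` of the incompressible uniaxial closed
#' form. With the default `c1 = 0` this is the raw terminal gradient of the
#' stress-strain curve.
#'
#' @param record An `experiment_record`.
#' @param c1 Ground-substance modulus used for the matrix correction, MPa.
#' @param top_fraction Fraction of the force range regarded as the linear
#'   regime (default 0.3).
#' @return Estimated `c5` in MPa.
#' @export
estimate_c5 <- function(record, c1 = 0, top_fraction = 0.3) {
  traj <- record$marker_trajectories
  m <- dim(traj)[2]
  L <- sqrt(rowSums((traj[, m, ] - traj[, 1, ])^2))
  L0 <- sqrt(sum((record$markers_ref[m, ] - record$markers_ref[1, ])^2))
  lam <- L / L0
  sig <- record$applied_force / record$csa_ref * lam
  fr <- record$applied_force
  sel <- fr >= max(fr) - top_fraction * (max(fr) - min(fr))
  if (sum(sel) < 2) stop("too few samples in the terminal force range")
  lamstar <- if (!is.null(record$true_params)) record$true_params$lambda_star
             else 1.03
  if (max(lam) <= lamstar + 0.002)
    stop("record lies entirely in the toe/uncrimping region; ",
         "cannot estimate the straightened-collagen modulus")
  fit <- stats::lm.fit(cbind(1, lam[sel]), sig[sel])
  slope <- fit$coefficients[2]
  lbar <- mean(lam[sel])
  unname(slope - c1 * (2 * lbar + lbar^-2))
}

#' Inverse estimation of the material coefficients
#'
#' Estimates (`c1`, `c3`, `c4`) by minimizing the RMS marker-position error
#' between forward finite-element simulations and the recorded trajectories,
#' with `c5` and `lambda_star` held fixed. The search is a bounded simplex
#' (Nelder-Mead on a log-box transform of the parameters) with seeded
#' multistart; `c6` is recomputed from the continuity condition inside every
#' objective evaluation. Ties between equal-objective starts go to the
#' smallest `c4`.
#'
#' @param record An `experiment_record`.
#' @param mesh,fiber_field Model on which to simulate.
#' @param c5 Fixed straightened-collagen modulus, MPa (e.g. from
#'   [estimate_c5()]).
#' @param lambda_star Fixed uncrimping stretch.
#' @param bounds Named list of length-2 ranges for `c1`, `c3`, `c4`
#'   (defaults span the coefficient ranges reported for human Achilles
#'   specimens: c1 in [1,300], c3 in [0.1,60], c4 in [1,200]).
#' @param n_starts Number of multistart points (default 5; the first is the
#'   box center, the rest are seeded uniform draws in log space).
#' @param seed RNG seed for the starts.
#' @param maxit Simplex iterations per start.
#' @param start Optional explicit first start `c(c1, c3, c4)` (e.g. the fit
#'   from a neighboring twist angle), replacing the box center.
#' @param polish Restart the simplex once from the best point found
#'   (default TRUE): a fresh simplex reliably escapes the collapsed one on
#'   the correlated (c3, c4) ridge.
#' @param control Solver control overrides for the forward solves.
#' @return A `calibration_result`: fitted [material_params()], achieved RMS
#'   error (mm), per-start objective history, bounds and seeds used.
#' @export
optimize_material <- function(record, mesh, fiber_field, c5,
                              lambda_star = 1.03,
                              bounds = list(c1 = c(1, 300), c3 = c(0.1, 60),
                                            c4 = c(1, 200)),
                              n_starts = 5, seed = 1, maxit = 150,
                              start = NULL, polish = TRUE,
                              control = list()) {
  lb <- log(c(bounds$c1[1], bounds$c3[1], bounds$c4[1]))
  ub <- log(c(bounds$c1[2], bounds$c3[2], bounds$c4[2]))
  to_par <- function(t) exp(lb + (ub - lb) * (tanh(t) + 1) / 2)
  n_eval <- 0L
  cache <- new.env(parent = emptyenv())
  objective <- function(t) {
    p <- to_par(t)
    params <- material_params(c1 = p[1], c3 = p[2], c4 = p[3], c5 = c5,
                              lambda_star = lambda_star)
    n_eval <<- n_eval + 1L
    traj <- forward_markers(mesh, fiber_field, params, record, control,
                            cache = cache)
    if (is.null(traj)) return(1e6)
    rms_marker_error(traj, record$marker_trajectories)
  }
  set.seed(seed)
  # start fractions inside the log box (kept off the saturating bounds)
  starts <- matrix(stats::runif(3 * n_starts, 0.15, 0.85), n_starts, 3)
  starts[1, ] <- if (is.null(start)) 0.5 else
    pmin(0.98, pmax(0.02, (log(start) - lb) / (ub - lb)))
  runs <- vector("list", n_starts)
  for (k in seq_len(n_starts)) {
    opt <- stats::optim(atanh(2 * starts[k, ] - 1), objective,
                        method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    runs[[k]] <- list(par = to_par(opt$par), value = opt$value,
                      counts = opt$counts[1])
  }
  vals <- vapply(runs, `[[`, 0, "value")
  c4s <- vapply(runs, function(r) r$par[3], 0)
  best_val <- min(vals)
  cand <- which(vals <= best_val + 1e-9)
  best <- cand[which.min(c4s[cand])]
  p <- runs[[best]]$par
  if (polish && best_val < 1e6) {
    from_par <- function(pp) atanh(pmin(0.999, pmax(-0.999,
      2 * (log(pp) - lb) / (ub - lb) - 1)))
    opt <- stats::optim(from_par(p), objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    if (opt$value <= best_val + 1e-12) {
      p <- to_par(opt$par)
      vals[best] <- opt$value
      runs[[best]] <- list(par = p, value = opt$value,
                           counts = runs[[best]]$counts + opt$counts[1])
    }
  }
  fitted <- material_params(c1 = p[1], c3 = p[2], c4 = p[3], c5 = c5,
                            lambda_star = lambda_star)
  structure(list(
    fitted_params = fitted, rms_error = vals[best],
    iterations = sum(vapply(runs, `[[`, 0, "counts")),
    n_forward_evals = n_eval,
    objective_history = vals, bounds = bounds,
    multistart_seeds = seed, best_start = best), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "calibration_result: RMS %.4g mm (best of %d starts, %d simplex iters)\n",
    x$rms_error, length(x$objective_history), x$iterations))
  print(x$fitted_params)
  invisible(x)
}
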