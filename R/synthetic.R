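#' Population model for synthetic tendon subjects
#'
#' Describes subject-to-subject variability of the quantities the pipeline
#' needs: tendon cross-sectional area, the five material coefficients and
#' the fascicle twist angle. Positive quantities are drawn log-normally
#' (moment-matched to the given mean/sd, so sd = 0 reproduces the mean
#' exactly); the twist angle is drawn normally and clamped to [0, 90]
#' degrees. Defaults emulate the adult human Achilles free tendon: mid CSA
#' about 70 mm^2, straightened-collagen modulus about 1.2 GPa, and the
#' cadaveric twist distribution (range about 11-65 degrees, mean 37) with
#' sd 14 degrees.
#'
#' @param csa_mean,csa_sd Mid-tendon cross-sectional area, mm^2.
#' @param c5_mean,c5_sd Straightened-collagen modulus, MPa.
#' @param twist_mean,twist_sd Total fascicle twist, degrees.
#' @param c1_mean,c1_sd Ground-substance modulus, MPa.
#' @param c3_mean,c3_sd Fiber exponential scale, MPa.
#' @param c4_mean,c4_sd Fiber uncrimping rate.
#' @param lambda_star Uncrimping stretch (fixed across the population).
#' @return A `population_model` object.
#' @export
population_model <- function(csa_mean = 70, csa_sd = 12,
                             c5_mean = 1200, c5_sd = 250,
                             twist_mean = 37, twist_sd = 14,
                             c1_mean = 50, c1_sd = 20,
                             c3_mean = 12, c3_sd = 5,
                             c4_mean = 45, c4_sd = 15,
                             lambda_star = 1.03) {
  p <- list(csa_mean = csa_mean, csa_sd = csa_sd, c5_mean = c5_mean,
            c5_sd = c5_sd, twist_mean = twist_mean, twist_sd = twist_sd,
            c1_mean = c1_mean, c1_sd = c1_sd, c3_mean = c3_mean,
            c3_sd = c3_sd, c4_mean = c4_mean, c4_sd = c4_sd,
            lambda_star = lambda_star)
  sds <- unlist(p[grep("_sd$", names(p))])
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  structure(p, class = "population_model")
}

# Moment-matched log-normal draw (exactly the mean when sd = 0).
rlnorm_mm <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Baseline free-tendon cross-section profile
#'
#' A 60 mm free Achilles tendon with elliptical sections at 0, 20, 40 and
#' 60 mm (the latter three mirroring the 2/4/6 cm ultrasound planes used for
#' subject-specific geometry), a slightly waisted mid-portion, medio-lateral
#' aspect ratio about 2.8, and a gentle medial/anterior bow of the centroid
#' line -- the geometric asymmetry that concentrates stress medially under
#' differential plantar-flexor loading.
#'
#' @param csa_mid Target mid-tendon (30 mm) cross-sectional area, mm^2.
#' @return A [cross_section_profile()].
#' @export
default_profile <- function(csa_mid = 70) {
  base <- data.frame(
    station_mm     = c(0, 20, 40, 60),
    csa            = c(75, 62, 60, 66),
    aspect         = 2.8,
    offset_x_mm    = c(0, 1.2, 2.8, 4.5),
    offset_y_mm    = c(0, 0.3, 1.0, 2.0))
  # scale all sections so the interpolated 30 mm CSA hits the target
  csa30 <- mean(base$csa[2:3])
  base$csa <- base$csa * csa_mid / csa30
  a <- sqrt(base$csa * base$aspect / pi)
  cross_section_profile(data.frame(
    station_mm = base$station_mm,
    semi_axis_a_mm = a, semi_axis_b_mm = a / base$aspect,
    offset_x_mm = base$offset_x_mm, offset_y_mm = base$offset_y_mm))
}

#' Draw a synthetic subject from the population model
#'
#' Reproducible given the seed: returns the subject's cross-section profile
#' (the baseline geometry scaled to the drawn CSA), material parameters and
#' total fascicle twist angle (clamped to [0, 90] degrees).
#'
#' @param population A [population_model()].
#' @param seed Integer RNG seed.
#' @return A `synthetic_subject`: list with `profile`, `params`,
#'   `twist_deg`, `csa`, `seed`.
#' @export
draw_subject <- function(population, seed) {
  p <- population
  set.seed(seed)
  csa <- rlnorm_mm(1, p$csa_mean, p$csa_sd)
  c1 <- rlnorm_mm(1, p$c1_mean, p$c1_sd)
  c3 <- rlnorm_mm(1, p$c3_mean, p$c3_sd)
  c4 <- rlnorm_mm(1, p$c4_mean, p$c4_sd)
  c5 <- rlnorm_mm(1, p$c5_mean, p$c5_sd)
  twist <- max(0, min(90, stats::rnorm(1, p$twist_mean, p$twist_sd)))
  structure(list(
    profile = default_profile(csa_mid = csa),
    params = material_params(c1 = c1, c3 = c3, c4 = c4, c5 = c5,
                             lambda_star = p$lambda_star),
    twist_deg = twist, csa = csa, seed = seed), class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf(
    "synthetic_subject (seed %d): CSA %.1f mm^2, twist %.1f deg\n",
    x$seed, x$csa, x$twist_deg))
  print(x$params)
  invisible(x)
}

#' Default marker layout: six equidistant surface markers
#'
#' Markers run from the distal to the proximal end of the free tendon along
#' the posterior surface (the side imaged by the camera in bench tests).
#'
#' @param mesh A `tendon_mesh`.
#' @param n_markers Number of markers (default 6).
#' @return Matrix of reference marker coordinates (n x 3).
#' @export
default_markers <- function(mesh, n_markers = 6) {
  f <- profile_interp(mesh$profile)
  zt <- seq(0.02, 0.98, length.out = n_markers)
  z <- f$z0 + zt * (f$z1 - f$z0)
  cbind(f$ox(z), f$oy(z) - f$b(z), z)
}

#' Simulate a uniaxial stretch experiment with marker tracking
#'
#' Runs the forward finite-element model at each sampled load level of a
#' ramp protocol (distal face clamped, total axial force applied over the
#' proximal face by tributary area), records the convected positions of the
#' surface markers, and adds i.i.d. Gaussian position noise. The protocol
#' default ramps from 0 to 6 kN in 10 levels, spanning the toe, uncrimping
#' and linear regimes that the material characterization needs.
#'
#' @param mesh A `tendon_mesh`.
#' @param fiber_field A `fiber_field`.
#' @param true_params Ground-truth [material_params()].
#' @param protocol List with `n_levels` and either `peak_force` (N) or
#'   `peak_stress` (MPa; the peak force is then `peak_stress` times the
#'   reference mid CSA, emulating bench protocols that load specimens to a
#'   target nominal stress below failure).
#' @param noise_sd Marker position noise, mm (default 0.1).
#' @param seed RNG seed for the noise.
#' @param markers Optional reference marker positions (default
#'   [default_markers()]).
#' @param control Solver control overrides.
#' @return An `experiment_record`: times (s), forces (N, starting at 0),
#'   reference marker positions, noisy trajectories
#'   (`(n_levels + 1) x n_markers x 3`), the
#'   noiseless trajectories, `noise_sd`, reference mid CSA, and the hidden
#'   ground-truth parameters.
#' @export
simulate_experiment <- function(mesh, fiber_field, true_params,
                                protocol = list(peak_stress = 80,
                                                n_levels = 10),
                                noise_sd = 0.1, seed = 1, markers = NULL,
                                control = list()) {
  if (is.null(markers)) markers <- default_markers(mesh)
  peak <- protocol$peak_force
  if (is.null(peak))
    peak <- protocol$peak_stress *
      mesh_section_csa(mesh, mean(range(mesh$z_planes)))
  forces <- seq(0, peak, length.out = protocol$n_levels + 1)
  traj <- array(0, c(length(forces), nrow(markers), 3))
  S <- point_interp_matrix(mesh, markers)
  funit <- proximal_force_matrix(mesh, 1)
  u <- NULL
  ctl <- utils::modifyList(list(n_steps = 4), control)
  for (i in seq_along(forces)) {
    bc <- boundary_conditions(fixed_nodes = mesh$distal_nodes,
                              forces = funit * forces[i])
    ctl$u0 <- u
    if (i > 1) ctl$n_steps <- 1
    ctl$ramp_from <- if (i > 2) forces[i - 1] / forces[i] else 0
    res <- solve_static(mesh, fiber_field, true_params, bc, control = ctl)
    if (!res$converged)
      stop("forward model failed to converge at ", forces[i], " N: ",
           res$diagnostics)
    u <- res$nodal_displacements
    traj[i, , ] <- markers + as.matrix(S %*% u)
  }
  set.seed(seed)
  noisy <- traj
  if (noise_sd > 0)
    noisy <- traj + array(stats::rnorm(length(traj), 0, noise_sd), dim(traj))
  structure(list(
    time = seq_along(forces), applied_force = forces,
    markers_ref = markers, marker_trajectories = noisy,
    noiseless_trajectories = traj, noise_sd = noise_sd,
    csa_ref = mesh_section_csa(mesh, mean(range(mesh$z_planes))),
    length_ref = diff(range(mesh$z_planes)),
    true_params = true_params, seed = seed), class = "experiment_record")
}

#' @export
print.experiment_record <- function(x, ...) {
  cat(sprintf(
    "experiment_record: %d load levels to %.0f N, %d markers, noise %.3g mm\n",
    length(x$applied_force), max(x$applied_force),
    nrow(x$markers_ref), x$noise_sd))
  invisible(x)
}

#' Write an experiment record as long-format CSV
#'
#' Columns: time, force_N, marker_id, x_mm, y_mm, z_mm.
#' @param record An `experiment_record`.
#' @param path CSV path.
#' @export
write_experiment_csv <- function(record, path) {
  n <- length(record$time); m <- nrow(record$markers_ref)
  df <- data.frame(
    time = rep(record$time, each = m),
    force_N = rep(record$applied_force, each = m),
    marker_id = rep(seq_len(m), n),
    x_mm = as.vector(t(record$marker_trajectories[, , 1])),
    y_mm = as.vector(t(record$marker_trajectories[, , 2])),
    z_mm = as.vector(t(record$marker_trajectories[, , 3])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
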