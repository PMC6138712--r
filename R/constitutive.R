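#' Transversely isotropic hyperelastic material parameters
#'
#' Constructs the parameter set of the tendon material model: a neo-Hookean
#' ground substance (modulus `c1`) reinforced by collagen fibers whose
#' stress-stretch law is piecewise -- zero in the crimped toe region
#' (stretch below 1), exponential while fibers uncrimp (between 1 and
#' `lambda_star`), and linear with modulus `c5` once straightened. The
#' linear-branch offset `c6` is fully determined by continuity at
#' `lambda_star` and is computed via [c6_from_continuity()]; passing an
#' inconsistent `c6` is an error. Near-incompressibility is enforced by a
#' volumetric penalty `kappa` (default `1000 * c1`).
#'
#' Units throughout the package are mm, N and MPa.
#'
#' @param c1 Ground-substance shear-like modulus, MPa (> 0).
#' @param c3 Fiber exponential scale, MPa (>= 0).
#' @param c4 Fiber uncrimping rate, dimensionless (> 0).
#' @param c5 Straightened-collagen modulus, MPa (>= 0).
#' @param lambda_star Uncrimping stretch (> 1); default 1.03.
#' @param kappa Volumetric penalty stiffness, MPa; default `1000 * c1`.
#' @param c6 Optional linear-branch offset, MPa. If supplied it must agree
#'   with the continuity condition to within `1e-8 * (1 + |c6|)`.
#' @return An object of class `material_params`: a named list with fields
#'   `c1, c3, c4, c5, c6, lambda_star, kappa`.
#' @examples
#' mp <- material_params(c1 = 38.07, c3 = 11.57, c4 = 30.65, c5 = 1200)
#' fiber_stress(mp, 1.02)
#' @export
material_params <- function(c1, c3, c4, c5, lambda_star = 1.03,
                            kappa = 1000 * c1, c6 = NULL) {
  stopifnot(is.numeric(c1), length(c1) == 1L, is.finite(c1))
  if (c1 <= 0) stop("c1 must be > 0")
  if (c3 < 0) stop("c3 must be >= 0")
  if (c4 <= 0) stop("c4 must be > 0")
  if (c5 < 0) stop("c5 must be >= 0")
  if (lambda_star <= 1) stop("lambda_star must be > 1")
  if (kappa <= 0) stop("kappa must be > 0")
  c6_req <- c6_from_continuity(c3, c4, c5, lambda_star)
  if (!is.null(c6)) {
    if (abs(c6 - c6_req) > 1e-8 * (1 + abs(c6_req)))
      stop("supplied c6 violates the branch-continuity condition; expected ",
           format(c6_req))
  }
  structure(list(c1 = c1, c3 = c3, c4 = c4, c5 = c5, c6 = c6_req,
                 lambda_star = lambda_star, kappa = kappa),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("Transversely isotropic hyperelastic parameters (MPa, dimensionless):\n")
  cat(sprintf("  c1=%.4g  c3=%.4g  c4=%.4g  c5=%.4g  c6=%.4g\n",
              x$c1, x$c3, x$c4, x$c5, x$c6))
  cat(sprintf("  lambda_star=%.4g  kappa=%.4g\n", x$lambda_star, x$kappa))
  invisible(x)
}

# Flat numeric vector consumed by the C++ kernels.
params_vec <- function(params) {
  c(params$c1, params$c3, params$c4, params$c5, params$c6,
    params$lambda_star, params$kappa)
}

#' Linear-branch offset from branch continuity
#'
#' The offset that makes the exponential (uncrimping) and linear
#' (straightened) branches of the fiber stress law meet at
#' `lambda_star`: `c6 = c3 (exp(c4 (l*-1)) - 1) - c5 l*`.
#'
#' @inheritParams material_params
#' @return Offset `c6` in MPa.
#' @export
c6_from_continuity <- function(c3, c4, c5, lambda_star) {
  if (lambda_star <= 1) stop("lambda_star must be > 1")
  c3 * (exp(c4 * (lambda_star - 1)) - 1) - c5 * lambda_star
}

#' Fiber stress law
#'
#' Evaluates `lambda * dF2/dlambda`, the fiber Cauchy-stress contribution at
#' fiber stretch `lam`: 0 for `lam <= 1`;
#' `c3 (exp(c4 (lam-1)) - 1)` for `1 <= lam <= lambda_star`;
#' `c5 lam + c6` beyond. Continuous by construction of `c6`. Vectorized in
#' `lam`.
#'
#' @param params A [material_params()] object.
#' @param lam Fiber stretch(es), > 0.
#' @return Fiber stress in MPa, same length as `lam`.
#' @export
fiber_stress <- function(params, lam) {
  if (any(lam <= 0)) stop("fiber stretch must be positive")
  out <- numeric(length(lam))
  mid <- lam > 1 & lam <= params$lambda_star
  top <- lam > params$lambda_star
  out[mid] <- params$c3 * (exp(params$c4 * (lam[mid] - 1)) - 1)
  out[top] <- params$c5 * lam[top] + params$c6
  out
}

# Fiber strain-energy F2(lam) by closed-form integration of each branch of
# fiber_stress(lam)/lam, with constants chosen so F2(1) = 0 and F2 is C1 at
# lambda_star. The exponential branch integrates to an exponential-integral
# term: int c3 (e^{c4(s-1)} - 1)/s ds = c3 e^{-c4} Ei(c4 s) - c3 log(s).
fiber_energy <- function(params, lam) {
  stopifnot(all(lam > 0))
  c3 <- params$c3; c4 <- params$c4; c5 <- params$c5; c6 <- params$c6
  ls <- params$lambda_star
  exp_branch <- function(l)
    c3 * exp(-c4) * (pracma::expint_Ei(c4 * l) - pracma::expint_Ei(c4)) -
      c3 * log(l)
  out <- numeric(length(lam))
  mid <- lam > 1 & lam <= ls
  top <- lam > ls
  if (any(mid)) out[mid] <- exp_branch(lam[mid])
  if (any(top))
    out[top] <- exp_branch(ls) + c5 * (lam[top] - ls) + c6 * log(lam[top] / ls)
  out
}

#' Deformation state
#'
#' Bundles a deformation gradient with the unit reference fiber direction.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param fiber_dir Reference fiber direction (3-vector, normalized
#'   internally; must be nonzero).
#' @return An object of class `deformation_state`.
#' @export
deformation_state <- function(F, fiber_dir = c(0, 0, 1)) {
  F <- matrix(as.numeric(F), 3, 3)
  if (det(F) <= 0) stop("det(F) must be positive")
  n <- sqrt(sum(fiber_dir^2))
  if (n < 1e-12) stop("fiber_dir must be nonzero")
  structure(list(F = F, fiber_dir = fiber_dir / n),
            class = "deformation_state")
}

#' Strain-energy density
#'
#' Isochoric/volumetric split: `W = c1/2 (I1bar - 3) + F2(lambda_bar) +
#' kappa/2 (ln J)^2`, where `I1bar` and the fiber stretch `lambda_bar` are
#' computed from the isochoric part of the deformation gradient. Zero in the
#' reference state and under pure rotations.
#'
#' @param params A [material_params()] object.
#' @param state A [deformation_state()].
#' @return Energy density in MPa (= mJ/mm^3).
#' @export
strain_energy <- function(params, state) {
  F <- state$F
  J <- det(F)
  if (J <= 0) stop("det(F) must be positive")
  Fb <- J^(-1 / 3) * F
  Cb <- crossprod(Fb)
  I1b <- sum(diag(Cb))
  lamb <- sqrt(drop(crossprod(state$fiber_dir, Cb %*% state$fiber_dir)))
  params$c1 / 2 * (I1b - 3) + fiber_energy(params, lamb) +
    params$kappa / 2 * log(J)^2
}

#' Cauchy stress at a material point
#'
#' Closed-form Cauchy stress of the split strain energy: traceless isochoric
#' ground-substance and fiber terms plus the volumetric pressure
#' `kappa ln(J)/J`. Symmetric and frame-indifferent; consistent with
#' numerical differentiation of [strain_energy()].
#'
#' @inheritParams strain_energy
#' @return 3x3 symmetric Cauchy stress, MPa.
#' @export
cauchy_stress <- function(params, state) {
  .tt_cauchy_point(state$F, state$fiber_dir, params_vec(params))
}

#' Closed-form incompressible uniaxial response
#'
#' Axial Cauchy stress for incompressible uniaxial stretch with the fiber
#' along the loading axis: `c1 (lam^2 - 1/lam) + fiber_stress(lam)`. Serves
#' as the analytic oracle for single-element solves and for extracting `c5`
#' from the terminal stress-strain gradient.
#'
#' @inheritParams fiber_stress
#' @return Axial Cauchy stress, MPa (vectorized in `lam`).
#' @export
uniaxial_closed_form <- function(params, lam) {
  if (any(lam <= 0)) stop("stretch must be positive")
  params$c1 * (lam^2 - 1 / lam) + fiber_stress(params, lam)
}

#' von Mises equivalent stress
#'
#' `sqrt(3/2 dev(sigma):dev(sigma))`; zero for hydrostatic states.
#'
#' @param sigma 3x3 symmetric stress tensor (MPa). Asymmetry beyond
#'   `1e-8 * (1 + max|sigma|)` is an error.
#' @return Scalar equivalent stress, MPa.
#' @export
von_mises <- function(sigma) {
  sigma <- matrix(as.numeric(sigma), 3, 3)
  if (max(abs(sigma - t(sigma))) > 1e-8 * (1 + max(abs(sigma))))
    stop("stress tensor must be symmetric")
  d <- sigma - diag(mean(diag(sigma)), 3)
  sqrt(1.5 * sum(d * d))
}

#' Write or read material parameters as a flat key-value config block
#'
#' All seven fields are written explicitly (YAML mapping of scalars), so no
#' defaults are hidden in result files.
#'
#' @param params A [material_params()] object.
#' @param path File path.
#' @return `read_material_params` returns a [material_params()] object.
#' @export
write_material_params <- function(params, path) {
  yaml::write_yaml(lapply(unclass(params), as.numeric), path)
  invisible(path)
}

#' @rdname write_material_params
#' @export
read_material_params <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("c1", "c3", "c4", "c5", "c6", "lambda_star", "kappa")
  if (!all(need %in% names(x)))
    stop("config is missing fields: ", paste(setdiff(need, names(x)), collapse = ", "))
  material_params(c1 = x$c1, c3 = x$c3, c4 = x$c4, c5 = x$c5,
                  lambda_star = x$lambda_star, kappa = x$kappa, c6 = x$c6)
}
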