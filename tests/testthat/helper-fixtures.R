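# Shared fixtures: small meshes and parameter sets reused across tests.

# Reference coefficient set (a cadaver-subject scale parameterization).
fix_params <- function(c5 = 1200, lambda_star = 1.03) {
  material_params(c1 = 38.07, c3 = 11.57, c4 = 30.65, c5 = c5,
                  lambda_star = lambda_star)
}

# Straight circular tendon: radius 5 mm, length 60 mm.
fix_circular_profile <- function(r = 5, L = 60) {
  cross_section_profile(data.frame(
    station_mm = c(0, L), semi_axis_a_mm = r, semi_axis_b_mm = r,
    offset_x_mm = 0, offset_y_mm = 0))
}

# Elliptical bowed profile at the package's default anatomical scale.
fix_bowed_profile <- function() default_profile()

fix_mesh <- function(profile = fix_circular_profile(), n_axial = 4,
                     n_circ = 4, n_radial = 4) {
  build_tendon_mesh(profile, n_axial, n_circ, n_radial)
}

# Single ~1 mm cube element (circle of radius sqrt(1/2) inscribes the unit
# square under the section mapping).
fix_single_element <- function() {
  build_tendon_mesh(cross_section_profile(data.frame(
    station_mm = c(0, 1), semi_axis_a_mm = sqrt(0.5),
    semi_axis_b_mm = sqrt(0.5), offset_x_mm = 0, offset_y_mm = 0)), 1, 1, 1)
}

# Random admissible material parameters for property tests.
fix_random_params <- function() {
  material_params(
    c1 = stats::runif(1, 5, 200), c3 = stats::runif(1, 0.1, 50),
    c4 = stats::runif(1, 2, 150), c5 = stats::runif(1, 100, 2000),
    lambda_star = stats::runif(1, 1.005, 1.08))
}

# Random deformation gradient near a stretch state (det > 0).
fix_random_state <- function(spread = 0.05) {
  repeat {
    F <- diag(3) + matrix(stats::rnorm(9, 0, spread), 3)
    if (det(F) > 0.3) break
  }
  a <- stats::rnorm(3); a <- a / sqrt(sum(a^2))
  deformation_state(F, a)
}
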