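test_that("analytic twist directions: trivial cases", {
  m <- fix_mesh()
  pts <- mesh_gauss_coords <- tendontwist:::mesh_gauss_coords(m)
  d0 <- analytic_twist_directions(m, 0)
  expect_equal(d0, matrix(rep(c(0, 0, 1), each = nrow(d0)), ncol = 3),
               tolerance = 1e-12)
  # mid-length point at radius r: helix tangent angle atan(r * psi')
  r <- 4
  p <- matrix(c(r, 0, 30), 1)
  d <- analytic_twist_directions(m, 60, "ccw", points = p)
  beta <- atan2(sqrt(sum(d[1:2]^2)), d[3])
  expect_equal(beta, atan(r * (60 * pi / 180) / 60), tolerance = 1e-9)
  # on-axis point stays axial for any angle
  d <- analytic_twist_directions(m, 45, points = matrix(c(0, 0, 20), 1))
  expect_equal(drop(d), c(0, 0, 1), tolerance = 1e-12)
  expect_error(analytic_twist_directions(m, -5), ">= 0")
  expect_warning(analytic_twist_directions(m, 75), "range")
})

test_that("cumulative material rotation is linear along the axis", {
  # rotating material points by t * total_angle means the fiber through a
  # point at axial fraction t has accumulated t * total_angle of azimuth:
  # integrate the helix tangent field from distal to mid-length
  m <- fix_mesh()
  total <- 60
  psi_rate <- total * pi / 180 / 60
  z <- seq(0, 30, length.out = 400)
  # azimuth of the fascicle through (r0, 0, 0): phi(z) = psi_rate * z
  r0 <- 3
  pts <- cbind(r0 * cos(psi_rate * z), r0 * sin(psi_rate * z), z)
  d <- analytic_twist_directions(m, total, "ccw", points = pts)
  # tangent direction must match the analytic helix tangent everywhere
  tan_exact <- cbind(-r0 * psi_rate * sin(psi_rate * z),
                     r0 * psi_rate * cos(psi_rate * z), rep(1, length(z)))
  tan_exact <- tan_exact / sqrt(rowSums(tan_exact^2))
  expect_lt(angular_rms_deg(d, tan_exact), 1e-6)
  # cumulative rotation at mid-length is half the total angle
  expect_equal(psi_rate * 30, total / 2 * pi / 180, tolerance = 1e-12)
})

test_that("euler field fit: identity and constant-rotation clouds", {
  m <- fix_mesh(n_axial = 3, n_circ = 3, n_radial = 3)
  cloud <- generate_fiber_cloud(m, 0)
  cloud$twisted_dirs <- cloud$straight_dirs
  f <- fit_euler_field(m, cloud)
  expect_lt(f$rms_residual, 1e-12)
  ff <- evaluate_fiber_at_gauss(m, f)
  expect_lt(angular_rms_deg(ff$gauss_fiber_dirs,
                            straight_fiber_field(m)$gauss_fiber_dirs), 1e-8)
})

test_that("round trip: cloud -> euler fit -> gauss evaluation reproduces the helix", {
  m <- fix_mesh(fix_bowed_profile(), n_axial = 6, n_circ = 4, n_radial = 4)
  for (ang in c(15, 30, 45, 60)) {
    ff_fit <- suppressWarnings(embed_twist_field(m, ang))
    ff_an <- suppressWarnings(analytic_twist_field(m, ang))
    expect_lt(angular_rms_deg(ff_fit$gauss_fiber_dirs,
                              ff_an$gauss_fiber_dirs), 2)
  }
})

test_that("handedness: mirroring the mesh flips cw and ccw fields", {
  m <- fix_mesh(n_axial = 3)
  pts <- tendontwist:::mesh_gauss_coords(m)
  d_ccw <- analytic_twist_directions(m, 30, "ccw", points = pts)
  # mirror x -> -x: the mirrored ccw field equals the cw field at the
  # mirrored points, with its x component flipped
  pts_m <- pts; pts_m[, 1] <- -pts_m[, 1]
  d_cw_m <- analytic_twist_directions(m, 30, "cw", points = pts_m)
  d_cw_m[, 1] <- -d_cw_m[, 1]
  expect_equal(d_ccw, d_cw_m, tolerance = 1e-12)
})

test_that("fiber fields are invariant under rigid mesh translation", {
  m <- fix_mesh(fix_bowed_profile(), n_axial = 3)
  ff1 <- suppressWarnings(embed_twist_field(m, 30))
  m2 <- m
  m2$nodes <- sweep(m2$nodes, 2, c(5, -3, 0), "+")
  off <- m2$profile$stations
  off$offset_x_mm <- off$offset_x_mm + 5
  off$offset_y_mm <- off$offset_y_mm - 3
  m2$profile <- cross_section_profile(off)
  ff2 <- suppressWarnings(embed_twist_field(m2, 30))
  expect_lt(angular_rms_deg(ff1$gauss_fiber_dirs, ff2$gauss_fiber_dirs),
            1e-4)
})

test_that("unit length invariant and euler CSV serialization", {
  m <- fix_mesh(n_axial = 3)
  ff <- suppressWarnings(embed_twist_field(m, 45))
  expect_true(all(abs(sqrt(rowSums(ff$gauss_fiber_dirs^2)) - 1) < 1e-10))
  f <- attr(ff, "euler_field")
  path <- withr::local_tempfile(fileext = ".csv")
  write_euler_field_csv(f, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), nrow(m$nodes))
  expect_equal(df$beta, f$nodal_euler_angles[, 2], tolerance = 1e-12)
})

test_that("zyz euler decomposition round-trips rotations", {
  set.seed(5)
  for (i in 1:50) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    a <- tendontwist:::euler_zyz_from_rotation(q)
    q2 <- tendontwist:::rotation_zyz(a[1], a[2], a[3])
    expect_equal(q2, q, tolerance = 1e-9)
  }
  # gimbal case: beta ~ 0 resolved with gamma = 0
  a <- tendontwist:::euler_zyz_from_rotation(
    tendontwist:::rotation_zyz(0.7, 0, 0))
  expect_equal(a[3], 0)
  expect_equal(a[1], 0.7, tolerance = 1e-9)
})
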