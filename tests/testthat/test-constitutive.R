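test_that("fiber stress law: toe region, exponential branch, continuity", {
  mp <- fix_params()
  expect_identical(fiber_stress(mp, 1.0), 0)
  expect_identical(fiber_stress(mp, 0.9), 0)
  # direct evaluation of the exponential branch: c3 (e^{c4 (lam-1)} - 1)
  expect_equal(fiber_stress(mp, 1.02), 11.57 * (exp(30.65 * 0.02) - 1),
               tolerance = 1e-12)
  expect_equal(fiber_stress(mp, 1.02), 9.7878, tolerance = 1e-4)
  # numerical differentiation of the fiber energy reproduces the stress law
  h <- 1e-7
  for (lam in c(1.01, 1.025, 1.05)) {
    dF2 <- (tendontwist:::fiber_energy(mp, lam + h) -
            tendontwist:::fiber_energy(mp, lam - h)) / (2 * h)
    expect_equal(lam * dF2, fiber_stress(mp, lam), tolerance = 1e-5)
  }
  expect_error(fiber_stress(mp, -1), "positive")
})

test_that("branch continuity at lambda = 1 and lambda* over random draws", {
  set.seed(42)
  for (i in 1:1000) {
    mp <- fix_random_params()
    eps <- 1e-12
    ls <- mp$lambda_star
    expect_lt(abs(fiber_stress(mp, 1 + eps)), 1e-8)
    lo <- mp$c3 * (exp(mp$c4 * (ls - 1)) - 1)
    hi <- mp$c5 * ls + mp$c6
    expect_equal(lo, hi, tolerance = 1e-12)
  }
})

test_that("fiber stress is non-decreasing in stretch for c5 >= 0", {
  set.seed(7)
  for (i in 1:50) {
    mp <- fix_random_params()
    lam <- seq(0.95, mp$lambda_star + 0.1, length.out = 400)
    expect_true(all(diff(fiber_stress(mp, lam)) >= -1e-12))
  }
})

test_that("c6 from the continuity condition", {
  expect_equal(c6_from_continuity(10, 30, 1000, 1.03),
               10 * (exp(0.9) - 1) - 1030, tolerance = 1e-12)
  expect_equal(c6_from_continuity(10, 30, 1000, 1.03), -1015.404,
               tolerance = 1e-5)
  expect_identical(c6_from_continuity(0, 30, 0, 1.5), 0)
  # with c5 = 0, c6 equals the exponential branch value at lambda*
  expect_equal(c6_from_continuity(3, 20, 0, 1.04), 3 * (exp(0.8) - 1))
  expect_error(c6_from_continuity(1, 1, 1, 1), "lambda_star")
  expect_error(material_params(c1 = 1, c3 = 10, c4 = 30, c5 = 1000,
                               lambda_star = 1.03, c6 = -900),
               "continuity")
})

test_that("strain energy: reference state, rotations, matrix-only shear", {
  mp <- fix_params()
  expect_equal(strain_energy(mp, deformation_state(diag(3))), 0)
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  expect_equal(strain_energy(mp, deformation_state(R, c(1, 0, 0))), 0,
               tolerance = 1e-12)
  # matrix-only simple shear: I1 = 3 + gamma^2, so W = c1/2 gamma^2
  mp0 <- material_params(c1 = 38.07, c3 = 0, c4 = 30, c5 = 0)
  for (g in c(0.05, 0.2)) {
    F <- diag(3); F[1, 3] <- g
    expect_equal(strain_energy(mp0, deformation_state(F, c(1, 0, 0))),
                 mp0$c1 / 2 * g^2, tolerance = 1e-12)
  }
  expect_error(deformation_state(-diag(3)), "det")
})

test_that("cauchy stress agrees with numerical differentiation of W", {
  set.seed(11)
  for (i in 1:20) {
    mp <- fix_random_params()
    st <- fix_random_state()
    sig <- cauchy_stress(mp, st)
    expect_equal(sig, t(sig), tolerance = 1e-9)
    h <- 1e-6
    P <- matrix(0, 3, 3)
    for (r in 1:3) for (cc in 1:3) {
      Fp <- st$F; Fp[r, cc] <- Fp[r, cc] + h
      Fm <- st$F; Fm[r, cc] <- Fm[r, cc] - h
      P[r, cc] <- (strain_energy(mp, deformation_state(Fp, st$fiber_dir)) -
                   strain_energy(mp, deformation_state(Fm, st$fiber_dir))) /
        (2 * h)
    }
    sig_num <- P %*% t(st$F) / det(st$F)
    expect_equal(sig, sig_num, tolerance = 1e-4)
  }
})

test_that("cauchy stress is frame-indifferent and zero at identity", {
  mp <- fix_params()
  expect_equal(cauchy_stress(mp, deformation_state(diag(3))),
               matrix(0, 3, 3), tolerance = 1e-12)
  set.seed(3)
  st <- fix_random_state()
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sig <- cauchy_stress(mp, st)
  sig_rot <- cauchy_stress(mp, deformation_state(q %*% st$F, st$fiber_dir))
  expect_equal(sig_rot, q %*% sig %*% t(q), tolerance = 1e-9)
  # rigid rotation alone produces no stress
  expect_equal(cauchy_stress(mp, deformation_state(q, c(0, 0, 1))),
               matrix(0, 3, 3), tolerance = 1e-9)
})

test_that("uniaxial closed form: reference, matrix-only value, c5 slope", {
  mp0 <- material_params(c1 = 38.07, c3 = 0, c4 = 30, c5 = 0)
  expect_equal(uniaxial_closed_form(mp0, 1), 0)
  expect_equal(uniaxial_closed_form(mp0, 1.05),
               38.07 * (1.05^2 - 1 / 1.05), tolerance = 1e-12)
  expect_equal(uniaxial_closed_form(mp0, 1.05), 5.715, tolerance = 1e-3)
  # slope beyond lambda*: c5 plus the matrix gradient c1 (2 lam + lam^-2)
  mp <- fix_params()
  h <- 1e-6; lam <- 1.08
  slope <- (uniaxial_closed_form(mp, lam + h) -
            uniaxial_closed_form(mp, lam - h)) / (2 * h)
  expect_equal(slope, mp$c5 + mp$c1 * (2 * lam + lam^-2), tolerance = 1e-5)
})

test_that("incompressible closed form matches the penalty model as kappa grows", {
  lam <- 1.05
  sig_exact <- uniaxial_closed_form(
    material_params(c1 = 38.07, c3 = 0, c4 = 30, c5 = 0), lam)
  err <- sapply(38.07 * c(1e2, 1e3, 1e4), function(k) {
    mp <- material_params(c1 = 38.07, c3 = 0, c4 = 30, c5 = 0, kappa = k)
    # equilibrium transverse stretch: solve sigma_xx = 0
    f <- function(lt) .tt_cauchy_point(diag(c(lt, lt, lam)), c(0, 0, 1),
                                       tendontwist:::params_vec(mp))[1, 1]
    lt <- uniroot(f, c(0.7, 1.1), tol = 1e-12)$root
    sig <- .tt_cauchy_point(diag(c(lt, lt, lam)), c(0, 0, 1),
                            tendontwist:::params_vec(mp))[3, 3]
    abs(sig - sig_exact) / sig_exact
  })
  expect_true(all(diff(err) < 0))   # converging in kappa
  expect_lt(err[2], 0.01)           # <1% at the default kappa = 1000 c1
})

test_that("von Mises stress: uniaxial, hydrostatic, pure shear", {
  s <- matrix(0, 3, 3); s[1, 1] <- 100
  expect_equal(von_mises(s), 100)
  expect_equal(von_mises(diag(c(7, 7, 7))), 0)
  s <- matrix(0, 3, 3); s[1, 2] <- s[2, 1] <- 5
  expect_equal(von_mises(s), sqrt(3) * 5)
  s[2, 1] <- 4.9
  expect_error(von_mises(s), "symmetric")
})

test_that("material parameter validation and config round trip", {
  expect_error(material_params(c1 = -1, c3 = 1, c4 = 1, c5 = 1), "c1")
  expect_error(material_params(c1 = 1, c3 = 1, c4 = 1, c5 = 1,
                               lambda_star = 0.99), "lambda_star")
  mp <- fix_params()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_material_params(mp, path)
  mp2 <- read_material_params(path)
  expect_equal(unclass(mp2), unclass(mp), tolerance = 1e-12)
})
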