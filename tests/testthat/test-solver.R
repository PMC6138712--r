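quick_ctl <- list(n_steps = 2)

test_that("zero external force gives zero displacement and stress", {
  m <- fix_mesh(n_axial = 2, n_circ = 2, n_radial = 2)
  res <- solve_static(m, straight_fiber_field(m), fix_params(),
                      boundary_conditions(fixed_nodes = m$distal_nodes))
  expect_true(res$converged)
  expect_equal(max(abs(res$nodal_displacements)), 0)
  expect_equal(max(res$gauss_von_mises), 0)
})

test_that("single element uniaxial force matches the closed form within 1%", {
  m <- fix_single_element()
  mp <- fix_params()
  lam <- 1.05
  sig <- uniaxial_closed_form(mp, lam)
  A0 <- mesh_section_csa(m, 0)
  bc <- boundary_conditions(
    fixed_nodes = m$distal_nodes,
    forces = tendontwist:::proximal_force_matrix(m, sig * A0 / lam))
  res <- solve_static(m, straight_fiber_field(m), mp, bc,
                      control = list(n_steps = 4))
  expect_true(res$converged)
  sig_fe <- mean(res$gauss_cauchy_stress[, 9])
  expect_lt(abs(sig_fe - sig) / sig, 0.01)
})

test_that("patch test: homogeneous stretch reproduces the constitutive stress", {
  m <- fix_single_element()
  mp <- fix_params()
  lam <- 1.04; lt <- 0.99
  pres <- rbind(
    data.frame(node = rep(seq_len(nrow(m$nodes)), each = 3),
               comp = rep(1:3, nrow(m$nodes)),
               value = NA))
  X <- m$nodes
  for (k in seq_len(nrow(pres))) {
    n <- pres$node[k]; cc <- pres$comp[k]
    tgt <- c((lt - 1) * X[n, 1], (lt - 1) * X[n, 2], (lam - 1) * X[n, 3])
    pres$value[k] <- tgt[cc]
  }
  res <- solve_static(m, straight_fiber_field(m), mp,
                      boundary_conditions(prescribed = pres),
                      control = quick_ctl)
  expect_true(res$converged)
  sig_exact <- .tt_cauchy_point(diag(c(lt, lt, lam)), c(0, 0, 1),
                                tendontwist:::params_vec(mp))
  for (q in 1:8)
    expect_equal(matrix(res$gauss_cauchy_stress[q, ], 3), sig_exact,
                 tolerance = 1e-6)
})

test_that("global equilibrium: reactions balance the applied load", {
  m <- fix_mesh(fix_bowed_profile(), n_axial = 3, n_circ = 3, n_radial = 3)
  mp <- fix_params()
  Ftot <- 800
  bc <- boundary_conditions(
    fixed_nodes = m$distal_nodes,
    forces = tendontwist:::proximal_force_matrix(m, Ftot))
  res <- solve_static(m, straight_fiber_field(m), mp, bc,
                      control = list(n_steps = 4))
  expect_true(res$converged)
  imb <- colSums(res$reactions) + c(0, 0, Ftot)
  expect_lt(max(abs(imb)) / Ftot, 1e-6)
})

test_that("tip displacement converges under mesh refinement", {
  mp <- fix_params()
  tip <- sapply(list(c(2, 2, 2), c(4, 3, 3), c(8, 4, 4)), function(rr) {
    m <- fix_mesh(fix_bowed_profile(), rr[1], rr[2], rr[3])
    bc <- boundary_conditions(
      fixed_nodes = m$distal_nodes,
      forces = tendontwist:::proximal_force_matrix(m, 1500))
    res <- solve_static(m, straight_fiber_field(m), mp, bc,
                        control = list(n_steps = 4))
    expect_true(res$converged)
    mean(res$nodal_displacements[m$proximal_nodes, 3])
  })
  expect_lt(abs(tip[3] - tip[2]), abs(tip[2] - tip[1]))
  expect_lt(abs(tip[3] - tip[2]) / abs(tip[3]), 0.02)
})

test_that("bonded two-body column equals the monolithic solution", {
  m <- label_subtendons(fix_mesh(n_axial = 3, n_circ = 4, n_radial = 4),
                        "two_way")
  mp <- fix_params()
  sp <- split_subtendon_mesh(m)
  con <- apply_interface(sp$interface, "bonded", nrow(sp$mesh$nodes))
  bc_mono <- tendontwist:::stretch_bc(m, 0.03)
  bc_split <- tendontwist:::stretch_bc(sp$mesh, 0.03)
  r_mono <- solve_static(m, straight_fiber_field(m), mp, bc_mono,
                         control = list(n_steps = 4))
  r_split <- solve_static(sp$mesh, straight_fiber_field(sp$mesh), mp,
                          bc_split, interfaces = con,
                          control = list(n_steps = 4))
  expect_true(r_mono$converged && r_split$converged)
  u_orig <- r_split$nodal_displacements[seq_len(nrow(m$nodes)), ]
  expect_equal(u_orig, r_mono$nodal_displacements, tolerance = 1e-5)
  vm_a <- tendontwist:::nodal_von_mises(m, r_mono)
  vm_b <- tendontwist:::nodal_von_mises(sp$mesh, r_split, sp$node_map,
                                        nrow(m$nodes))
  expect_gt(nodal_stress_r2(vm_a, vm_b), 0.999)
})

test_that("frictionless interface permits tangential slip but no opening", {
  m <- label_subtendons(fix_mesh(n_axial = 3, n_circ = 4, n_radial = 4),
                        "two_way")
  mp <- fix_params()
  sp <- split_subtendon_mesh(m)
  con <- apply_interface(sp$interface, "frictionless_sliding",
                         nrow(sp$mesh$nodes))
  # zero load: zero jumps in either mode
  res0 <- solve_static(sp$mesh, straight_fiber_field(sp$mesh), mp,
                       boundary_conditions(fixed_nodes = sp$mesh$distal_nodes),
                       interfaces = con)
  expect_equal(max(abs(res0$nodal_displacements)), 0)
  # differential axial load on one body only: tangential jump appears,
  # normal jump stays zero
  f <- matrix(0, nrow(sp$mesh$nodes), 3)
  sol_prox <- intersect(which(seq_len(nrow(sp$mesh$nodes)) <=
                                nrow(m$nodes)), sp$mesh$proximal_nodes)
  sol_only <- setdiff(sol_prox, sp$interface$pairs[, 1])
  f[sol_only, 3] <- 300 / length(sol_only)
  res <- solve_static(sp$mesh, straight_fiber_field(sp$mesh), mp,
                      boundary_conditions(fixed_nodes = sp$mesh$distal_nodes,
                                          forces = f),
                      interfaces = con, control = list(n_steps = 4))
  expect_true(res$converged)
  jump <- res$nodal_displacements[sp$interface$pairs[, 1], ] -
    res$nodal_displacements[sp$interface$pairs[, 2], ]
  njump <- rowSums(jump * sp$interface$normals)
  tjump <- jump - njump * sp$interface$normals
  expect_lt(max(abs(njump)), 1e-8)
  expect_gt(max(abs(tjump)), 1e-3)
})

test_that("marker tracking: identity, rigid translation, affine stretch", {
  m <- fix_mesh(n_axial = 3)
  mk <- default_markers(m)
  U0 <- matrix(0, nrow(m$nodes), 3)
  expect_equal(track_markers(m, U0, mk), mk)
  Ut <- matrix(rep(c(1, -2, 3), each = nrow(m$nodes)), ncol = 3)
  expect_equal(track_markers(m, Ut, mk),
               mk + matrix(rep(c(1, -2, 3), each = 6), ncol = 3),
               tolerance = 1e-9)
  lam <- 1.05
  Us <- cbind(0 * m$nodes[, 1], 0 * m$nodes[, 2], (lam - 1) * m$nodes[, 3])
  out <- track_markers(m, Us, mk)
  expect_equal(diff(out[, 3]), lam * diff(mk[, 3]), tolerance = 1e-9)
  far <- matrix(c(50, 50, 30), 1)
  expect_error(track_markers(m, U0, far), "outside")
})

test_that("transverse rotation: zero, imposed rigid rotation, pure stretch", {
  m <- fix_mesh(fix_bowed_profile(), n_axial = 3, n_circ = 4, n_radial = 4)
  res <- list(nodal_displacements = matrix(0, nrow(m$nodes), 3))
  class(res) <- "solve_result"
  expect_equal(transverse_rotation(m, res), 0)
  # rotate the proximal plane rigidly by 10 degrees about the section center
  th <- 10 * pi / 180
  npl <- (m$n_circ + 1) * (m$n_radial + 1)
  prox <- (m$n_axial * npl) + seq_len(npl)
  U <- matrix(0, nrow(m$nodes), 3)
  ctr <- colMeans(m$nodes[prox, 1:2])
  rel <- sweep(m$nodes[prox, 1:2], 2, ctr)
  U[prox, 1] <- rel[, 1] * cos(th) - rel[, 2] * sin(th) - rel[, 1]
  U[prox, 2] <- rel[, 1] * sin(th) + rel[, 2] * cos(th) - rel[, 2]
  res$nodal_displacements <- U
  expect_equal(transverse_rotation(m, res), 10, tolerance = 1e-6)
  # pure axial stretch: no rotation
  U2 <- cbind(0 * m$nodes[, 1], 0 * m$nodes[, 2], 0.05 * m$nodes[, 3])
  res$nodal_displacements <- U2
  expect_equal(transverse_rotation(m, res), 0, tolerance = 1e-9)
})

test_that("twisted tendon under load develops transverse rotation", {
  m <- fix_mesh(fix_bowed_profile(), n_axial = 4, n_circ = 4, n_radial = 4)
  mp <- fix_params()
  ff <- suppressWarnings(analytic_twist_field(m, 30))
  bc <- boundary_conditions(
    fixed_nodes = m$distal_nodes,
    forces = tendontwist:::proximal_force_matrix(m, 2000))
  res <- solve_static(m, ff, mp, bc, control = list(n_steps = 4))
  expect_true(res$converged)
  expect_gt(abs(transverse_rotation(m, res)), 0.5)
})

test_that("non-convergence is reported honestly", {
  m <- fix_single_element()
  mp <- fix_params()
  # starve the solver of iterations: an honest solver reports failure
  # instead of accepting the unconverged state
  bc <- boundary_conditions(
    fixed_nodes = m$distal_nodes,
    forces = tendontwist:::proximal_force_matrix(m, 60))
  res <- suppressWarnings(
    solve_static(m, straight_fiber_field(m), mp, bc,
                 control = list(n_steps = 1, max_iter = 1,
                                max_bisect = 2)))
  expect_false(res$converged)
  expect_true(!is.null(res$diagnostics))
  expect_lt(res$load_factor, 1)
})
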