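test_that("profile validation and CSV round trip", {
  expect_error(cross_section_profile(data.frame(station_mm = 1)), "columns")
  df <- data.frame(station_mm = c(0, 10), semi_axis_a_mm = c(3, 3),
                   semi_axis_b_mm = c(2, 2), offset_x_mm = 0, offset_y_mm = 0)
  p <- cross_section_profile(df)
  expect_equal(profile_csa(p, 5), pi * 6)
  expect_error(cross_section_profile(df[2:1, ]), "increasing")
  bad <- df; bad$semi_axis_a_mm <- c(3, -1)
  expect_error(cross_section_profile(bad), "positive")
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(p, path)
  expect_equal(read_profile_csv(path)$stations, p$stations)
})

test_that("lofted mesh matches analytic section areas and volume", {
  m <- fix_mesh(fix_circular_profile(), n_axial = 4, n_circ = 6,
                n_radial = 6)
  for (z in c(0, 30, 60))
    expect_lt(abs(mesh_section_csa(m, z) - pi * 25) / (pi * 25), 0.02)
  expect_lt(abs(sum(m$elem_volume) - pi * 25 * 60) / (pi * 25 * 60), 0.02)
  expect_equal(diff(range(m$z_planes)), 60)
  # prism from translated identical stations: volume = CSA * length
  m1 <- fix_mesh(cross_section_profile(data.frame(
    station_mm = c(10, 50), semi_axis_a_mm = 4, semi_axis_b_mm = 2,
    offset_x_mm = 3, offset_y_mm = 1)), 2, 6, 6)
  expect_lt(abs(sum(m1$elem_volume) - pi * 8 * 40) / (pi * 8 * 40), 0.02)
})

test_that("smallest valid mesh has positive Jacobians", {
  m <- fix_single_element()
  expect_equal(nrow(m$conn), 1L)
  q <- .tt_mesh_quality(m$nodes, m$conn)
  expect_gt(min(q$min_jac), 0)
  expect_error(build_tendon_mesh(fix_circular_profile(), 0, 1, 1), ">= 1")
})

test_that("mesh volume converges to the lofted-ellipse volume under refinement", {
  prof <- fix_bowed_profile()
  exact <- stats::integrate(function(z) profile_csa(prof, z), 0, 60,
                            subdivisions = 400)$value
  errs <- sapply(c(4, 8, 16), function(n) {
    m <- build_tendon_mesh(prof, 6, n, n)
    abs(sum(m$elem_volume) - exact) / exact
  })
  expect_true(all(diff(errs) < 0))
  # observed order >= 1 (errors shrink at least ~2x per refinement)
  expect_gt(errs[1] / errs[2], 2)
})

test_that("compartment labels split the section about the centroid line", {
  m <- label_compartments(fix_mesh(n_circ = 6, n_radial = 4))
  expect_equal(sum(m$compartment == "medial"), nrow(m$conn) / 2)
  # mirrored mesh swaps the label multiset
  m2 <- fix_mesh(n_circ = 6, n_radial = 4)
  m2$nodes[, 1] <- -m2$nodes[, 1]
  m2$conn <- m2$conn[, c(2, 1, 4, 3, 6, 5, 8, 7)]  # restore orientation
  m2 <- label_compartments(m2)
  expect_equal(sum(m2$compartment == "medial"),
               sum(m$compartment == "lateral"))
})

test_that("sub-tendon sectors realize the requested area fractions", {
  m <- fix_mesh(n_axial = 2, n_circ = 10, n_radial = 10)
  m3 <- label_subtendons(m, "three_way")
  areas <- tapply(m3$elem_volume, m3$subtendon, sum) / sum(m3$elem_volume)
  expect_equal(unname(areas["SOL"]), 2 / 3, tolerance = 0.03)
  expect_equal(unname(areas["MG"]), 2 / 9, tolerance = 0.1)
  expect_equal(unname(areas["LG"]), 1 / 9, tolerance = 0.1)
  m2 <- label_subtendons(m, "two_way")
  a2 <- tapply(m2$elem_volume, m2$subtendon, sum) / sum(m2$elem_volume)
  expect_equal(unname(a2["SOL"]), 2 / 3, tolerance = 0.03)
  # partition axially constant: same in-plane labels in every layer
  lab <- matrix(as.character(m3$subtendon), ncol = 2)
  expect_identical(lab[, 1], lab[, 2])
  # custom anatomical fractions
  mf <- label_subtendons(m, "three_way",
                         fractions = c(SOL = 0.52, MG = 0.35, LG = 0.13))
  af <- tapply(mf$elem_volume, mf$subtendon, sum) / sum(mf$elem_volume)
  expect_equal(unname(af["SOL"]), 0.52, tolerance = 0.05)
  # too coarse to resolve a 1/9 sector
  expect_error(label_subtendons(fix_mesh(n_circ = 1, n_radial = 1),
                                "three_way"), "resolution")
})

test_that("labels are invariant under node renumbering", {
  m <- fix_mesh(n_axial = 2, n_circ = 6, n_radial = 6)
  m3 <- label_subtendons(label_compartments(m), "three_way")
  perm <- sample(nrow(m$nodes))
  m2 <- m
  m2$nodes[perm, ] <- m$nodes
  m2$conn <- matrix(perm[m$conn], ncol = 8)
  m2$distal_nodes <- perm[m$distal_nodes]
  m2$proximal_nodes <- perm[m$proximal_nodes]
  m2 <- label_subtendons(label_compartments(m2), "three_way")
  expect_identical(m2$subtendon, m3$subtendon)
  expect_identical(m2$compartment, m3$compartment)
})

test_that("free-form CSA scaling hits the mid-section and fixes the ends", {
  m <- fix_mesh(fix_circular_profile(), n_axial = 6, n_circ = 6,
                n_radial = 6)
  expect_identical(ffd_scale_csa(m, 1)$nodes, m$nodes)
  m2 <- ffd_scale_csa(m, 1.1)
  expect_equal(mesh_section_csa(m2, 30) / mesh_section_csa(m, 30), 1.1,
               tolerance = 1e-10)
  expect_equal(mesh_section_csa(m2, 0), mesh_section_csa(m, 0))
  expect_equal(mesh_section_csa(m2, 60), mesh_section_csa(m, 60))
  # composing with the reciprocal scale restores the CSA
  m3 <- ffd_scale_csa(m2, 1 / 1.1)
  expect_equal(mesh_section_csa(m3, 30), mesh_section_csa(m, 30),
               tolerance = 1e-10)
  expect_error(ffd_scale_csa(m, 0), "> 0")
  expect_error(ffd_scale_csa(fix_mesh(n_axial = 2), 1e-4), "invert")
})

test_that("VTK write/read round trip preserves mesh and labels", {
  m <- label_subtendons(label_compartments(fix_mesh(n_axial = 2)),
                        "three_way")
  path <- withr::local_tempfile(fileext = ".vtk")
  write_vtk_mesh(m, path, point_data = list(u = matrix(1, nrow(m$nodes), 3)),
                 cell_data = list(vm = seq_len(nrow(m$conn)) * 1.5))
  rd <- read_vtk_mesh(path)
  expect_equal(rd$nodes, m$nodes, tolerance = 1e-9)
  expect_identical(rd$conn, m$conn)
  expect_equal(rd$compartment, as.integer(m$compartment))
  expect_equal(rd$vm, seq_len(nrow(m$conn)) * 1.5)
})
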