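test_that("load split defaults and validation", {
  sp <- load_split()
  expect_equal(unname(sp), c(2 / 3, 2 / 9, 1 / 9))
  expect_equal(sum(sp), 1)
  expect_error(load_split(0.5, 0.3, 0.1), "sum to 1")
  # 900 N split: exactly 600/200/100 through the nodal force pattern
  m <- label_subtendons(fix_mesh(n_axial = 2, n_circ = 4, n_radial = 4),
                        "three_way")
  f <- tendontwist:::proximal_force_matrix(m, 900, split = as.list(sp))
  expect_equal(sum(f[, 3]), 900, tolerance = 1e-9)
  # per sub-tendon totals are exactly 600/200/100 N: the full pattern is the
  # sum of the three single-group patterns
  totals <- c(SOL = 600, MG = 200, LG = 100)
  acc <- matrix(0, nrow(m$nodes), 3)
  for (g in names(totals)) {
    fg <- tendontwist:::proximal_force_matrix(
      m, totals[[g]], split = stats::setNames(list(1), g))
    expect_equal(sum(fg[, 3]), totals[[g]], tolerance = 1e-9)
    acc <- acc + fg
  }
  expect_equal(acc, f, tolerance = 1e-9)
})

test_that("rupture criterion boundary: 14 consecutive points do not trigger, 15 do", {
  m <- fix_mesh(fix_circular_profile(), n_axial = 8, n_circ = 2,
                n_radial = 2)
  vm <- numeric(nrow(m$conn) * 8)
  cols <- tendontwist:::gauss_axial_columns(m)
  expect_equal(length(cols[[1]]), 16)   # 8 layers x 2 axial gp
  col <- cols[[3]]
  vm[col[2:15]] <- 150                  # 14 consecutive points
  expect_equal(tendontwist:::max_overthreshold_run(m, vm, 100), 14)
  expect_lt(tendontwist:::max_overthreshold_run(m, vm, 100), 15)
  vm[col[16]] <- 150                    # no: 2..15 plus 16 = 15 consecutive
  expect_equal(tendontwist:::max_overthreshold_run(m, vm, 100), 15)
  # a gap resets the run
  vm[col[10]] <- 0
  expect_lt(tendontwist:::max_overthreshold_run(m, vm, 100), 15)
  # points in different columns never chain
  vm2 <- numeric(nrow(m$conn) * 8)
  vm2[cols[[1]][1:8]] <- 150
  vm2[cols[[2]][9:16]] <- 150
  expect_equal(tendontwist:::max_overthreshold_run(m, vm2, 100), 8)
})

test_that("infinite threshold never ruptures and reports the cap honestly", {
  s <- draw_subject(population_model(), 13)
  mod <- subject_model(s, twist_deg = 0, n_axial = 8, n_circ = 3,
                       n_radial = 3)
  rr <- run_rupture(mod$mesh, mod$fiber_field, s$params, threshold = Inf,
                    increment = 500, max_load = 1500)
  expect_true(is.na(rr$rupture_load))
  expect_equal(rr$status, "no_rupture")
  expect_equal(nrow(rr$load_history), 3)
})

test_that("rupture staircase finds the threshold-crossing load", {
  s <- draw_subject(population_model(), 13)
  mod <- subject_model(s, twist_deg = 0, n_axial = 8, n_circ = 3,
                       n_radial = 3)
  rr <- run_rupture(mod$mesh, mod$fiber_field, s$params, increment = 500,
                    threshold = 40, run_length = 15, max_load = 8000)
  expect_false(is.na(rr$rupture_load))
  expect_equal(rr$status, "ruptured")
  h <- rr$load_history
  # criterion satisfied at rupture and not at the previous increment
  expect_gte(h$max_run[nrow(h)], 15)
  expect_true(all(h$max_run[-nrow(h)] < 15))
  expect_equal(rr$rupture_load %% 500, 0)
  expect_equal(rr$run_length_mm, 15 * 60 / 16)
})

test_that("coarsening the load increment never lowers the rupture load", {
  s <- draw_subject(population_model(), 13)
  mod <- subject_model(s, twist_deg = 0, n_axial = 8, n_circ = 3,
                       n_radial = 3)
  fine <- run_rupture(mod$mesh, mod$fiber_field, s$params, increment = 400,
                      threshold = 40, max_load = 8000)
  coarse <- run_rupture(mod$mesh, mod$fiber_field, s$params,
                        increment = 800, threshold = 40, max_load = 8000)
  expect_gte(coarse$rupture_load, fine$rupture_load)
})

test_that("compartment stress summary: uniform field and mirrored solution", {
  m <- label_compartments(fix_mesh(fix_bowed_profile(), 2, 4, 4))
  fake <- structure(list(
    gauss_von_mises = rep(50, nrow(m$conn) * 8),
    gauss_weight = rep(1, nrow(m$conn) * 8)), class = "solve_result")
  cs <- compartment_stress_summary(m, fake)
  expect_equal(cs$percent_difference, 0)
  expect_equal(cs$medial_mean, 50)
  # stress only in medial elements: lateral mean zero is flagged
  vm <- numeric(nrow(m$conn) * 8)
  vm[rep(m$compartment == "medial", each = 8)] <- 10
  fake$gauss_von_mises <- vm
  expect_warning(cs2 <- compartment_stress_summary(m, fake), "infinite")
  expect_equal(cs2$lateral_mean, 0)
  # swapping labels swaps the means
  m2 <- m
  m2$compartment <- factor(
    ifelse(m$compartment == "medial", "lateral", "medial"),
    levels = c("medial", "lateral"))
  cs3 <- suppressWarnings(compartment_stress_summary(m2, fake))
  expect_equal(cs3$medial_mean, cs2$lateral_mean)
  expect_equal(cs3$lateral_mean, cs2$medial_mean)
})

test_that("nodal stress r^2: identity, affine invariance, null pair", {
  set.seed(9)
  a <- rnorm(1000)
  expect_equal(nodal_stress_r2(a, a), 1)
  expect_equal(nodal_stress_r2(a, 2 * a + 3), 1)
  b <- rnorm(1000)
  b_orth <- b - a * sum(a * b) / sum(a * a)   # exactly decorrelated
  expect_lt(nodal_stress_r2(a, b_orth), 1e-6)
  expect_error(nodal_stress_r2(a, rep(1, 1000)), "variance")
  expect_error(nodal_stress_r2(a, b[1:10]), "match")
})

test_that("split mesh: coincident pairing, labels and constraints", {
  m <- label_subtendons(fix_mesh(n_axial = 2, n_circ = 4, n_radial = 4),
                        "two_way")
  sp <- split_subtendon_mesh(m)
  expect_gt(nrow(sp$interface$pairs), 0)
  expect_equal(sp$mesh$nodes[sp$interface$pairs[, 1], ],
               sp$mesh$nodes[sp$interface$pairs[, 2], ])
  expect_true(all(abs(sqrt(rowSums(sp$interface$normals^2)) - 1) < 1e-9))
  con_b <- apply_interface(sp$interface, "bonded", nrow(sp$mesh$nodes))
  expect_equal(nrow(con_b$G), 3 * nrow(sp$interface$pairs))
  con_s <- apply_interface(sp$interface, "frictionless_sliding",
                           nrow(sp$mesh$nodes))
  expect_equal(nrow(con_s$G), nrow(sp$interface$pairs))
  expect_error(label_subtendons(m, "three_way") |> split_subtendon_mesh(),
               "two_way")
})
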