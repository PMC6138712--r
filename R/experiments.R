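#' Differential triceps-surae load split
#'
#' Fractions of the total proximal force carried by each sub-tendon,
#' defaulting to the 6:2:1 soleus : medial gastrocnemius : lateral
#' gastrocnemius ratio of the muscles' physiological cross-sectional areas.
#'
#' @param soleus,mg,lg Force fractions; must sum to 1.
#' @return Named vector `c(SOL=, MG=, LG=)`.
#' @export
load_split <- function(soleus = 2 / 3, mg = 2 / 9, lg = 1 / 9) {
  if (abs(soleus + mg + lg - 1) > 1e-12) stop("fractions must sum to 1")
  if (any(c(soleus, mg, lg) < 0)) stop("fractions must be non-negative")
  c(SOL = soleus, MG = mg, LG = lg)
}

# Axial Gauss-point columns: lists of Gauss-point indices (into the
# nelem*8 Gauss vector) sharing one in-plane position, ordered distal to
# proximal. Column identity = (in-plane element cell, in-plane gp index);
# axial order = (axial element layer, axial gp index).
gauss_axial_columns <- function(mesh) {
  ne <- nrow(mesh$conn)
  gi <- seq_len(ne * 8)
  e <- (gi - 1) %/% 8 + 1
  q <- (gi - 1) %% 8            # 0..7, xi fastest, zeta slowest
  g1 <- q %% 2; g2 <- (q %/% 2) %% 2; g3 <- q %/% 4
  ia <- mesh$elem_grid[e, 1]; iu <- mesh$elem_grid[e, 2]
  iv <- mesh$elem_grid[e, 3]
  col_id <- paste(iu, iv, g1, g2, sep = ".")
  ord <- order(col_id, 2 * (ia - 1) + g3)
  split(gi[ord], col_id[ord])
}

# Longest run of consecutive over-threshold Gauss points along any axial
# column of the given von Mises field.
max_overthreshold_run <- function(mesh, vm, threshold,
                                  columns = gauss_axial_columns(mesh)) {
  best <- 0L
  for (col in columns) {
    r <- rle(vm[col] > threshold)
    runs <- r$lengths[r$values]
    if (length(runs)) best <- max(best, max(runs))
  }
  best
}

#' Compartmental stress summary
#'
#' Volume-weighted mean von Mises stress over the medial and lateral
#' compartments' Gauss points, and their percent difference
#' `(medial - lateral) / lateral * 100`.
#'
#' @param mesh A compartment-labeled `tendon_mesh`.
#' @param result A converged `solve_result`.
#' @return List with `medial_mean`, `lateral_mean`, `percent_difference`
#'   (MPa, MPa, %). A zero lateral mean gives an infinite percent
#'   difference with a warning.
#' @export
compartment_stress_summary <- function(mesh, result) {
  if (is.null(mesh$compartment)) stop("mesh has no compartment labels")
  if (is.null(result$gauss_von_mises)) stop("result carries no stress field")
  lab <- rep(as.character(mesh$compartment), each = 8)
  w <- result$gauss_weight
  vm <- result$gauss_von_mises
  mean_of <- function(side) {
    sel <- lab == side
    if (!any(sel)) stop("empty compartment: ", side)
    sum(vm[sel] * w[sel]) / sum(w[sel])
  }
  med <- mean_of("medial"); lat <- mean_of("lateral")
  if (lat == 0) {
    warning("lateral compartment carries zero stress; ",
            "percent difference is infinite")
    pd <- Inf
  } else pd <- (med - lat) / lat * 100
  list(medial_mean = med, lateral_mean = lat, percent_difference = pd)
}

#' In-silico rupture experiment under differential loading
#'
#' Applies the total proximal force in a monotone staircase of fixed
#' increments, split across the sub-tendon node sets (6:2:1 by default),
#' with the distal face clamped. After each converged step the longest run
#' of consecutive over-threshold von Mises Gauss points along any axial
#' Gauss column is evaluated; the tendon is regarded as ruptured at the
#' first load whose run reaches `run_length` points. The physical length
#' spanned by `run_length` points on the actual mesh is recorded.
#'
#' @param mesh A labeled `tendon_mesh` (sub-tendons; compartments optional
#'   but used for the per-step stress summary if present).
#' @param fiber_field A `fiber_field`.
#' @param params [material_params()].
#' @param split Load split from [load_split()].
#' @param increment Force step, N (default 100).
#' @param threshold Rupture stress, MPa (default 100).
#' @param run_length Consecutive over-threshold Gauss points required
#'   (default 15).
#' @param max_load Load cap, N (default 10000); reaching it without
#'   rupture returns an explicit no-rupture result.
#' @param vtk_dir Optional directory: writes the displacement and von Mises
#'   fields of every converged load step as a legacy-VTK time series
#'   (`step_<load>N.vtk`).
#' @param control Solver control overrides.
#' @return A `rupture_result`: `rupture_load` (N, `NA` if no rupture),
#'   per-step history (load, max run, compartment means), criterion
#'   settings, and the run length expressed in mm.
#' @export
run_rupture <- function(mesh, fiber_field, params, split = load_split(),
                        increment = 100, threshold = 100, run_length = 15,
                        max_load = 10000, vtk_dir = NULL,
                        control = list()) {
  if (!is.null(vtk_dir))
    dir.create(vtk_dir, showWarnings = FALSE, recursive = TRUE)
  if (increment <= 0) stop("increment must be > 0")
  if (max_load < increment) stop("max_load must be at least one increment")
  if (is.null(mesh$subtendon)) stop("mesh has no sub-tendon labels")
  funit <- proximal_force_matrix(mesh, 1, split = as.list(split))
  columns <- gauss_axial_columns(mesh)
  has_comp <- !is.null(mesh$compartment)
  L <- diff(range(mesh$z_planes))
  hist <- list()
  u <- NULL
  loads <- seq(increment, max_load, by = increment)
  rupture_load <- NA_real_
  status <- "no_rupture"
  for (k in seq_along(loads)) {
    bc <- boundary_conditions(fixed_nodes = mesh$distal_nodes,
                              forces = funit * loads[k])
    ctl <- utils::modifyList(
      list(n_steps = if (k == 1) 2 else 1, u0 = u,
           ramp_from = if (k == 1) 0 else loads[k - 1] / loads[k]),
      control)
    res <- solve_static(mesh, fiber_field, params, bc, control = ctl)
    if (!res$converged) {
      status <- paste0("solver_failure_at_", loads[k], "N")
      warning("solver failed at ", loads[k], " N (last converged ",
              if (k > 1) loads[k - 1] else 0, " N): ", res$diagnostics)
      break
    }
    u <- res$nodal_displacements
    if (!is.null(vtk_dir))
      write_vtk_result(mesh, res,
                       file.path(vtk_dir, sprintf("step_%06dN.vtk",
                                                  as.integer(loads[k]))))
    run <- max_overthreshold_run(mesh, res$gauss_von_mises, threshold,
                                 columns)
    cs <- if (has_comp) compartment_stress_summary(mesh, res)
          else list(medial_mean = NA, lateral_mean = NA,
                    percent_difference = NA)
    hist[[k]] <- data.frame(load_N = loads[k], max_run = run,
                            max_vm = max(res$gauss_von_mises),
                            medial_mean = cs$medial_mean,
                            lateral_mean = cs$lateral_mean,
                            percent_difference = cs$percent_difference)
    if (run >= run_length) {
      rupture_load <- loads[k]
      status <- "ruptured"
      break
    }
  }
  structure(list(
    rupture_load = rupture_load, status = status,
    load_history = do.call(rbind, hist),
    threshold = threshold, run_length = run_length,
    run_length_mm = run_length * L / (2 * mesh$n_axial),
    increment = increment, split = split), class = "rupture_result")
}

#' @export
print.rupture_result <- function(x, ...) {
  if (is.na(x$rupture_load))
    cat(sprintf("rupture_result: NO rupture up to %.0f N (%s)\n",
                max(x$load_history$load_N), x$status))
  else
    cat(sprintf(
      "rupture_result: ruptured at %.0f N (>%g MPa over %d Gauss points ~ %.1f mm)\n",
      x$rupture_load, x$threshold, x$run_length, x$run_length_mm))
  invisible(x)
}

#' Squared Pearson correlation between two nodal scalar fields
#'
#' @param field_a,field_b Numeric vectors over matching node sets.
#' @return r^2 in [0, 1].
#' @export
nodal_stress_r2 <- function(field_a, field_b) {
  if (length(field_a) != length(field_b)) stop("node sets do not match")
  if (stats::sd(field_a) == 0 || stats::sd(field_b) == 0)
    stop("zero-variance stress field")
  stats::cor(field_a, field_b)^2
}

# Volume-weighted nodal von Mises stress: Gauss values of each element
# averaged to its nodes, then averaged over adjacent elements. An optional
# node map collapses duplicated interface nodes back to their originals.
nodal_von_mises <- function(mesh, result, node_map = NULL,
                            n_nodes_out = NULL) {
  ne <- nrow(mesh$conn)
  evm <- numeric(ne)
  for (e in seq_len(ne)) {
    idx <- 8 * (e - 1) + 1:8
    evm[e] <- sum(result$gauss_von_mises[idx] * result$gauss_weight[idx]) /
      sum(result$gauss_weight[idx])
  }
  ids <- as.vector(mesh$conn)
  if (!is.null(node_map)) ids <- node_map[ids]
  if (is.null(n_nodes_out)) n_nodes_out <- max(ids)
  num <- tapply(rep(evm, 8), ids, sum)
  cnt <- tapply(rep(1, length(ids)), ids, sum)
  out <- numeric(n_nodes_out)
  out[as.integer(names(num))] <- num / cnt
  out
}

#' Split a two-way labeled mesh into sliding sub-tendon bodies
#'
#' Duplicates the nodes on the surface shared by the SOL and GAS element
#' groups, reassigns the GAS-side connectivity to the duplicates, and
#' returns the node pairing with area-averaged reference interface normals
#' -- the geometry needed for bonded or frictionless-sliding interface
#' constraints.
#'
#' @param mesh A `tendon_mesh` labeled with [label_subtendons()]
#'   (`two_way`).
#' @return List: `mesh` (the split mesh; structured-section helpers no
#'   longer apply to it), `interface` (a `sliding_interface` with `pairs`,
#'   `normals`, `ref_coords`), and `node_map` (split node id -> original
#'   node id).
#' @export
split_subtendon_mesh <- function(mesh) {
  if (is.null(mesh$subtendon) || !all(levels(mesh$subtendon) ==
                                      c("SOL", "GAS")))
    stop("mesh must carry a two_way sub-tendon labeling")
  faces_loc <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8), c(1, 2, 6, 5),
                     c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
  sol_e <- which(mesh$subtendon == "SOL")
  gas_e <- which(mesh$subtendon == "GAS")
  face_key <- function(els) {
    keys <- character(0); owner <- integer(0); loc <- integer(0)
    for (e in els) for (fc in 1:6) {
      ids <- sort(mesh$conn[e, faces_loc[fc, ]])
      keys <- c(keys, paste(ids, collapse = "."))
      owner <- c(owner, e); loc <- c(loc, fc)
    }
    data.frame(key = keys, elem = owner, face = loc,
               stringsAsFactors = FALSE)
  }
  fs <- face_key(sol_e); fg <- face_key(gas_e)
  shared <- intersect(fs$key, fg$key)
  if (!length(shared)) stop("sub-tendon groups share no interface faces")
  # interface nodes and per-node average normal (from the SOL-side faces)
  nrm_acc <- matrix(0, nrow(mesh$nodes), 3)
  itf_nodes <- integer(0)
  for (k in which(fs$key %in% shared)) {
    e <- fs$elem[k]
    ids <- mesh$conn[e, faces_loc[fs$face[k], ]]
    p <- mesh$nodes[ids, ]
    nrm <- pracma::cross(p[3, ] - p[1, ], p[4, ] - p[2, ]) / 2
    for (n in ids) nrm_acc[n, ] <- nrm_acc[n, ] + nrm
    itf_nodes <- union(itf_nodes, ids)
  }
  itf_nodes <- sort(itf_nodes)
  normals <- nrm_acc[itf_nodes, , drop = FALSE]
  normals <- normals / sqrt(rowSums(normals^2))
  nn0 <- nrow(mesh$nodes)
  dup_ids <- nn0 + seq_along(itf_nodes)
  remap <- seq_len(nn0)
  remap[itf_nodes] <- dup_ids
  split_mesh <- mesh
  split_mesh$nodes <- rbind(mesh$nodes, mesh$nodes[itf_nodes, , drop = FALSE])
  for (e in gas_e) split_mesh$conn[e, ] <- remap[mesh$conn[e, ]]
  add <- function(set) unique(c(set, remap[intersect(set, itf_nodes)]))
  split_mesh$distal_nodes <- add(mesh$distal_nodes)
  split_mesh$proximal_nodes <- add(mesh$proximal_nodes)
  split_mesh$is_split <- TRUE
  node_map <- c(seq_len(nn0), itf_nodes)
  interface <- structure(list(
    pairs = cbind(itf_nodes, dup_ids), normals = normals,
    ref_coords = list(a = mesh$nodes[itf_nodes, , drop = FALSE],
                      b = mesh$nodes[itf_nodes, , drop = FALSE])),
    class = "sliding_interface")
  list(mesh = split_mesh, interface = interface, node_map = node_map)
}

# Displacement-controlled uniaxial stretch solve: distal face clamped,
# proximal face displaced axially by strain * length (in-plane clamped).
stretch_bc <- function(mesh, strain) {
  L <- diff(range(mesh$z_planes))
  pn <- mesh$proximal_nodes
  boundary_conditions(
    fixed_nodes = mesh$distal_nodes,
    prescribed = data.frame(
      node = rep(pn, each = 3), comp = rep(1:3, length(pn)),
      value = rep(c(0, 0, strain * L), length(pn))))
}

#' Four-case sub-tendon sliding study
#'
#' Solves the two-body sub-tendon model (SOL + gastrocnemius) under
#' displacement-controlled uniaxial stretch for the four cases
#' straight/twisted x bonded/frictionless-sliding, measuring the failure
#' strain of each case with the same over-threshold run-length criterion as
#' the rupture experiment. At a common comparison stretch the nodal von
#' Mises field of each sub-tendon case is also compared (squared Pearson
#' correlation) against the monolithic mesh with the same twist embedded as
#' a fitted fiber field.
#'
#' @param mesh A two-way labeled `tendon_mesh` (monolithic).
#' @param params [material_params()].
#' @param twist_deg Twist angle of the twisted cases (default 30).
#' @param strain_increment Stretch staircase step (default 0.005).
#' @param max_strain Stretch cap (default 0.2).
#' @param threshold,run_length Failure criterion (defaults 100 MPa, 15
#'   points).
#' @param compare_strain Stretch at which stress patterns are compared
#'   (default 0.10).
#' @param control Solver control overrides.
#' @return A `sliding_comparison`: failure strain per case, r^2 of each
#'   case against the matching embedded-twist monolithic solve, the
#'   relative failure-strain gain of sliding over bonded, and the nodal
#'   stress fields at the comparison stretch.
#' @export
run_sliding_study <- function(mesh, params, twist_deg = 30,
                              strain_increment = 0.005, max_strain = 0.2,
                              threshold = 100, run_length = 15,
                              compare_strain = 0.10, control = list()) {
  sp <- split_subtendon_mesh(mesh)
  smesh <- sp$mesh
  cases <- expand.grid(twist = c("straight", "twisted"),
                       interface = c("bonded", "sliding"),
                       stringsAsFactors = FALSE)
  fields <- list(
    straight = straight_fiber_field(smesh),
    twisted = suppressWarnings(embed_twist_field(smesh, twist_deg)))
  nn <- nrow(smesh$nodes)
  columns <- gauss_axial_columns(smesh)
  failure <- numeric(nrow(cases)); names(failure) <- paste(
    cases$twist, cases$interface, sep = "_")
  strains <- seq(strain_increment, max_strain, by = strain_increment)
  # nodal stress fields captured at every converged strain step, so the
  # pattern comparison can use the largest strain all cases reached
  fields_by_step <- list()
  for (ci in seq_len(nrow(cases))) {
    con <- apply_interface(sp$interface,
                           if (cases$interface[ci] == "bonded") "bonded"
                           else "frictionless_sliding", nn)
    ff <- fields[[cases$twist[ci]]]
    u <- NULL
    fail <- NA_real_
    steps <- list()
    for (si in seq_along(strains)) {
      s <- strains[si]
      ctl <- utils::modifyList(
        list(n_steps = if (is.null(u)) 2 else 1, u0 = u,
             ramp_from = if (si == 1) 0 else strains[si - 1] / s), control)
      res <- solve_static(smesh, ff, params, stretch_bc(smesh, s),
                          interfaces = con, control = ctl)
      if (!res$converged) {
        warning(names(failure)[ci], ": solver failed at strain ", s)
        break
      }
      u <- res$nodal_displacements
      steps[[si]] <- nodal_von_mises(smesh, res, sp$node_map,
                                     nrow(mesh$nodes))
      if (max_overthreshold_run(smesh, res$gauss_von_mises, threshold,
                                columns) >= run_length) {
        fail <- s
        break
      }
    }
    failure[ci] <- fail
    fields_by_step[[names(failure)[ci]]] <- steps
  }
  cmp_idx <- min(c(which.min(abs(strains - compare_strain)),
                   vapply(fields_by_step, length, 0L)))
  if (cmp_idx < 1) stop("no common converged strain step to compare at")
  compare_strain_used <- strains[cmp_idx]
  nodal <- lapply(fields_by_step, `[[`, cmp_idx)
  # monolithic references at the common comparison stretch
  mono <- list()
  for (tw in c("straight", "twisted")) {
    ffm <- if (tw == "straight") straight_fiber_field(mesh)
           else suppressWarnings(embed_twist_field(mesh, twist_deg))
    res <- solve_static(mesh, ffm, params,
                        stretch_bc(mesh, compare_strain_used),
                        control = utils::modifyList(list(n_steps = 8),
                                                    control))
    if (!res$converged) stop("monolithic reference solve failed (", tw, ")")
    mono[[tw]] <- nodal_von_mises(mesh, res)
  }
  r2 <- c(
    straight_bonded_vs_monolithic =
      nodal_stress_r2(nodal$straight_bonded, mono$straight),
    twisted_bonded_vs_monolithic =
      nodal_stress_r2(nodal$twisted_bonded, mono$twisted),
    twisted_sliding_vs_embedded =
      nodal_stress_r2(nodal$twisted_sliding, mono$twisted))
  structure(list(
    failure_strain = failure, r_squared = r2,
    sliding_strain_gain =
      unname(failure["twisted_sliding"] / failure["twisted_bonded"] - 1),
    twist_deg = twist_deg, threshold = threshold, run_length = run_length,
    compare_strain = compare_strain_used,
    nodal_von_mises = nodal, monolithic_von_mises = mono),
    class = "sliding_comparison")
}

#' @export
print.sliding_comparison <- function(x, ...) {
  cat("sliding_comparison (twist", x$twist_deg, "deg):\n  failure strains:\n")
  for (n in names(x$failure_strain))
    cat(sprintf("    %-18s %.3f\n", n, x$failure_strain[n]))
  cat(sprintf("  sliding vs bonded failure-strain gain: %+.1f%%\n",
              100 * x$sliding_strain_gain))
  for (n in names(x$r_squared))
    cat(sprintf("  r^2 %-32s %.3f\n", n, x$r_squared[n]))
  invisible(x)
}
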