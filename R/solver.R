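#' Boundary conditions for a static solve
#'
#' @param fixed_nodes Node ids whose three displacement components are fixed
#'   to zero (typically the distal face, representing the calcaneal clamp).
#' @param forces Either `NULL` or an `n_nodes x 3` matrix of dead nodal
#'   forces in N.
#' @param prescribed Optional data frame `(node, comp, value)` of nonzero
#'   prescribed displacement components (mm), `comp` in 1:3.
#' @return A `boundary_conditions` object.
#' @export
boundary_conditions <- function(fixed_nodes = integer(), forces = NULL,
                                prescribed = NULL) {
  fixed <- data.frame(node = rep(as.integer(fixed_nodes), each = 3),
                      comp = rep(1:3, length(fixed_nodes)),
                      value = rep(0, 3 * length(fixed_nodes)))
  if (!is.null(prescribed)) {
    stopifnot(all(c("node", "comp", "value") %in% names(prescribed)))
    fixed <- rbind(fixed, prescribed[c("node", "comp", "value")])
    fixed <- fixed[!duplicated(fixed[c("node", "comp")], fromLast = TRUE), ]
  }
  if (!is.null(forces)) {
    fdof <- 3 * (fixed$node - 1) + fixed$comp
    ldof <- which(t(forces) != 0)
    if (length(intersect(fdof, ldof)))
      stop("fixed and loaded dof sets must be disjoint per component")
    if (!all(is.finite(forces))) stop("total applied force must be finite")
  }
  structure(list(fixed = fixed, forces = forces),
            class = "boundary_conditions")
}

# Tributary areas of the nodes of one end face: each boundary quad
# contributes a quarter of its area to each of its four nodes.
face_tributary_areas <- function(mesh, which = c("proximal", "distal"),
                                 elements = NULL) {
  which <- match.arg(which)
  k <- if (which == "proximal") mesh$n_axial else 1L
  loc <- if (which == "proximal") 5:8 else 1:4
  sel <- which(mesh$elem_grid[, 1] == k)
  if (!is.null(elements)) sel <- intersect(sel, elements)
  w <- numeric(nrow(mesh$nodes))
  for (e in sel) {
    ids <- mesh$conn[e, loc]
    p <- mesh$nodes[ids, ]
    a <- 0.5 * sqrt(sum(pracma::cross(p[3, ] - p[1, ], p[4, ] - p[2, ])^2))
    w[ids] <- w[ids] + a / 4
  }
  w
}

# Nodal force matrix applying a total axial force over the proximal face,
# optionally split across sub-tendon node groups (per-node weights by
# tributary area within each group).
proximal_force_matrix <- function(mesh, total_force, split = NULL,
                                  direction = NULL) {
  if (is.null(direction)) direction <- mesh$long_axis
  fmat <- matrix(0, nrow(mesh$nodes), 3)
  if (is.null(split)) {
    w <- face_tributary_areas(mesh, "proximal")
    fmat <- fmat + outer(w / sum(w) * total_force, direction)
  } else {
    stopifnot(!is.null(mesh$subtendon))
    for (g in names(split)) {
      els <- which(mesh$subtendon == g)
      w <- face_tributary_areas(mesh, "proximal", els)
      if (sum(w) <= 0) stop("sub-tendon ", g, " has no proximal face nodes")
      fmat <- fmat + outer(w / sum(w) * total_force * split[[g]], direction)
    }
  }
  fmat
}

# Default solver control settings.
solve_control <- function(tol_rel = 1e-8, max_iter = 50, n_steps = 1,
                          max_bisect = 6, u0 = NULL, ramp_from = 0,
                          verbose = FALSE) {
  list(tol_rel = tol_rel, max_iter = max_iter, n_steps = n_steps,
       max_bisect = max_bisect, u0 = u0, ramp_from = ramp_from,
       verbose = verbose)
}

#' Static nonlinear finite-element solve
#'
#' Newton-Raphson solution of large-deformation equilibrium for the
#' transversely isotropic hyperelastic tendon under dead nodal forces and/or
#' prescribed displacements, with incremental load stepping and automatic
#' step bisection on failure. Optional node-pair constraints (bonded or
#' frictionless-sliding sub-tendon interfaces) are enforced with Lagrange
#' multipliers. The `converged` flag is honest: a non-converged state is
#' returned as such (with diagnostics) and never silently accepted.
#'
#' @param mesh A `tendon_mesh`.
#' @param fiber_field A `fiber_field` with one direction per Gauss point.
#' @param params A [material_params()] object.
#' @param bc A [boundary_conditions()] object.
#' @param interfaces Optional constraint set from [apply_interface()].
#' @param control List of solver settings from `solve_control()`: relative
#'   force-residual tolerance `tol_rel` (default 1e-8), `max_iter` Newton
#'   iterations per step (50), initial number of load steps `n_steps`,
#'   `max_bisect` step bisections, warm-start displacement `u0`.
#' @return A `solve_result`: nodal displacements (mm), per-Gauss-point
#'   Cauchy stress (9 columns, column-major) and von Mises stress (MPa),
#'   current-volume Gauss weights, reactions at fixed dofs, convergence
#'   diagnostics.
#' @export
solve_static <- function(mesh, fiber_field, params, bc,
                         interfaces = NULL, control = solve_control()) {
  control <- utils::modifyList(solve_control(), control)
  nn <- nrow(mesh$nodes); ndof <- 3L * nn
  pv <- params_vec(params)
  fib <- fiber_field$gauss_fiber_dirs
  stopifnot(nrow(fib) == 8 * nrow(mesh$conn))

  fixed_dof <- 3L * (bc$fixed$node - 1L) + bc$fixed$comp
  fixed_val <- bc$fixed$value
  if (anyDuplicated(fixed_dof)) {
    keep <- !duplicated(fixed_dof, fromLast = TRUE)
    fixed_dof <- fixed_dof[keep]; fixed_val <- fixed_val[keep]
  }
  free <- setdiff(seq_len(ndof), fixed_dof)
  fext <- if (is.null(bc$forces)) numeric(ndof) else as.vector(t(bc$forces))

  G <- NULL
  if (!is.null(interfaces)) {
    G <- interfaces$G
    stopifnot(ncol(G) == ndof)
    G <- G[, free, drop = FALSE]
    keep <- Matrix::rowSums(G != 0) > 0
    G <- G[keep, , drop = FALSE]
  }
  nc <- if (is.null(G)) 0L else nrow(G)

  u <- if (is.null(control$u0)) matrix(0, nn, 3) else control$u0
  lam <- numeric(nc)
  uvec <- as.vector(t(u))

  # the tangent sparsity pattern is fixed: build the triplet -> CSC slot
  # map once, then refresh the values by a precomputed gather + segmented
  # cumulative sum (cheaper than re-sorting triplets every iteration)
  K_template <- NULL; K_ord <- NULL; K_ends <- NULL
  build_K <- function(asm) {
    if (is.null(K_template)) {
      K <- Matrix::sparseMatrix(i = asm$ti, j = asm$tj, x = asm$tv,
                                dims = c(ndof, ndof))
      j_csc <- rep(seq_len(ndof), diff(K@p))
      kmap <- match(asm$ti + ndof * (asm$tj - 1),
                    (K@i + 1) + ndof * (j_csc - 1))
      K_ord <<- order(kmap)
      K_ends <<- cumsum(tabulate(kmap, nbins = length(K@x)))
      K_template <<- K
      K
    } else {
      K <- K_template
      cs <- cumsum(asm$tv[K_ord])
      K@x <- cs[K_ends] - c(0, cs[K_ends[-length(K_ends)]])
      K
    }
  }

  total_iter <- 0L; n_steps_done <- 0L
  # a warm start u0 is assumed consistent with load factor ramp_from, so a
  # bisected staircase step never rewinds the load below its starting state
  # (capped below 1 so at least one equilibrium solve always happens)
  s <- max(0, min(0.999, control$ramp_from))
  ds <- (1 - s) / control$n_steps
  ds_min <- ds / 2^control$max_bisect
  converged_all <- TRUE
  diag_msg <- NULL

  newton <- function(uvec, lam, s) {
    uvec[fixed_dof] <- s * fixed_val
    ref <- max(1, s * sqrt(sum(fext^2)))
    rhist <- rep(NA_real_, control$max_iter)
    for (it in seq_len(control$max_iter)) {
      U <- matrix(uvec, nn, 3, byrow = TRUE)
      asm <- .tt_assemble(mesh$nodes, U, mesh$conn, fib, pv, TRUE, FALSE)
      if (!isTRUE(asm$ok))
        return(list(ok = FALSE, why = paste0("element ", asm$bad_element,
                                             " inverted")))
      res <- asm$resid - s * fext
      ref <- max(1, s * sqrt(sum(fext^2)), sqrt(sum(res[fixed_dof]^2)))
      rfree <- res[free]
      if (nc > 0) rfree <- rfree + as.vector(Matrix::crossprod(G, lam))
      rnorm <- sqrt(sum(rfree^2))
      if (!is.finite(rnorm) || rnorm > 1e10 * ref)
        return(list(ok = FALSE, why = "residual diverged"))
      if (rnorm <= control$tol_rel * ref)
        return(list(ok = TRUE, uvec = uvec, lam = lam, iters = it - 1L))
      rhist[it] <- rnorm
      # stagnation guard (e.g. iterates oscillating across the fiber-law
      # kink): no net decay over a 6-iteration window triggers load
      # bisection instead of burning the full iteration budget
      if (it >= 10 && rnorm > 0.9 * rhist[it - 6])
        return(list(ok = FALSE, why = "stagnating residual", iters = it))
      K <- build_K(asm)
      Kff <- K[free, free, drop = FALSE]
      if (nc > 0) {
        gap <- as.vector(G %*% uvec[free])
        A <- rbind(cbind(Kff, Matrix::t(G)),
                   cbind(G, Matrix::sparseMatrix(i = integer(), j = integer(),
                                                 dims = c(nc, nc))))
        rhs <- c(-rfree, -gap)
      } else {
        A <- Matrix::forceSymmetric(Kff); rhs <- -rfree
      }
      du <- try(as.vector(Matrix::solve(A, rhs)), silent = TRUE)
      if (inherits(du, "try-error") && nc == 0)  # indefinite state: LU
        du <- try(as.vector(Matrix::solve(Kff, rhs)), silent = TRUE)
      if (inherits(du, "try-error") || !all(is.finite(du)))
        return(list(ok = FALSE, why = "linear solve failed"))
      # backtracking line search on the force residual
      alpha <- 1; accepted <- FALSE
      for (ls in 1:6) {
        utry <- uvec; utry[free] <- uvec[free] + alpha * du[seq_along(free)]
        ltry <- if (nc > 0) lam + alpha * du[length(free) + seq_len(nc)] else lam
        Ut <- matrix(utry, nn, 3, byrow = TRUE)
        at <- .tt_assemble(mesh$nodes, Ut, mesh$conn, fib, pv, FALSE, FALSE)
        if (isTRUE(at$ok)) {
          rt <- at$resid - s * fext
          rtf <- rt[free]
          if (nc > 0) rtf <- rtf + as.vector(Matrix::crossprod(G, ltry))
          rn_t <- sqrt(sum(rtf^2))
          if (is.finite(rn_t) && (rn_t < rnorm || alpha < 0.2)) {
            uvec <- utry; lam <- ltry; accepted <- TRUE
            break
          }
        }
        alpha <- alpha / 2
      }
      if (!accepted)
        return(list(ok = FALSE, why = "line search failed"))
    }
    list(ok = FALSE, why = "max Newton iterations reached")
  }

  while (s < 1 - 1e-12) {
    s_try <- min(1, s + ds)
    st <- newton(uvec, lam, s_try)
    total_iter <- total_iter + if (is.null(st$iters)) control$max_iter else st$iters
    if (st$ok) {
      uvec <- st$uvec; lam <- st$lam; s <- s_try
      n_steps_done <- n_steps_done + 1L
      ds <- min(ds * 1.5, (1 - control$ramp_from) / control$n_steps)
      if (control$verbose) message(sprintf("  step to s=%.3f (%d iters)", s, st$iters))
    } else {
      ds <- ds / 2
      if (control$verbose) message("  bisecting step (", st$why, "), ds=", ds)
      if (ds < ds_min) {
        converged_all <- FALSE
        diag_msg <- paste0("load stepping failed at factor ", round(s, 4),
                           ": ", st$why)
        break
      }
    }
  }

  U <- matrix(uvec, nn, 3, byrow = TRUE)
  asm <- .tt_assemble(mesh$nodes, U, mesh$conn, fib, pv, FALSE, TRUE)
  res <- if (isTRUE(asm$ok)) asm$resid - s * fext else rep(NA_real_, ndof)
  reactions <- res
  reactions[free] <- 0
  structure(list(
    nodal_displacements = U,
    gauss_cauchy_stress = if (isTRUE(asm$ok)) asm$gp_stress else NULL,
    gauss_von_mises = if (isTRUE(asm$ok)) asm$gp_vm else NULL,
    gauss_weight = if (isTRUE(asm$ok)) asm$gp_w else NULL,
    converged = converged_all && s >= 1 - 1e-12,
    load_factor = s,
    newton_iterations = total_iter, load_steps = n_steps_done,
    reactions = matrix(reactions, nn, 3, byrow = TRUE),
    multipliers = lam, diagnostics = diag_msg,
    lambda_star = params$lambda_star), class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("solve_result: %s (load factor %.3f, %d steps, %d Newton iters)\n",
              if (x$converged) "converged" else "NOT converged",
              x$load_factor, x$load_steps, x$newton_iterations))
  if (!is.null(x$gauss_von_mises))
    cat(sprintf("  von Mises: max %.2f MPa, mean %.2f MPa\n",
                max(x$gauss_von_mises), mean(x$gauss_von_mises)))
  if (!is.null(x$diagnostics)) cat("  ", x$diagnostics, "\n")
  invisible(x)
}

#' Build a sub-tendon interface constraint set
#'
#' Converts node pairs on geometrically coincident sub-tendon surfaces into
#' linear constraints: `bonded` ties all three displacement components of
#' each pair; `frictionless_sliding` ties only the component along the
#' interface normal (no interpenetration, free tangential slip).
#'
#' @param interface A `sliding_interface` (see [split_subtendon_mesh()]):
#'   list with `pairs` (m x 2 node ids) and `normals` (m x 3 unit vectors).
#' @param mode `"bonded"` or `"frictionless_sliding"`.
#' @param n_nodes Total node count of the mesh the constraints address.
#' @return Constraint set with sparse matrix `G` (rows are constraints over
#'   the 3n displacement vector, node-major xyz).
#' @export
apply_interface <- function(interface, mode = c("bonded",
                                                "frictionless_sliding"),
                            n_nodes) {
  mode <- match.arg(mode)
  pr <- interface$pairs
  m <- nrow(pr)
  if (m == 0) stop("empty interface pairing")
  if (!is.null(interface$ref_coords)) {
    d <- interface$ref_coords$a - interface$ref_coords$b
    if (max(abs(d)) > 1e-6)
      stop("interface node pairs are not geometrically coincident")
  }
  ndof <- 3L * n_nodes
  if (mode == "bonded") {
    i <- rep(seq_len(3 * m), 2)
    j <- c(3 * (rep(pr[, 1], each = 3) - 1) + 1:3,
           3 * (rep(pr[, 2], each = 3) - 1) + 1:3)
    x <- c(rep(1, 3 * m), rep(-1, 3 * m))
    G <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(3 * m, ndof))
  } else {
    nrm <- interface$normals
    i <- rep(seq_len(m), 6)
    j <- c(3 * (pr[, 1] - 1) + 1, 3 * (pr[, 1] - 1) + 2, 3 * (pr[, 1] - 1) + 3,
           3 * (pr[, 2] - 1) + 1, 3 * (pr[, 2] - 1) + 2, 3 * (pr[, 2] - 1) + 3)
    x <- c(nrm[, 1], nrm[, 2], nrm[, 3], -nrm[, 1], -nrm[, 2], -nrm[, 3])
    G <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(m, ndof))
  }
  structure(list(G = G, mode = mode, pairs = pr, normals = interface$normals),
            class = "interface_constraints")
}

# Locate reference points in the mesh: element id and local coordinates via
# Newton inversion of the trilinear map, searching nearest elements first.
locate_points <- function(mesh, points, tol = 0.05) {
  cen <- element_centroids(mesh)
  ne <- nrow(mesh$conn)
  out_e <- integer(nrow(points)); out_xi <- matrix(0, nrow(points), 3)
  for (p in seq_len(nrow(points))) {
    x <- points[p, ]
    cand <- order((cen[, 1] - x[1])^2 + (cen[, 2] - x[2])^2 +
                  (cen[, 3] - x[3])^2)[seq_len(min(12, ne))]
    found <- FALSE
    best_xi <- NULL; best_e <- NA; best_over <- Inf
    for (e in cand) {
      Xe <- mesh$nodes[mesh$conn[e, ], ]
      xi <- c(0, 0, 0)
      for (it in 1:30) {
        N <- shape_values(matrix(xi, 1))
        r <- drop(N %*% Xe) - x
        if (max(abs(r)) < 1e-10) break
        d <- dshape_values(xi)
        J <- t(Xe) %*% d
        xi <- xi - drop(solve(J, r))
        if (max(abs(xi)) > 3) break
      }
      over <- max(abs(xi)) - 1
      if (over < best_over) { best_over <- over; best_xi <- xi; best_e <- e }
      if (over <= 1e-9) { found <- TRUE; break }
    }
    if (!found && best_over > tol)
      stop("point (", paste(signif(x, 4), collapse = ", "),
           ") lies outside the mesh beyond tolerance")
    out_e[p] <- best_e
    out_xi[p, ] <- pmax(-1, pmin(1, best_xi))
  }
  list(elem = out_e, local = out_xi)
}

# Shape function derivatives at a single local point: 8 x 3.
dshape_values <- function(xi) {
  s <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
             c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  d <- matrix(0, 8, 3)
  for (a in 1:8) {
    d[a, 1] <- 0.125 * s[a, 1] * (1 + xi[2] * s[a, 2]) * (1 + xi[3] * s[a, 3])
    d[a, 2] <- 0.125 * (1 + xi[1] * s[a, 1]) * s[a, 2] * (1 + xi[3] * s[a, 3])
    d[a, 3] <- 0.125 * (1 + xi[1] * s[a, 1]) * (1 + xi[2] * s[a, 2]) * s[a, 3]
  }
  d
}

# Sparse interpolation matrix (m x n_nodes) whose product with the nodal
# displacement matrix gives displacements at the given reference points.
point_interp_matrix <- function(mesh, points, tol = 0.05) {
  loc <- locate_points(mesh, points, tol)
  N <- shape_values(loc$local)
  Matrix::sparseMatrix(i = rep(seq_len(nrow(points)), 8),
                       j = as.vector(mesh$conn[loc$elem, ]),
                       x = as.vector(N),
                       dims = c(nrow(points), nrow(mesh$nodes)))
}

#' Convect surface markers with the displacement field
#'
#' @param mesh A `tendon_mesh`.
#' @param result A `solve_result` (or a nodal displacement matrix).
#' @param marker_positions Reference marker coordinates (m x 3), on or near
#'   the mesh surface (projected if within tolerance in local coordinates).
#' @return Displaced marker coordinates (m x 3).
#' @export
track_markers <- function(mesh, result, marker_positions) {
  U <- if (inherits(result, "solve_result")) result$nodal_displacements
       else result
  S <- point_interp_matrix(mesh, marker_positions)
  marker_positions + as.matrix(S %*% U)
}

# In-plane principal-axis angle and aspect ratio of a point set (2-column),
# from second moments about the centroid.
principal_axis_angle <- function(xy) {
  q <- sweep(xy, 2, colMeans(xy))
  M <- crossprod(q) / nrow(q)
  ev <- eigen(M, symmetric = TRUE)
  v <- ev$vectors[, 1]
  list(angle = atan2(v[2], v[1]) %% pi,
       aspect = sqrt(max(ev$values) / max(ev$values[2], 1e-30)))
}

#' Transverse rotation of the loaded tendon
#'
#' Rotation of the proximal-most cross-section's in-plane principal axis
#' relative to the distal-most section's, in degrees, measured on the
#' deformed configuration and referenced to the undeformed state (so zero
#' displacement gives exactly 0). Positive is anticlockwise about the long
#' axis viewed from proximal. Near-circular sections (principal-axis aspect
#' ratio < 1.05) fall back to the mean azimuthal rotation of the section
#' nodes about the section centroid.
#'
#' @param mesh A `tendon_mesh`.
#' @param result A `solve_result`.
#' @return Angle in degrees.
#' @export
transverse_rotation <- function(mesh, result) {
  U <- result$nodal_displacements
  nu <- mesh$n_circ; nv <- mesh$n_radial
  npl <- (nu + 1) * (nv + 1)
  sect <- function(k) (k - 1) * npl + seq_len(npl)
  dist_idx <- sect(1); prox_idx <- sect(mesh$n_axial + 1)
  ang_pair <- function(idx) {
    ref <- principal_axis_angle(mesh$nodes[idx, 1:2, drop = FALSE])
    cur <- principal_axis_angle(mesh$nodes[idx, 1:2, drop = FALSE] +
                                U[idx, 1:2, drop = FALSE])
    if (ref$aspect < 1.05 || cur$aspect < 1.05) {
      # degenerate principal axis: mean azimuthal rotation instead
      p0 <- sweep(mesh$nodes[idx, 1:2, drop = FALSE], 2,
                  colMeans(mesh$nodes[idx, 1:2, drop = FALSE]))
      p1 <- mesh$nodes[idx, 1:2, drop = FALSE] + U[idx, 1:2, drop = FALSE]
      p1 <- sweep(p1, 2, colMeans(p1))
      da <- atan2(p1[, 2], p1[, 1]) - atan2(p0[, 2], p0[, 1])
      da <- (da + pi) %% (2 * pi) - pi
      r <- sqrt(rowSums(p0^2))
      return(sum(da * r) / sum(pmax(r, 1e-12)))
    }
    d <- cur$angle - ref$angle
    (d + pi / 2) %% pi - pi / 2
  }
  (ang_pair(prox_idx) - ang_pair(dist_idx)) * 180 / pi
}
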