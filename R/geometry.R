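#' Cross-section profile of the free tendon
#'
#' A profile is a table of elliptical cross-sections along the tendon's long
#' axis: axial station (mm), ellipse semi-axes (mm) and in-plane centroid
#' offsets (mm). The mesh generator lofts a solid through these sections.
#' Coordinate convention: x = medial(+)/lateral(-), y = anterior(+)/
#' posterior(-), z = distal (0) to proximal (+).
#'
#' @param stations Data frame with columns `station_mm`, `semi_axis_a_mm`
#'   (medial-lateral), `semi_axis_b_mm` (anterior-posterior), `offset_x_mm`,
#'   `offset_y_mm`. At least two rows, strictly increasing stations,
#'   positive semi-axes.
#' @return An object of class `cross_section_profile`.
#' @export
cross_section_profile <- function(stations) {
  need <- c("station_mm", "semi_axis_a_mm", "semi_axis_b_mm",
            "offset_x_mm", "offset_y_mm")
  if (!is.data.frame(stations) || !all(need %in% names(stations)))
    stop("stations must be a data frame with columns: ",
         paste(need, collapse = ", "))
  stations <- stations[need]
  if (nrow(stations) < 2) stop("need at least 2 stations")
  if (any(diff(stations$station_mm) <= 0))
    stop("station positions must be strictly increasing")
  if (any(stations$semi_axis_a_mm <= 0) || any(stations$semi_axis_b_mm <= 0))
    stop("semi-axes must be positive")
  structure(list(stations = stations), class = "cross_section_profile")
}

#' @export
print.cross_section_profile <- function(x, ...) {
  cat("Cross-section profile (", nrow(x$stations), " stations):\n", sep = "")
  print(x$stations, row.names = FALSE)
  invisible(x)
}

#' @rdname cross_section_profile
#' @param profile A `cross_section_profile`.
#' @param path CSV file path.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(profile$stations, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cross_section_profile
#' @export
read_profile_csv <- function(path) {
  cross_section_profile(utils::read.csv(path))
}

#' Analytic cross-section area of a profile station
#' @param profile A [cross_section_profile()].
#' @param z Axial position(s), mm (linearly interpolated between stations).
#' @return Ellipse area pi*a*b in mm^2.
#' @export
profile_csa <- function(profile, z) {
  f <- profile_interp(profile)
  pi * f$a(z) * f$b(z)
}

# Linear interpolants of the profile fields along the axis.
profile_interp <- function(profile) {
  s <- profile$stations
  mk <- function(col) {
    stats::approxfun(s$station_mm, s[[col]], rule = 2)
  }
  list(a = mk("semi_axis_a_mm"), b = mk("semi_axis_b_mm"),
       ox = mk("offset_x_mm"), oy = mk("offset_y_mm"),
       z0 = s$station_mm[1], z1 = s$station_mm[nrow(s)])
}

# Smooth square-to-disk mapping (elliptical mapping): takes the structured
# (u,v) grid on [-1,1]^2 onto the unit disk without a polar singularity.
square_to_disk <- function(u, v) {
  list(x = u * sqrt(pmax(0, 1 - v^2 / 2)), y = v * sqrt(pmax(0, 1 - u^2 / 2)))
}

#' Build a hexahedral tendon mesh from a cross-section profile
#'
#' Lofts the elliptical sections into a structured 8-node hexahedral mesh.
#' Each cross-section is discretized by mapping an
#' `n_circumferential x n_radial` structured grid on the square smoothly
#' onto the ellipse (so the section boundary is an inscribed polygon with
#' `2 (n_circumferential + n_radial)` edges); `n_axial` element layers span
#' the axis. At the default resolution (6 x 6 in-plane) the meshed
#' cross-section area is within 2% of the analytic `pi a b`.
#'
#' @param profile A [cross_section_profile()].
#' @param n_axial Number of element layers along the axis (>= 1).
#' @param n_circumferential In-plane divisions across the medial-lateral
#'   (x) direction (>= 1).
#' @param n_radial In-plane divisions across the anterior-posterior (y)
#'   direction (>= 1).
#' @return A `tendon_mesh`: node coordinates (mm), hex connectivity (VTK
#'   node ordering, local zeta axial), structured grid indices, distal and
#'   proximal node sets, long axis, and the generating profile. Element
#'   labels (`compartment`, `subtendon`) start unset.
#' @export
build_tendon_mesh <- function(profile, n_axial = 8, n_circumferential = 6,
                              n_radial = 6) {
  stopifnot(inherits(profile, "cross_section_profile"))
  if (n_axial < 1 || n_circumferential < 1 || n_radial < 1)
    stop("resolution parameters must be >= 1")
  nu <- n_circumferential; nv <- n_radial; nz <- n_axial
  f <- profile_interp(profile)
  if (pi * f$a(f$z0) * f$b(f$z0) <= 0) stop("degenerate profile")

  u <- seq(-1, 1, length.out = nu + 1)
  v <- seq(-1, 1, length.out = nv + 1)
  g <- expand.grid(u = u, v = v)        # u fastest
  d <- square_to_disk(g$u, g$v)
  zs <- seq(f$z0, f$z1, length.out = nz + 1)

  npl <- (nu + 1) * (nv + 1)            # nodes per plane
  nodes <- matrix(0, npl * (nz + 1), 3)
  for (k in seq_len(nz + 1)) {
    z <- zs[k]
    idx <- (k - 1) * npl + seq_len(npl)
    nodes[idx, 1] <- f$ox(z) + f$a(z) * d$x
    nodes[idx, 2] <- f$oy(z) + f$b(z) * d$y
    nodes[idx, 3] <- z
  }

  nid <- function(i, j, k) (k - 1) * npl + (j - 1) * (nu + 1) + i
  ne <- nu * nv * nz
  conn <- matrix(0L, ne, 8)
  egrid <- matrix(0L, ne, 3)
  e <- 0L
  for (k in seq_len(nz)) for (j in seq_len(nv)) for (i in seq_len(nu)) {
    e <- e + 1L
    conn[e, ] <- c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k),
                   nid(i, j + 1, k), nid(i, j, k + 1), nid(i + 1, j, k + 1),
                   nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
    egrid[e, ] <- c(k, i, j)            # axial, u, v element indices
  }

  mesh <- structure(list(
    nodes = nodes, conn = conn, elem_grid = egrid,
    n_axial = nz, n_circ = nu, n_radial = nv,
    z_planes = zs, profile = profile,
    long_axis = c(0, 0, 1), medial_axis = c(1, 0, 0),
    distal_nodes = as.integer(nid(rep(seq_len(nu + 1), nv + 1),
                                  rep(seq_len(nv + 1), each = nu + 1), 1)),
    proximal_nodes = as.integer(nid(rep(seq_len(nu + 1), nv + 1),
                                    rep(seq_len(nv + 1), each = nu + 1),
                                    nz + 1)),
    gauss_order = 2L,
    compartment = NULL, subtendon = NULL,
    disk_uv = cbind(d$x, d$y)), class = "tendon_mesh")

  q <- .tt_mesh_quality(mesh$nodes, mesh$conn)
  if (any(q$min_jac <= 0)) stop("mesh contains inverted elements")
  mesh$elem_volume <- q$volume
  mesh
}

#' @export
print.tendon_mesh <- function(x, ...) {
  cat(sprintf("tendon_mesh: %d nodes, %d hex elements (%d axial x %d x %d)\n",
              nrow(x$nodes), nrow(x$conn), x$n_axial, x$n_circ, x$n_radial))
  cat(sprintf("  axial span %.1f..%.1f mm, volume %.1f mm^3\n",
              x$z_planes[1], x$z_planes[length(x$z_planes)],
              sum(x$elem_volume)))
  if (!is.null(x$compartment))
    cat("  compartments:", paste(names(table(x$compartment)),
                                 table(x$compartment), collapse = ", "), "\n")
  if (!is.null(x$subtendon))
    cat("  sub-tendons:", paste(names(table(x$subtendon)),
                                table(x$subtendon), collapse = ", "), "\n")
  invisible(x)
}

# Element centroids (reference configuration).
element_centroids <- function(mesh) {
  n <- mesh$nodes
  (n[mesh$conn[, 1], , drop = FALSE] + n[mesh$conn[, 2], , drop = FALSE] +
   n[mesh$conn[, 3], , drop = FALSE] + n[mesh$conn[, 4], , drop = FALSE] +
   n[mesh$conn[, 5], , drop = FALSE] + n[mesh$conn[, 6], , drop = FALSE] +
   n[mesh$conn[, 7], , drop = FALSE] + n[mesh$conn[, 8], , drop = FALSE]) / 8
}

# Section centroid (offset) at an axial position, from the profile.
section_centroid <- function(mesh, z) {
  f <- profile_interp(mesh$profile)
  cbind(f$ox(z), f$oy(z))
}

#' Measured cross-section area of a mesh section
#'
#' Sums the in-plane quadrilateral areas of the node plane closest to `z`
#' (shoelace per cell), on current coordinates if displacements are given.
#'
#' @param mesh A `tendon_mesh`.
#' @param z Axial position, mm.
#' @param displacements Optional nodal displacement matrix to evaluate the
#'   deformed section.
#' @return Area in mm^2.
#' @export
mesh_section_csa <- function(mesh, z, displacements = NULL) {
  k <- which.min(abs(mesh$z_planes - z))
  nu <- mesh$n_circ; nv <- mesh$n_radial
  npl <- (nu + 1) * (nv + 1)
  idx <- (k - 1) * npl + seq_len(npl)
  xy <- mesh$nodes[idx, 1:2, drop = FALSE]
  if (!is.null(displacements)) xy <- xy + displacements[idx, 1:2, drop = FALSE]
  quad_area <- function(p) {
    0.5 * abs(sum(p[, 1] * p[c(2:4, 1), 2] - p[c(2:4, 1), 1] * p[, 2]))
  }
  a <- 0
  for (j in seq_len(nv)) for (i in seq_len(nu)) {
    ids <- c((j - 1) * (nu + 1) + i, (j - 1) * (nu + 1) + i + 1,
             j * (nu + 1) + i + 1, j * (nu + 1) + i)
    a <- a + quad_area(xy[ids, , drop = FALSE])
  }
  a
}

#' Label medial and lateral compartments
#'
#' Splits elements along the center line: an element is `medial` when its
#' centroid lies on the positive side of the medial-lateral axis through the
#' section centroid at its axial position, `lateral` otherwise.
#'
#' @param mesh A `tendon_mesh`.
#' @return The mesh with a `compartment` factor per element.
#' @export
label_compartments <- function(mesh) {
  cen <- element_centroids(mesh)
  f <- profile_interp(mesh$profile)
  rel <- cen[, 1] - f$ox(cen[, 3])
  if (max(abs(rel)) < 1e-9) stop("zero-width mesh: cannot split compartments")
  mesh$compartment <- factor(ifelse(rel >= 0, "medial", "lateral"),
                             levels = c("medial", "lateral"))
  mesh
}

#' Label sub-tendons by angular sectors of the cross-section
#'
#' Partitions the cross-section into angular sectors around the section
#' centroid, anticlockwise starting from the medial (+x) axis, with area
#' fractions 6:2:1 (`three_way`: soleus, medial gastrocnemius, lateral
#' gastrocnemius) or 6:3 (`two_way`: soleus, gastrocnemius). The partition
#' is identical in every axial layer. Cells are assigned greedily in angular
#' order by accumulated in-plane area, so achieved fractions are within one
#' element of the targets; too coarse a section is an error.
#'
#' @param mesh A `tendon_mesh`.
#' @param scheme `"three_way"` (SOL/MG/LG) or `"two_way"` (SOL/GAS).
#' @param fractions Optional named area fractions overriding the scheme
#'   defaults (must sum to 1). Anatomical morphometry puts the soleus
#'   sub-tendon at only about half the tendon cross-section (around
#'   52/35/13), below its two-thirds share of the plantar-flexor force --
#'   the mismatch that drives differential loading; pass such fractions to
#'   emulate it.
#' @return The mesh with a `subtendon` factor per element.
#' @export
label_subtendons <- function(mesh, scheme = c("three_way", "two_way"),
                             fractions = NULL) {
  scheme <- match.arg(scheme)
  nu <- mesh$n_circ; nv <- mesh$n_radial
  ncell <- nu * nv
  # in-plane cell geometry on the unit disk (area fractions are invariant
  # under the affine per-section scaling to the actual ellipse)
  uv <- mesh$disk_uv
  cell_nodes <- function(i, j) c((j - 1) * (nu + 1) + i,
                                 (j - 1) * (nu + 1) + i + 1,
                                 j * (nu + 1) + i + 1, j * (nu + 1) + i)
  area <- ang <- numeric(ncell)
  c_idx <- 0
  for (j in seq_len(nv)) for (i in seq_len(nu)) {
    c_idx <- c_idx + 1
    p <- uv[cell_nodes(i, j), , drop = FALSE]
    area[c_idx] <- 0.5 * abs(sum(p[, 1] * p[c(2:4, 1), 2] -
                                 p[c(2:4, 1), 1] * p[, 2]))
    cc <- colMeans(p)
    ang[c_idx] <- atan2(cc[2], cc[1]) %% (2 * pi)
  }
  ord <- order(ang)
  frac <- cumsum(area[ord]) / sum(area)
  targets <- if (!is.null(fractions)) {
    if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
    fractions
  } else if (scheme == "three_way") c(SOL = 6, MG = 2, LG = 1) / 9
    else c(SOL = 6, GAS = 3) / 9
  cuts <- cumsum(targets)
  lab_cell <- character(ncell)
  lo <- 0
  for (gi in seq_along(targets)) {
    hi <- if (gi == length(targets)) ncell else {
      w <- which(frac >= cuts[gi] - 1e-12)
      # cut at the cell boundary nearest the target fraction
      k <- w[1]
      if (k > lo + 1 && abs(frac[k - 1] - cuts[gi]) < abs(frac[k] - cuts[gi]))
        k - 1 else k
    }
    if (hi <= lo) stop("insufficient circumferential resolution to realize ",
                       "the sub-tendon area fractions")
    lab_cell[ord[(lo + 1):hi]] <- names(targets)[gi]
    lo <- hi
  }
  ach <- tapply(area, lab_cell, sum) / sum(area)
  maxcell <- max(area) / sum(area)
  if (any(abs(ach[names(targets)] - targets) > maxcell + 1e-12))
    stop("insufficient circumferential resolution to realize ",
         "the sub-tendon area fractions")
  # map in-plane cell labels onto all axial layers
  cell_of_elem <- (mesh$elem_grid[, 3] - 1) * nu + mesh$elem_grid[, 2]
  mesh$subtendon <- factor(lab_cell[cell_of_elem], levels = names(targets))
  mesh
}

#' Free-form scaling of the mid-section cross-sectional area
#'
#' Scales the in-plane coordinates about the section centroid by a smooth
#' axial blend `scale^(w(z)/2)` with `w = sin^2(pi zt)` (zt the axial
#' fraction), so the mid-section area is multiplied exactly by `scale` while
#' the end sections are unchanged.
#'
#' @param mesh A `tendon_mesh`.
#' @param scale Area scale factor for the mid-section (> 0).
#' @return The morphed mesh (labels preserved). Scaling that inverts
#'   elements is an error.
#' @export
ffd_scale_csa <- function(mesh, scale) {
  if (scale <= 0) stop("scale must be > 0")
  if (scale < 0.01)
    stop("CSA scaling of ", scale,
         " inverts or degenerates elements at this resolution")
  if (scale == 1) return(mesh)
  q0 <- .tt_mesh_quality(mesh$nodes, mesh$conn)
  f <- profile_interp(mesh$profile)
  z <- mesh$nodes[, 3]
  zt <- (z - f$z0) / (f$z1 - f$z0)
  fac <- scale^(sin(pi * zt)^2 / 2)
  cx <- f$ox(z); cy <- f$oy(z)
  mesh$nodes[, 1] <- cx + fac * (mesh$nodes[, 1] - cx)
  mesh$nodes[, 2] <- cy + fac * (mesh$nodes[, 2] - cy)
  q <- .tt_mesh_quality(mesh$nodes, mesh$conn)
  if (any(q$min_jac <= 0.01 * q0$min_jac))
    stop("CSA scaling of ", scale,
         " inverts or degenerates elements at this resolution")
  mesh$elem_volume <- q$volume
  mesh$csa_scale <- scale * if (is.null(mesh$csa_scale)) 1 else mesh$csa_scale
  mesh
}

# Reference coordinates of all Gauss points, (nelem*8) x 3, gp order
# matching the C++ kernels (xi fastest, zeta = axial slowest).
mesh_gauss_coords <- function(mesh) {
  gp <- gauss_local()
  N <- shape_values(gp)                 # 8 gp x 8 nodes
  ne <- nrow(mesh$conn)
  out <- matrix(0, ne * 8, 3)
  for (a in 1:8) {
    xa <- mesh$nodes[mesh$conn[, a], , drop = FALSE]   # ne x 3
    for (q in 1:8) {
      rows <- seq.int(q, by = 8, length.out = ne)
      out[rows, ] <- out[rows, ] + N[q, a] * xa
    }
  }
  out
}

# 2x2x2 Gauss point local coordinates, xi fastest (must match fe_core.cpp).
gauss_local <- function() {
  g <- 1 / sqrt(3)
  as.matrix(expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g)))
}

# Trilinear shape function values at given local points: npts x 8.
shape_values <- function(pts) {
  s <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
             c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  out <- matrix(0, nrow(pts), 8)
  for (a in 1:8)
    out[, a] <- 0.125 * (1 + pts[, 1] * s[a, 1]) * (1 + pts[, 2] * s[a, 2]) *
      (1 + pts[, 3] * s[a, 3])
  out
}
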