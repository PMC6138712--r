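#' Write a tendon mesh (and optional fields) as legacy VTK
#'
#' ASCII legacy unstructured-grid format with hexahedron cells. Compartment
#' and sub-tendon labels are written as integer cell data; point and cell
#' arrays supplied by the caller are appended (vectors as 3-column
#' matrices, scalars as vectors).
#'
#' @param mesh A `tendon_mesh`.
#' @param path Output file path (conventionally `.vtk`).
#' @param point_data Named list of per-node arrays.
#' @param cell_data Named list of per-element arrays.
#' @param displacements Optional nodal displacements added to the written
#'   coordinates (to export a deformed configuration).
#' @export
write_vtk_mesh <- function(mesh, path, point_data = list(),
                           cell_data = list(), displacements = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nodes <- mesh$nodes
  if (!is.null(displacements)) nodes <- nodes + displacements
  nn <- nrow(nodes); ne <- nrow(mesh$conn)
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("tendontwist mesh (mm; x medial+, y anterior+, z distal->proximal)")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS ", nn, " double")
  utils::write.table(format(nodes, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  wl("CELLS ", ne, " ", ne * 9)
  utils::write.table(cbind(8L, mesh$conn - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  wl("CELL_TYPES ", ne)
  writeLines(rep("12", ne), con)
  if (!is.null(mesh$compartment))
    cell_data$compartment <- as.integer(mesh$compartment)
  if (!is.null(mesh$subtendon))
    cell_data$subtendon <- as.integer(mesh$subtendon)
  write_block <- function(data, n, kind) {
    if (!length(data)) return()
    wl(kind, " ", n)
    for (nm in names(data)) {
      x <- data[[nm]]
      if (is.matrix(x) && ncol(x) == 3) {
        wl("VECTORS ", nm, " double")
        utils::write.table(format(x, digits = 10, trim = TRUE), con,
                           row.names = FALSE, col.names = FALSE,
                           quote = FALSE)
      } else {
        wl("SCALARS ", nm, if (is.integer(x)) " int 1" else " double 1")
        wl("LOOKUP_TABLE default")
        writeLines(format(x, digits = 10, trim = TRUE), con)
      }
    }
  }
  write_block(point_data, nn, "POINT_DATA")
  write_block(cell_data, ne, "CELL_DATA")
  invisible(path)
}

#' Export a solve result as VTK
#'
#' Writes the mesh with nodal displacements (as a vector field) and the
#' element-mean von Mises stress as cell data.
#'
#' @param mesh A `tendon_mesh`.
#' @param result A `solve_result`.
#' @param path Output file path.
#' @param deformed Write deformed coordinates (default FALSE; the
#'   displacement field is always included).
#' @export
write_vtk_result <- function(mesh, result, path, deformed = FALSE) {
  ne <- nrow(mesh$conn)
  evm <- vapply(seq_len(ne), function(e) {
    idx <- 8 * (e - 1) + 1:8
    sum(result$gauss_von_mises[idx] * result$gauss_weight[idx]) /
      sum(result$gauss_weight[idx])
  }, 0)
  write_vtk_mesh(
    mesh, path,
    point_data = list(displacement = result$nodal_displacements),
    cell_data = list(von_mises = evm),
    displacements = if (deformed) result$nodal_displacements else NULL)
}

#' Read node coordinates and hexahedral connectivity from a legacy VTK file
#'
#' Minimal reader for the ASCII unstructured-grid files written by
#' [write_vtk_mesh()] (points, hexahedron cells and integer cell scalars).
#'
#' @param path VTK file path.
#' @return List with `nodes`, `conn` (1-based) and any integer cell-data
#'   scalars found.
#' @export
read_vtk_mesh <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  nn <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- scan(text = lines[(ip + 1):(ip + nn)], quiet = TRUE)
  nodes <- matrix(pts, nn, 3, byrow = TRUE)
  ic <- grep("^CELLS", lines)[1]
  ne <- as.integer(strsplit(lines[ic], "\\s+")[[1]][2])
  cc <- scan(text = lines[(ic + 1):(ic + ne)], quiet = TRUE)
  cm <- matrix(cc, ne, 9, byrow = TRUE)
  if (any(cm[, 1] != 8)) stop("only hexahedron cells are supported")
  out <- list(nodes = nodes, conn = cm[, -1, drop = FALSE] + 1L)
  for (is in grep("^SCALARS", lines)) {
    nm <- strsplit(lines[is], "\\s+")[[1]][2]
    if (is > ic) {
      vals <- scan(text = lines[(is + 2):(is + 1 + ne)], quiet = TRUE)
      out[[nm]] <- vals
    }
  }
  out
}
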