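#' Export a tet mesh as a legacy VTK unstructured grid
#'
#' ASCII legacy VTK. Region labels and node-set membership are written as
#' cell/point data; optional extra arrays (e.g. displacement, per-element J
#' or energy density) can be attached.
#'
#' @param mesh a `tet_mesh`.
#' @param path output path (conventionally `.vtk`).
#' @param state optional `solver_state`; if given, deformed positions are
#'   written and displacement becomes a point-data array.
#' @param point_data named list of per-node vectors.
#' @param cell_data named list of per-tet vectors.
#' @return the path, invisibly.
#' @export
write_vtk <- function(mesh, path, state = NULL, point_data = list(),
                      cell_data = list()) {
  x <- if (is.null(state)) mesh$nodes else state$x
  n <- nrow(x); m <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("morphofrill tetrahedral mesh")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS ", n, " double")
  utils::write.table(format(x, digits = 10, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  wl("CELLS ", m, " ", m * 5L)
  utils::write.table(cbind(4L, mesh$tets - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  wl("CELL_TYPES ", m)
  writeLines(rep("10", m), con)
  # point data: node-set labels (+ displacement, + extras)
  sets <- mesh$node_sets
  setlab <- integer(n)
  for (i in seq_along(sets)) setlab[sets[[i]]] <- i
  pd <- c(list(node_set = setlab), point_data)
  if (!is.null(state)) {
    d <- state$x - mesh$nodes
    wl("POINT_DATA ", n)
    wl("VECTORS displacement double")
    utils::write.table(format(d, digits = 10, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    wl("POINT_DATA ", n)
  }
  for (nm in names(pd)) {
    wl("SCALARS ", nm, " double 1")
    wl("LOOKUP_TABLE default")
    writeLines(format(pd[[nm]], digits = 10, trim = TRUE), con)
  }
  cd <- c(list(region = as.integer(factor(mesh$region,
                                          levels = c("SKIN", "SUBSTRATE")))),
          cell_data)
  wl("CELL_DATA ", m)
  for (nm in names(cd)) {
    wl("SCALARS ", nm, " double 1")
    wl("LOOKUP_TABLE default")
    writeLines(format(cd[[nm]], digits = 10, trim = TRUE), con)
  }
  invisible(path)
}

#' Export the anterior surface as an ASCII PLY
#'
#' @inheritParams write_vtk
#' @return the path, invisibly.
#' @export
write_ply <- function(mesh, path, state = NULL) {
  x <- if (is.null(state)) mesh$nodes else state$x
  tris <- mesh$surface_tris
  used <- sort(unique(as.vector(tris)))
  remap <- match(tris, used)
  dim(remap) <- dim(tris)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", length(used)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(tris)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(x[used, , drop = FALSE], digits = 10, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, remap - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
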