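# Plain-text I/O: legacy-VTK unstructured meshes (ASCII), YAML run
# configurations, and CSV tables. No binary artifacts are produced.

#' Write a mesh (or surface) as legacy ASCII VTK
#'
#' Writes a tetrahedral volume mesh or a triangulated surface as an
#' unstructured-grid legacy VTK file, with optional point and cell data
#' arrays (scalars or 3-vectors).
#'
#' @param points `N x 3` vertex coordinates, m.
#' @param cells `M x 4` tetrahedra or `M x 3` triangles (1-based).
#' @param file output path.
#' @param point_data named list of per-vertex vectors/matrices.
#' @param cell_data named list of per-cell vectors/matrices.
#' @return the file path, invisibly.
#' @export
write_vtk <- function(points, cells, file, point_data = list(),
                      cell_data = list()) {
  nc <- ncol(cells)
  stopifnot(nc %in% c(3L, 4L))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "lhflow mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", nrow(points)), con)
  writeLines(paste(format(points[, 1], digits = 9),
                   format(points[, 2], digits = 9),
                   format(points[, 3], digits = 9)), con)
  m <- nrow(cells)
  writeLines(sprintf("CELLS %d %d", m, m * (nc + 1L)), con)
  writeLines(do.call(paste, c(list(nc), as.data.frame(cells - 1L))), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(if (nc == 4L) 10L else 5L, m)), con)
  wr_data <- function(data, n, kind) {
    if (length(data) == 0L) return(invisible())
    writeLines(sprintf("%s %d", kind, n), con)
    for (nm in names(data)) {
      v <- data[[nm]]
      if (is.matrix(v) && ncol(v) == 3L) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(paste(format(v[, 1], digits = 9),
                         format(v[, 2], digits = 9),
                         format(v[, 3], digits = 9)), con)
      } else {
        writeLines(sprintf("SCALARS %s double 1", nm), con)
        writeLines("LOOKUP_TABLE default", con)
        writeLines(format(as.numeric(v), digits = 9), con)
      }
    }
  }
  wr_data(point_data, nrow(points), "POINT_DATA")
  wr_data(cell_data, m, "CELL_DATA")
  invisible(file)
}

#' Write / read a run configuration as YAML
#'
#' @param config a named list (scenario parameters, solver settings, seeds).
#' @param file path.
#' @return `write_run_config` the path invisibly; `read_run_config` the list.
#' @export
write_run_config <- function(config, file) {
  drop_classes <- function(x) {
    if (is.list(x)) lapply(unclass(x), drop_classes) else x
  }
  yaml::write_yaml(drop_classes(config), file)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  yaml::read_yaml(file)
}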