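# ---------------------------------------------------------------------------
# VTK legacy ASCII unstructured-grid output of solver snapshots (cell-centred
# fields), plus a minimal reader used by the test suite to validate format
# conformance.
# ---------------------------------------------------------------------------

#' Write a solver snapshot as a legacy VTK unstructured grid
#'
#' @param snapshot solver snapshot (fields `u`, `p`, `k`, `omega`, `nut`,
#'   `nodes`).
#' @param mesh its `lvot_mesh`.
#' @param path output `.vtk` path.
#' @param extra named list of additional per-cell scalar fields.
#' @export
write_vtk_snapshot <- function(snapshot, mesh, path, extra = list()) {
  nodes <- snapshot$nodes
  tris <- mesh$tris
  np <- nrow(nodes); nc <- nrow(tris)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl(sprintf("lvotflow snapshot t=%.6g", snapshot$time))
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", np))
  writeLines(sprintf("%.9g %.9g 0", nodes[, 1], nodes[, 2]), con)
  wl(sprintf("CELLS %d %d", nc, 4L * nc))
  writeLines(sprintf("3 %d %d %d", tris[, 1] - 1L, tris[, 2] - 1L,
                     tris[, 3] - 1L), con)
  wl(sprintf("CELL_TYPES %d", nc))
  writeLines(rep("5", nc), con)             # VTK_TRIANGLE
  wl(sprintf("CELL_DATA %d", nc))
  wl("VECTORS velocity double")
  writeLines(sprintf("%.9g %.9g 0", snapshot$u[, 1], snapshot$u[, 2]), con)
  sc <- c(list(pressure = snapshot$p, k = snapshot$k, omega = snapshot$omega,
               nut = snapshot$nut), extra)
  for (nm in names(sc)) {
    wl(sprintf("SCALARS %s double 1", nm))
    wl("LOOKUP_TABLE default")
    writeLines(sprintf("%.9g", sc[[nm]]), con)
  }
  invisible(path)
}

#' Minimal legacy VTK unstructured-grid reader (validation helper)
#' @param path `.vtk` file written by [write_vtk_snapshot()].
#' @return list with `points`, `cells`, `cell_data` (named list).
#' @export
read_vtk_snapshot <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1]
  np <- as.integer(strsplit(ln[ip], "\\s+")[[1]][2])
  pts <- do.call(rbind, lapply(ln[(ip + 1):(ip + np)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  ic <- grep("^CELLS", ln)[1]
  nc <- as.integer(strsplit(ln[ic], "\\s+")[[1]][2])
  cells <- do.call(rbind, lapply(ln[(ic + 1):(ic + nc)], function(s)
    as.integer(strsplit(trimws(s), "\\s+")[[1]][-1]) + 1L))
  cd <- list()
  iv <- grep("^VECTORS", ln)
  for (i in iv) {
    nm <- strsplit(ln[i], "\\s+")[[1]][2]
    vals <- do.call(rbind, lapply(ln[(i + 1):(i + nc)], function(s)
      as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
    cd[[nm]] <- vals
  }
  isc <- grep("^SCALARS", ln)
  for (i in isc) {
    nm <- strsplit(ln[i], "\\s+")[[1]][2]
    cd[[nm]] <- as.numeric(ln[(i + 2):(i + 1 + nc)])
  }
  list(points = pts, cells = cells, cell_data = cd)
}
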