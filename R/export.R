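# Plain-text exports: ASCII STL and legacy VTK for surfaces and centerlines,
# legacy VTK structured points for volume fields, CSV/JSON for metrics, and
# a YAML round-trip for anatomy configurations.

#' Write a tube surface as ASCII STL
#'
#' @param surface a [centerline_to_surface()] result
#' @param path output file
#' @param patches patch subset to write (default: all)
#' @export
write_stl <- function(surface, path, patches = NULL) {
  sel <- if (is.null(patches)) seq_len(nrow(surface$triangles))
         else which(surface$patch %in% patches)
  v <- surface$vertices
  tr <- surface$triangles[sel, , drop = FALSE]
  nrm <- -surface$normal_in[sel, , drop = FALSE]   # outward facet normals
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid pvshemo", con)
  p1 <- v[tr[, 1], , drop = FALSE]
  p2 <- v[tr[, 2], , drop = FALSE]
  p3 <- v[tr[, 3], , drop = FALSE]
  txt <- sprintf(
    "facet normal %g %g %g\n outer loop\n  vertex %g %g %g\n  vertex %g %g %g\n  vertex %g %g %g\n endloop\nendfacet",
    nrm[, 1], nrm[, 2], nrm[, 3],
    p1[, 1], p1[, 2], p1[, 3], p2[, 1], p2[, 2], p2[, 3], p3[, 1], p3[, 2], p3[, 3])
  writeLines(txt, con)
  writeLines("endsolid pvshemo", con)
  invisible(path)
}

# integer patch codes with a JSON legend alongside
patch_codes <- function(patch) {
  lv <- sort(unique(patch))
  list(code = match(patch, lv), legend = stats::setNames(seq_along(lv), lv))
}

#' Write a tube surface as legacy VTK polydata
#'
#' Includes per-face patch and vessel codes (integer cell data) plus a JSON
#' legend file `<path>.legend.json`.
#'
#' @inheritParams write_stl
#' @param cell_data optional named list of numeric per-face vectors (e.g.
#'   WSS) written as additional cell data arrays
#' @export
write_vtk_surface <- function(surface, path, cell_data = list()) {
  v <- surface$vertices
  tr <- surface$triangles - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "pvshemo surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nrow(v))), con)
  writeLines(sprintf("%g %g %g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(tr), 4 * nrow(tr)), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
  pc <- patch_codes(surface$patch)
  vc <- patch_codes(surface$vessel)
  writeLines(sprintf("CELL_DATA %d", nrow(tr)), con)
  writeLines(c("SCALARS patch int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", pc$code), con)
  writeLines(c("SCALARS vessel int 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%d", vc$code), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%g", cell_data[[nm]]), con)
  }
  jsonlite::write_json(list(patch = as.list(pc$legend),
                            vessel = as.list(vc$legend)),
                       paste0(path, ".legend.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write centerlines as legacy VTK polylines
#'
#' @param model a [build_centerlines()] result
#' @param path output file
#' @export
write_vtk_centerlines <- function(model, path) {
  pts <- do.call(rbind, lapply(model$vessels, function(v) v$points))
  counts <- vapply(model$vessels, function(v) nrow(v$points), 0L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "pvshemo centerlines", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", nrow(pts))), con)
  writeLines(sprintf("%g %g %g", pts[, 1], pts[, 2], pts[, 3]), con)
  writeLines(sprintf("LINES %d %d", length(counts),
                     sum(counts) + length(counts)), con)
  ofs <- c(0, cumsum(counts))
  for (i in seq_along(counts))
    writeLines(paste(c(counts[i], seq(ofs[i], ofs[i + 1] - 1)), collapse = " "), con)
  invisible(path)
}

#' Write a flow solution as legacy VTK structured points
#'
#' Cell-centred velocity magnitude, pressure, shear rate and viscosity on
#' the Cartesian grid (solid cells carry zeros), for visualization.
#'
#' @param solution a [solve_steady_flow()] result
#' @param mesh the matching [generate_mesh()]
#' @param path output file
#' @export
write_vtk_solution <- function(solution, mesh, path) {
  g <- solution$grid
  nx <- g$dims[1]; ny <- g$dims[2]; nz <- g$dims[3]
  cv <- cell_velocities(solution)
  speed <- sqrt(cv$u^2 + cv$v^2 + cv$w^2)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "pvshemo solution", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", nx, ny, nz),
               sprintf("ORIGIN %g %g %g",
                       g$origin[1] + g$h / 2, g$origin[2] + g$h / 2,
                       g$origin[3] + g$h / 2),
               sprintf("SPACING %g %g %g", g$h, g$h, g$h),
               sprintf("POINT_DATA %d", nx * ny * nz)), con)
  wr <- function(name, vals) {
    writeLines(c(sprintf("SCALARS %s float 1", name), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%g", vals), con)
  }
  wr("speed", speed)
  wr("pressure", solution$fields$p + solution$outlet_pressure)
  wr("shear_rate", solution$fields$shear_rate)
  wr("viscosity", solution$fields$viscosity)
  wr("mask", as.numeric(mesh$cell_class != 0))
  invisible(path)
}

#' Write a metrics report as JSON and/or a CSV row
#'
#' @param report a [metrics_report()]
#' @param json,csv output paths (either may be `NULL`)
#' @export
write_metrics <- function(report, json = NULL, csv = NULL) {
  if (!is.null(json)) {
    obj <- report
    class(obj) <- NULL
    obj$per_vessel <- NULL
    obj$field <- NULL
    obj$solution <- NULL
    jsonlite::write_json(obj, json, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  if (!is.null(csv)) {
    sc <- report$scenario
    row <- data.frame(
      type = if (!is.null(sc)) sc$anatomy_type else NA,
      variations = if (!is.null(sc)) paste(sc$variations, collapse = ",") else "",
      condition = if (!is.null(sc)) sc$condition else "",
      method = report$method,
      sa_wss = report$sa_wss, als = report$als,
      M = report$M, N = report$N, max_viscosity = report$max_mu_nw)
    utils::write.csv(row, csv, row.names = FALSE)
  }
  invisible(report)
}

#' Write / read an anatomy configuration as YAML
#'
#' @param config an [build_anatomy()] configuration
#' @param path file path
#' @export
write_anatomy_yaml <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for YAML export")
  obj <- unclass(config)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_anatomy_yaml
#' @export
read_anatomy_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for YAML import")
  obj <- yaml::read_yaml(path)
  cfg <- build_anatomy(obj$anatomy_type, obj$variations %||% character(),
                       obj$condition)
  for (nm in intersect(names(obj), names(cfg)))
    cfg[[nm]] <- obj[[nm]]
  class(cfg) <- "anatomy_config"
  validate_anatomy(cfg)
  cfg
}
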