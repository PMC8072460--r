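# Triangulated tube surfaces for the vessel tree. Each vessel is swept as a
# ring strip along its (resampled) centerline; flat port disks are fanned at
# real ports. At junctions, triangles whose centroid lies inside another
# vessel are removed, leaving the boolean-union shell that the signed-distance
# field also describes. Per-face areas and patch labels feed the wall-shear
# statistics (Eq. area weights), so areas here come from the true tessellated
# surface, not from the volume grid.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# resample a polyline at approximately even arc-length steps
resample_polyline <- function(pts, step) {
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  ns <- max(2L, ceiling(L / step))
  st <- seq(0, L, length.out = ns + 1)
  cbind(approx(s, pts[, 1], xout = st)$y,
        approx(s, pts[, 2], xout = st)$y,
        approx(s, pts[, 3], xout = st)$y)
}

#' Triangulate the tube surface of a centerline model
#'
#' Sweeps a circular cross-section of each vessel's diameter along its
#' centerline, caps real ports with flat disks, and removes triangles interior
#' to other vessels so that the union shell of the vessel tree remains. Every
#' triangle carries its patch label (`"wall"`, an inlet/outlet port name, or
#' the postoperative `"sv_cap"`), its vessel of origin, its area and its
#' inward normal.
#'
#' @param model a [build_centerlines()] result
#' @param n_theta number of circumferential vertices per ring
#' @param ring_step axial ring spacing (mm)
#' @return An object of class `tube_surface` with fields `vertices` (mm),
#'   `triangles` (vertex indices), `patch`, `vessel`, `area` (mm^2),
#'   `normal_in` (unit inward normals) and the source `model`.
#' @export
centerline_to_surface <- function(model, n_theta = 28, ring_step = 1.25) {
  stopifnot(inherits(model, "centerline_model"), n_theta >= 8, ring_step > 0)
  geom <- geom_from_model(model)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  verts <- list(); tris <- list(); patch <- list(); vessel <- list()
  nv <- 0L
  for (v in model$vessels) {
    r <- v$diameter / 2
    pts <- resample_polyline(v$points, ring_step)
    ns <- nrow(pts)
    # tangents by central differences; planar geometry: frame from z axis
    tg <- rbind(pts[2, ] - pts[1, ],
                pts[-(1:2), , drop = FALSE] - pts[seq_len(ns - 2), , drop = FALSE],
                pts[ns, ] - pts[ns - 1, ])
    tg <- tg / sqrt(rowSums(tg^2))
    ring_v <- matrix(0, ns * n_theta, 3)
    for (i in seq_len(ns)) {
      t1 <- tg[i, ]
      n1 <- cross3(c(0, 0, 1), t1)
      nn <- sqrt(sum(n1^2))
      if (nn < 1e-9) n1 <- c(1, 0, 0) else n1 <- n1 / nn
      n2 <- cross3(t1, n1)
      ring_v[(i - 1) * n_theta + seq_len(n_theta), ] <-
        rep(pts[i, ], each = n_theta) +
        r * (outer(cos(th), n1) + outer(sin(th), n2))
    }
    # lateral strip triangles
    i0 <- rep(seq_len(ns - 1), each = n_theta)
    j0 <- rep(seq_len(n_theta), ns - 1)
    j1 <- j0 %% n_theta + 1
    a <- (i0 - 1) * n_theta + j0
    b <- (i0 - 1) * n_theta + j1
    cc <- i0 * n_theta + j0
    d <- i0 * n_theta + j1
    lat <- rbind(cbind(a, b, cc), cbind(b, d, cc))
    ring_base <- nv                       # vertex offset of this vessel's rings
    verts[[length(verts) + 1]] <- ring_v
    tris[[length(tris) + 1]] <- lat + ring_base
    patch[[length(patch) + 1]] <- rep("wall", nrow(lat))
    vessel[[length(vessel) + 1]] <- rep(v$name, nrow(lat))
    nv <- nv + nrow(ring_v)
    # port caps as fans around the port centre
    caps <- list(list(port = v$port_start, ring = seq_len(n_theta), ctr = pts[1, ]),
                 list(port = v$port_end,
                      ring = (ns - 1) * n_theta + seq_len(n_theta), ctr = pts[ns, ]))
    for (cp in caps) {
      if (is.null(cp$port)) next
      verts[[length(verts) + 1]] <- matrix(cp$ctr, 1, 3)
      ctr_id <- nv + 1L
      ring_ids <- cp$ring + ring_base
      fan <- cbind(ring_ids, c(ring_ids[-1], ring_ids[1]), ctr_id)
      tris[[length(tris) + 1]] <- fan
      patch[[length(patch) + 1]] <- rep(cp$port$label, nrow(fan))
      vessel[[length(vessel) + 1]] <- rep(v$name, nrow(fan))
      nv <- nv + 1L
    }
  }
  vertices <- do.call(rbind, verts)
  triangles <- do.call(rbind, tris)
  patch <- unlist(patch)
  vessel <- unlist(vessel)

  p1 <- vertices[triangles[, 1], , drop = FALSE]
  p2 <- vertices[triangles[, 2], , drop = FALSE]
  p3 <- vertices[triangles[, 3], , drop = FALSE]
  cen <- (p1 + p2 + p3) / 3
  e1 <- p2 - p1; e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- 0.5 * sqrt(rowSums(cr^2))

  # clip triangles interior to other vessels (junction union)
  vnames <- vapply(model$vessels, function(x) x$name, "")
  keep <- rep(TRUE, nrow(triangles))
  if (length(geom) > 1) {
    for (vi in seq_along(geom)) {
      sel <- which(vessel == vnames[vi])
      if (!length(sel)) next
      d_other <- cpp_sdf(geom[-vi], cen[sel, , drop = FALSE] / 1000)
      keep[sel][d_other < -1e-6] <- FALSE
    }
  }

  # inward normals: lateral triangles point to the local centerline, caps
  # point into the vessel along the port axis
  normal_in <- matrix(0, nrow(triangles), 3)
  for (vi in seq_along(model$vessels)) {
    v <- model$vessels[[vi]]
    sel <- which(vessel == v$name)
    if (!length(sel)) next
    is_cap <- patch[sel] != "wall"
    lat_sel <- sel[!is_cap]
    if (length(lat_sel)) {
      pts <- v$points
      # nearest centerline sample for each centroid
      rs <- resample_polyline(pts, 0.75)
      nn <- apply(cen[lat_sel, , drop = FALSE], 1, function(p) {
        which.min(colSums((t(rs) - p)^2))
      })
      dirv <- rs[nn, , drop = FALSE] - cen[lat_sel, , drop = FALSE]
      dirv <- dirv / pmax(sqrt(rowSums(dirv^2)), 1e-12)
      normal_in[lat_sel, ] <- dirv
    }
    cap_sel <- sel[is_cap]
    if (length(cap_sel)) {
      for (cp in list(v$port_start, v$port_end)) {
        if (is.null(cp)) next
        csel <- cap_sel[patch[cap_sel] == cp$label]
        if (!length(csel)) next
        n <- nrow(v$points)
        if (identical(cp$label, v$port_start$label %||% "")) {
          ax <- v$points[2, ] - v$points[1, ]
        } else {
          ax <- v$points[n - 1, ] - v$points[n, ]
        }
        ax <- ax / sqrt(sum(ax^2))
        normal_in[csel, ] <- matrix(ax, length(csel), 3, byrow = TRUE)
      }
    }
  }

  structure(list(
    vertices = vertices,
    triangles = triangles[keep, , drop = FALSE],
    patch = patch[keep],
    vessel = vessel[keep],
    area = area[keep],
    centroid = cen[keep, , drop = FALSE],
    normal_in = normal_in[keep, , drop = FALSE],
    n_theta = n_theta, ring_step = ring_step,
    model = model, geom = geom
  ), class = "tube_surface")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tube_surface <- function(x, ...) {
  cat(sprintf("tube surface: %d vertices, %d triangles, area %.1f mm^2\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$area)))
  cat("  patches:", paste(sort(unique(x$patch)), collapse = ", "), "\n")
  invisible(x)
}

#' Total surface area by patch
#'
#' @param surface a [centerline_to_surface()] result
#' @param patches patch labels to include; default all
#' @return area in mm^2
#' @export
surface_area <- function(surface, patches = NULL) {
  sel <- if (is.null(patches)) TRUE else surface$patch %in% patches
  sum(surface$area[sel])
}

# wall selector: lateral walls plus ligated caps; open ports excluded
wall_faces <- function(patch) patch == "wall" | grepl("_cap$", patch)

#' Check that a surface is a closed 2-manifold
#'
#' Verifies that every edge is shared by exactly two triangles. Single-vessel
#' tubes are exactly watertight; junction models are union shells whose seams
#' are tessellation-scale, so this check is meaningful for single tubes and
#' reported (not asserted) for junction models.
#'
#' @param surface a `tube_surface`
#' @export
surface_is_watertight <- function(surface) {
  tr <- surface$triangles
  ed <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  all(table(key) == 2)
}

#' Integral of the outward area vector over the surface
#'
#' For a closed surface this integral vanishes; its residual is a watertight-
#' ness diagnostic in mm^2.
#' @param surface a `tube_surface`
#' @export
surface_closure_defect <- function(surface) {
  p1 <- surface$vertices[surface$triangles[, 1], , drop = FALSE]
  p2 <- surface$vertices[surface$triangles[, 2], , drop = FALSE]
  p3 <- surface$vertices[surface$triangles[, 3], , drop = FALSE]
  e1 <- p2 - p1; e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
  # orient by the inward normal so all triangles count outward consistently
  sgn <- sign(rowSums(cr * surface$normal_in))
  sqrt(sum(colSums(-sgn * cr)^2))
}
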