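# Parametric idealized geometry of the portal venous system (PVS).
#
# The vessel tree is built in a single construction plane (z = 0): the
# splenoportal junction sits at the origin, the splenic vein (SV) runs along
# +x toward the spleen, and the portal vein (PV) and superior mesenteric vein
# (SMV) leave the junction at the configured angles. The left gastric vein
# (LGV) and inferior mesenteric vein (IMV) attach to hosts determined by the
# anatomy type. All lengths are millimetres, all angles degrees.

#' Literature table of vessel diameters and lengths
#'
#' Population-averaged diameters and lengths of the five PVS vessels as
#' collected from published clinical studies, together with their arithmetic
#' means, which parameterize the baseline geometry.
#'
#' @return A data frame with one row per vessel: literature values (mm, as
#'   comma-separated strings), and the derived mean diameter and length (mm).
#' @export
pvs_vessel_table <- function() {
  lit <- list(
    PV  = list(d = c(12.9, 13.3, 13.9, 12.9, 14.1), len = c(70, 73.4)),
    SV  = list(d = c(9.3, 10.2, 10.3, 10.0, 10.8),  len = c(122, 105)),
    SMV = list(d = c(12.3, 14.5, 8.6, 12.1),        len = c(60.8)),
    LGV = list(d = c(6.0),                          len = c(50)),
    IMV = list(d = c(4.1),                          len = c(59.7))
  )
  data.frame(
    vessel = names(lit),
    diameters_lit = vapply(lit, function(x) paste(x$d, collapse = ", "), ""),
    diameter = vapply(lit, function(x) mean_of_literature(x$d), 0),
    lengths_lit = vapply(lit, function(x) paste(x$len, collapse = ", "), ""),
    length = vapply(lit, function(x) mean_of_literature(x$len), 0),
    row.names = NULL
  )
}

# reported SV diameter standard deviations; their mean sets the magnitude of
# the 'C' (SV diameter) variation
.sv_diameter_sds <- c(2.2, 2.8, 3.2, 2.3)

#' Mean of literature-reported values
#'
#' Baseline geometric parameters are assigned as arithmetic means of values
#' reported across clinical studies.
#'
#' @param values numeric vector of positive lengths (mm)
#' @return the arithmetic mean (mm)
#' @export
mean_of_literature <- function(values) {
  if (length(values) == 0) stop("no literature values supplied")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("literature values must be positive and finite")
  mean(values)
}

#' Variation magnitude of the SV-diameter ('C') feature
#'
#' The 'C' variation changes the SV diameter by the mean of the standard
#' deviations reported for the SV diameter in the literature (2.625 mm).
#' @export
sv_diameter_variation <- function() mean_of_literature(.sv_diameter_sds)

.variation_tags <- c("A-", "A+", "B-", "B+", "C-", "C+", "D-", "D+", "curved")

#' Build an anatomy configuration
#'
#' Assembles the full parametric description of one PVS model: the anatomy
#' type (tributary connection pattern), optional morphogeometrical variation
#' tags, and the pre-/post-splenectomy condition. Each variation tag modifies
#' exactly one scalar relative to the baseline:
#'
#' * `A-`/`A+`: angle between the IMV and its trunk vein, 70 deg +/- 20 deg
#' * `B-`/`B+`: angle between the PV and SV, 113 deg +/- 10 deg
#' * `C-`/`C+`: SV diameter, 10.12 mm +/- 2.625 mm
#' * `D-`/`D+`: IMV distance from the splenoportal junction, 60 mm +/- 20 mm
#' * `curved`: replace the straight mid-SV segment between the LGV and IMV by
#'   an S-shaped curve (requires `D+`, which makes that segment 50 mm long)
#'
#' Anatomy types map tributaries to hosts: type 1 IMV->SV, LGV->SV; type 2
#' IMV->SV, LGV->PV; type 3 IMV->SMV, LGV->SV; type 4 IMV->SMV, LGV->PV.
#'
#' @param anatomy_type integer 1--4
#' @param variations character vector of tags from
#'   `c("A-","A+","B-","B+","C-","C+","D-","D+","curved")`
#' @param condition `"preoperative"` (SV inlet open) or `"postoperative"`
#'   (SV proximal end ligated: a flat no-slip cap)
#' @param allow_free_curvature allow `"curved"` without `D+` (the curved
#'   construction still requires a 50 mm mid-SV segment)
#' @return An object of class `anatomy_config`.
#' @examples
#' cfg <- build_anatomy(1, c("C+"), "postoperative")
#' cfg$vessels$SV$diameter  # 12.745
#' @export
build_anatomy <- function(anatomy_type = 1, variations = character(),
                          condition = c("preoperative", "postoperative"),
                          allow_free_curvature = FALSE) {
  condition <- match.arg(condition)
  if (!anatomy_type %in% 1:4) stop("anatomy_type must be 1, 2, 3 or 4")
  bad <- setdiff(variations, .variation_tags)
  if (length(bad)) stop("unknown variation tag(s): ", paste(bad, collapse = ", "))
  letters_used <- sub("[-+]$", "", setdiff(variations, "curved"))
  if (anyDuplicated(letters_used))
    stop("conflicting variation tags: at most one of '-'/'+' per feature")
  if ("curved" %in% variations && !"D+" %in% variations && !allow_free_curvature)
    stop("'curved' is defined on top of the 'D+' variation ",
         "(set allow_free_curvature = TRUE to override)")

  tab <- pvs_vessel_table()
  vessels <- stats::setNames(lapply(seq_len(nrow(tab)), function(i) {
    list(name = tab$vessel[i], diameter = tab$diameter[i], length = tab$length[i])
  }), tab$vessel)

  cfg <- list(
    anatomy_type = as.integer(anatomy_type),
    vessels = vessels,
    angle_PV_vertical = 29,
    angle_PV_SV = 113,
    angle_SV_SMV = 96,
    angle_IMV_trunk = 70,
    angle_LGV_trunk = 70,
    dist_IMV_junction = 60,
    dist_LGV_junction = 30,
    dist_LGV_on_PV = 35,
    dist_IMV_on_SMV = 25,
    sv_curved = FALSE,
    condition = condition,
    variations = variations,
    hosts = list(
      IMV = if (anatomy_type %in% c(1, 2)) "SV" else "SMV",
      LGV = if (anatomy_type %in% c(1, 3)) "SV" else "PV"
    ),
    curve_step = 0.5
  )
  dC <- sv_diameter_variation()
  for (tag in variations) {
    switch(tag,
      "A-" = { cfg$angle_IMV_trunk <- cfg$angle_IMV_trunk - 20 },
      "A+" = { cfg$angle_IMV_trunk <- cfg$angle_IMV_trunk + 20 },
      "B-" = { cfg$angle_PV_SV <- cfg$angle_PV_SV - 10 },
      "B+" = { cfg$angle_PV_SV <- cfg$angle_PV_SV + 10 },
      "C-" = { cfg$vessels$SV$diameter <- cfg$vessels$SV$diameter - dC },
      "C+" = { cfg$vessels$SV$diameter <- cfg$vessels$SV$diameter + dC },
      "D-" = { cfg$dist_IMV_junction <- cfg$dist_IMV_junction - 20 },
      "D+" = { cfg$dist_IMV_junction <- cfg$dist_IMV_junction + 20 },
      "curved" = { cfg$sv_curved <- TRUE }
    )
  }
  class(cfg) <- "anatomy_config"
  validate_anatomy(cfg)
  cfg
}

validate_anatomy <- function(cfg) {
  for (v in cfg$vessels)
    if (v$diameter <= 0 || v$length <= 0)
      stop("vessel ", v$name, " must have positive diameter and length")
  if (cfg$hosts$IMV == "SV" &&
      (cfg$dist_IMV_junction <= 0 || cfg$dist_IMV_junction >= cfg$vessels$SV$length))
    stop("IMV junction lies outside the SV")
  if (cfg$hosts$LGV == "SV" &&
      (cfg$dist_LGV_junction <= 0 || cfg$dist_LGV_junction >= cfg$vessels$SV$length))
    stop("LGV junction lies outside the SV")
  if (cfg$hosts$LGV == "PV" &&
      (cfg$dist_LGV_on_PV <= 0 || cfg$dist_LGV_on_PV >= cfg$vessels$PV$length))
    stop("LGV junction lies outside the PV")
  if (cfg$hosts$IMV == "SMV" &&
      (cfg$dist_IMV_on_SMV <= 0 || cfg$dist_IMV_on_SMV >= cfg$vessels$SMV$length))
    stop("IMV junction lies outside the SMV")
  invisible(cfg)
}

#' @export
print.anatomy_config <- function(x, ...) {
  cat(sprintf("PVS anatomy: type %d, %s%s\n", x$anatomy_type, x$condition,
              if (length(x$variations)) paste0(" [", paste(x$variations, collapse = ","), "]") else ""))
  cat(sprintf("  hosts: IMV->%s, LGV->%s; SV %s\n", x$hosts$IMV, x$hosts$LGV,
              if (x$sv_curved) "curved" else "straight"))
  invisible(x)
}

unit2 <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180), 0)

# S-shaped replacement for the straight mid-SV segment: two straight lines
# (10 mm) and three tangential arcs (two quadrants r = 10 mm, one semicircle
# r = 15 mm), bulging toward -y. Starts at (x0, 0, 0) heading +x, ends at
# (x0 + 50, 0, 0) heading +x.
curved_midsv_points <- function(x0, step = 0.5) {
  pts <- list()
  arc <- function(center, r, a0, a1) {
    n <- max(2L, ceiling(abs(a1 - a0) * r / step))
    a <- seq(a0, a1, length.out = n + 1)
    cbind(center[1] + r * cos(a), center[2] + r * sin(a), 0)
  }
  p1 <- arc(c(x0, -10), 10, pi / 2, 0)                  # quadrant down
  p2 <- rbind(c(x0 + 10, -10, 0), c(x0 + 10, -20, 0))   # straight 10 mm
  p3 <- arc(c(x0 + 25, -20), 15, pi, 2 * pi)            # semicircle
  p4 <- rbind(c(x0 + 40, -20, 0), c(x0 + 40, -10, 0))   # straight 10 mm
  p5 <- arc(c(x0 + 50, -10), 10, pi, pi / 2)            # quadrant up
  out <- rbind(p1, p2[-1, , drop = FALSE], p3[-1, , drop = FALSE],
               p4[-1, , drop = FALSE], p5[-1, , drop = FALSE])
  out
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

#' Distance factor of a centerline curve
#'
#' Curvature measure of a centerline segment: the ratio of its arc length L to
#' the straight-line distance D between its two terminals. Straight segments
#' have DF = 1; any curvature gives DF > 1.
#'
#' @param curve an n x 3 matrix of centerline points (mm), n >= 2
#' @return list with `L`, `D` (mm) and `DF = L / D`
#' @export
distance_factor <- function(curve) {
  curve <- as.matrix(curve)
  if (nrow(curve) < 2) stop("curve needs at least two points")
  L <- polyline_length(curve)
  D <- sqrt(sum((curve[nrow(curve), ] - curve[1, ])^2))
  if (D < 1e-9) stop("coincident terminals: distance factor undefined")
  list(L = L, D = D, DF = L / D)
}

#' Build the centerline model for an anatomy configuration
#'
#' Lays out the five vessels in the construction plane: SV along +x from the
#' splenoportal junction (origin), PV and SMV leaving the junction at the
#' configured angles, and LGV/IMV attached to their type-determined hosts at
#' the configured distances and angles. Tributary centerlines terminate on the
#' host axis so that the tube union blends the junction. The 29 deg tilt of
#' the PV against the vertical plane is kept as orientation metadata only (the
#' geometry is planar; gravity is not modelled).
#'
#' @param config an [build_anatomy()] configuration
#' @return An object of class `centerline_model`: per-vessel centerline point
#'   matrices (mm) with diameters, port annotations and junction locations.
#' @export
build_centerlines <- function(config) {
  stopifnot(inherits(config, "anatomy_config"))
  validate_anatomy(config)
  v <- config$vessels
  th_pv <- config$angle_PV_SV          # PV ray angle from +x (SV ray)
  th_smv <- -config$angle_SV_SMV       # SMV ray angle from +x
  u_pv <- unit2(th_pv)
  u_smv <- unit2(th_smv)

  # trunk centerlines; inlet vessels run port -> junction, PV junction -> port
  sv_pts <- rbind(c(v$SV$length, 0, 0), c(0, 0, 0))
  pv_pts <- rbind(c(0, 0, 0), v$PV$length * u_pv)
  smv_pts <- rbind(v$SMV$length * u_smv, c(0, 0, 0))

  junctions <- list()
  add_junction <- function(trib, host, s_host, attach, angle_from_upstream) {
    junctions[[trib]] <<- list(tributary = trib, host = host, s = s_host,
                               point = attach, angle = angle_from_upstream)
  }

  # tributary ray: rotate the host-upstream direction by the junction angle,
  # choosing the side that keeps each tributary clear of the other vessels
  if (config$hosts$IMV == "SV") {
    attach <- c(config$dist_IMV_junction, 0, 0)
    ray <- unit2(-config$angle_IMV_trunk)           # below the SV
    add_junction("IMV", "SV", config$dist_IMV_junction, attach, config$angle_IMV_trunk)
  } else {
    attach <- config$dist_IMV_on_SMV * u_smv
    ray <- unit2(th_smv + config$angle_IMV_trunk)   # east side of the SMV
    add_junction("IMV", "SMV", config$dist_IMV_on_SMV, attach, config$angle_IMV_trunk)
  }
  imv_pts <- rbind(attach + v$IMV$length * ray, attach)

  if (config$hosts$LGV == "SV") {
    attach <- c(config$dist_LGV_junction, 0, 0)
    ray <- unit2(config$angle_LGV_trunk)            # above the SV
    add_junction("LGV", "SV", config$dist_LGV_junction, attach, config$angle_LGV_trunk)
  } else {
    attach <- config$dist_LGV_on_PV * u_pv
    # host-upstream direction along the PV points back to the junction
    ray <- unit2(th_pv + 180 + config$angle_LGV_trunk)
    add_junction("LGV", "PV", config$dist_LGV_on_PV, attach, config$angle_LGV_trunk)
  }
  lgv_pts <- rbind(attach + v$LGV$length * ray, attach)

  if (config$sv_curved) {
    if (config$hosts$IMV != "SV" || config$hosts$LGV != "SV")
      stop("curved mid-SV requires both LGV and IMV on the SV")
    mid_len <- config$dist_IMV_junction - config$dist_LGV_junction
    if (abs(mid_len - 50) > 1e-9)
      stop("curved mid-SV construction requires a 50 mm LGV-IMV segment ",
           sprintf("(got %.3f mm)", mid_len))
    curve <- curved_midsv_points(config$dist_LGV_junction, config$curve_step)
    # SV runs inlet (x = L) -> junction (x = 0); insert the curve reversed
    sv_pts <- rbind(
      c(v$SV$length, 0, 0),
      curve[rev(seq_len(nrow(curve))), , drop = FALSE],
      c(0, 0, 0)
    )
  }

  sv_port_kind <- if (config$condition == "preoperative") "inlet" else "cap"
  vessels <- list(
    SV = list(name = "SV", diameter = v$SV$diameter, points = sv_pts,
              port_start = list(label = if (sv_port_kind == "inlet") "sv_inlet" else "sv_cap",
                                kind = sv_port_kind),
              port_end = NULL),
    SMV = list(name = "SMV", diameter = v$SMV$diameter, points = smv_pts,
               port_start = list(label = "smv_inlet", kind = "inlet"),
               port_end = NULL),
    LGV = list(name = "LGV", diameter = v$LGV$diameter, points = lgv_pts,
               port_start = list(label = "lgv_inlet", kind = "inlet"),
               port_end = NULL),
    IMV = list(name = "IMV", diameter = v$IMV$diameter, points = imv_pts,
               port_start = list(label = "imv_inlet", kind = "inlet"),
               port_end = NULL),
    PV = list(name = "PV", diameter = v$PV$diameter, points = pv_pts,
              port_start = NULL,
              port_end = list(label = "pv_outlet", kind = "outlet"))
  )
  for (nm in names(vessels)) {
    vessels[[nm]]$arc_length <- polyline_length(vessels[[nm]]$points)
  }
  structure(list(vessels = vessels, junctions = junctions, config = config),
            class = "centerline_model")
}

#' Build the centerline model with the curved mid-SV segment
#'
#' Convenience wrapper that enforces the curved-SV construction: the straight
#' 50 mm mid-SV segment between the LGV and IMV junctions is replaced by an
#' in-plane S-curve of two 10 mm straights and three tangential arcs (two
#' quadrants of radius 10 mm and one semicircle of radius 15 mm), with end
#' tangents collinear with the original SV axis.
#'
#' @param config an [build_anatomy()] configuration containing the `D+`
#'   variation (or any layout with a 50 mm LGV-IMV mid segment)
#' @export
build_curved_sv <- function(config) {
  stopifnot(inherits(config, "anatomy_config"))
  config$sv_curved <- TRUE
  build_centerlines(config)
}

#' Single straight tube geometry
#'
#' A one-vessel centerline model (straight tube along +x with an inlet at
#' x = 0 and an outlet at x = `length`), used for analytic solver validation
#' against Poiseuille flow.
#'
#' @param diameter tube diameter (mm)
#' @param length tube length (mm)
#' @export
tube_geometry <- function(diameter = 10, length = 100) {
  stopifnot(diameter > 0, length > 0)
  vessels <- list(
    TUBE = list(name = "TUBE", diameter = diameter,
                points = rbind(c(0, 0, 0), c(length, 0, 0)),
                port_start = list(label = "inlet", kind = "inlet"),
                port_end = list(label = "outlet", kind = "outlet"),
                arc_length = length)
  )
  structure(list(vessels = vessels, junctions = list(), config = NULL),
            class = "centerline_model")
}

#' @export
print.centerline_model <- function(x, ...) {
  cat("PVS centerline model:\n")
  for (v in x$vessels)
    cat(sprintf("  %-4s d = %6.3f mm, L = %7.2f mm (%d pts)\n",
                v$name, v$diameter, v$arc_length, nrow(v$points)))
  invisible(x)
}

# geometry list for the C++ kernels, in metres
geom_from_model <- function(model) {
  lapply(unname(model$vessels), function(v) {
    pts <- v$points / 1000
    n <- nrow(pts)
    t0 <- pts[1, ] - pts[2, ]
    t0 <- t0 / sqrt(sum(t0^2))          # outward at start
    t1 <- pts[n, ] - pts[n - 1, ]
    t1 <- t1 / sqrt(sum(t1^2))          # outward at end
    list(pts = pts, r = v$diameter / 2000,
         cap0 = !is.null(v$port_start), cap1 = !is.null(v$port_end),
         n0 = t0, n1 = t1)
  })
}

# port table (SI units) for meshing / boundary conditions
ports_from_model <- function(model) {
  out <- list()
  vi <- 0
  for (v in model$vessels) {
    vi <- vi + 1
    n <- nrow(v$points)
    if (!is.null(v$port_start)) {
      t0 <- v$points[1, ] - v$points[2, ]
      t0 <- t0 / sqrt(sum(t0^2))
      out[[length(out) + 1]] <- list(
        label = v$port_start$label, kind = v$port_start$kind, vessel = v$name,
        vessel_index = vi, center = v$points[1, ] / 1000, normal = t0,
        radius = v$diameter / 2000)
    }
    if (!is.null(v$port_end)) {
      t1 <- v$points[n, ] - v$points[n - 1, ]
      t1 <- t1 / sqrt(sum(t1^2))
      out[[length(out) + 1]] <- list(
        label = v$port_end$label, kind = v$port_end$kind, vessel = v$name,
        vessel_index = vi, center = v$points[n, ] / 1000, normal = t1,
        radius = v$diameter / 2000)
    }
  }
  out
}
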