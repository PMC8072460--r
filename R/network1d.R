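# Reduced-order Poiseuille network model of the vessel tree. Because the
# tree has a single outlet, segment flows follow from mass conservation
# alone (junction pressure losses never enter); each segment's wall shear
# uses fully developed pipe-flow relations with the Carreau viscosity. The
# network model serves as a fast screening tool and as an independent
# cross-check on the 3D pipeline's scenario trends.

#' Build the segment graph of an anatomy
#'
#' Splits every vessel at its junctions and assigns volumetric flows by
#' Kirchhoff conservation from the inlet flows (velocity times cross-section
#' area). Postoperatively the SV inlet carries no flow, so the SV segments
#' upstream of the first perfused junction become a dead-end stump with
#' exactly zero flow.
#'
#' @param config an [build_anatomy()] configuration
#' @param flow_scale multiplier on all inlet flows
#' @param velocities named inlet mean velocities (m/s), as in
#'   [build_boundary_conditions()]
#' @return object of class `segment_graph`: data frame of directed segments
#'   (vessel, s0/s1 positions from the splenoportal junction in mm, length
#'   mm, diameter mm, lateral area mm^2, flow m^3/s)
#' @export
network_from_anatomy <- function(config, flow_scale = 1,
                                 velocities = c(SV = 0.0889, SMV = 0.0502,
                                                LGV = 0.078, IMV = 0.08)) {
  stopifnot(inherits(config, "anatomy_config"))
  v <- config$vessels
  area_m2 <- function(d_mm) pi * (d_mm / 1000)^2 / 4
  qin <- c(SV = if (config$condition == "preoperative")
                  velocities[["SV"]] * area_m2(v$SV$diameter) else 0,
           SMV = velocities[["SMV"]] * area_m2(v$SMV$diameter),
           LGV = velocities[["LGV"]] * area_m2(v$LGV$diameter),
           IMV = velocities[["IMV"]] * area_m2(v$IMV$diameter)) * flow_scale

  # tributary attachment positions along each trunk (mm from the junction)
  att <- list(SV = numeric(0), SMV = numeric(0), PV = numeric(0))
  trib_at <- list()
  if (config$hosts$IMV == "SV") {
    att$SV <- c(att$SV, config$dist_IMV_junction)
    trib_at[[paste0("SV@", config$dist_IMV_junction)]] <- "IMV"
  } else {
    att$SMV <- c(att$SMV, config$dist_IMV_on_SMV)
    trib_at[[paste0("SMV@", config$dist_IMV_on_SMV)]] <- "IMV"
  }
  if (config$hosts$LGV == "SV") {
    att$SV <- c(att$SV, config$dist_LGV_junction)
    trib_at[[paste0("SV@", config$dist_LGV_junction)]] <- "LGV"
  } else {
    att$PV <- c(att$PV, config$dist_LGV_on_PV)
    trib_at[[paste0("PV@", config$dist_LGV_on_PV)]] <- "LGV"
  }

  # flow through a trunk cross-section at position s (mm from the junction):
  # the trunk's own inlet flow plus tributaries attached farther than s
  trunk_flow <- function(trunk, s) {
    q <- if (trunk == "SV") qin[["SV"]]
         else if (trunk == "SMV") qin[["SMV"]]
         else sum(qin)                      # PV carries everything at s = 0
    if (trunk == "PV") {
      # tributaries attached to the PV enter between the junction and their
      # attachment point, so they are NOT yet in the flow upstream of it
      for (a in att$PV) if (s < a) q <- q - qin[[trib_at[[paste0("PV@", a)]]]]
    } else {
      # the trunk drains toward the junction at s = 0, so a cross-section at
      # s carries every tributary attached farther out (a > s)
      for (a in att[[trunk]]) if (a > s) q <- q + qin[[trib_at[[paste0(trunk, "@", a)]]]]
    }
    q
  }

  curved_len <- NULL
  if (config$sv_curved)
    curved_len <- distance_factor(
      curved_midsv_points(config$dist_LGV_junction, config$curve_step))$L

  segs <- list()
  add_seg <- function(vessel, s0, s1, diameter, flow, length = NULL) {
    len <- length %||% (s1 - s0)
    segs[[length(segs) + 1]] <<- data.frame(
      vessel = vessel, s0 = s0, s1 = s1, length = len, diameter = diameter,
      lateral_area = pi * diameter * len, flow = flow)
  }
  for (trunk in c("SV", "SMV", "PV")) {
    L <- v[[trunk]]$length
    brk <- sort(unique(c(0, att[[trunk]], L)))
    for (i in seq_len(length(brk) - 1)) {
      s0 <- brk[i]; s1 <- brk[i + 1]
      smid <- (s0 + s1) / 2
      len <- NULL
      if (trunk == "SV" && !is.null(curved_len) &&
          isTRUE(all.equal(c(s0, s1), c(config$dist_LGV_junction,
                                        config$dist_IMV_junction))))
        len <- curved_len
      add_seg(trunk, s0, s1, v[[trunk]]$diameter, trunk_flow(trunk, smid), len)
    }
  }
  add_seg("LGV", 0, v$LGV$length, v$LGV$diameter, qin[["LGV"]])
  add_seg("IMV", 0, v$IMV$length, v$IMV$diameter, qin[["IMV"]])

  g <- do.call(rbind, segs)
  rownames(g) <- NULL
  structure(list(segments = g, inflows = qin, config = config,
                 flow_scale = flow_scale),
            class = "segment_graph")
}

#' @export
print.segment_graph <- function(x, ...) {
  cat(sprintf("segment graph (%s): %d segments, total inflow %.3f mL/s\n",
              x$config$condition, nrow(x$segments), sum(x$inflows) * 1e6))
  print(cbind(x$segments[c("vessel", "s0", "s1", "length", "diameter")],
              flow_mLs = x$segments$flow * 1e6))
  invisible(x)
}

#' Segment wall shear stress (Newtonian-profile approximation)
#'
#' Wall shear from fully developed pipe flow assuming the parabolic
#' (Newtonian) velocity profile, so the wall shear rate is 8 vbar / D; the
#' wall shear stress is the fixed point of tau = mu(gamma_w) gamma_w, which
#' with gamma_w fixed closes under damped iteration immediately. Zero flow
#' gives exactly zero stress.
#'
#' @param flow volumetric flow (m^3/s), non-negative
#' @param diameter vessel diameter (mm)
#' @param rheology a [rheology_model()]
#' @param damping,tol,max_iter damped fixed-point controls
#' @return wall shear stress in Pa
#' @export
segment_wss <- function(flow, diameter, rheology = rheology_model(),
                        damping = 0.5, tol = 1e-10, max_iter = 200) {
  stopifnot(flow >= 0, diameter > 0)
  if (flow == 0) return(0)
  D <- diameter / 1000
  vbar <- flow / (pi * D^2 / 4)
  gw <- 8 * vbar / D
  tau <- carreau_viscosity(gw, rheology) * gw
  for (i in seq_len(max_iter)) {
    tau_new <- (1 - damping) * tau + damping * carreau_viscosity(gw, rheology) * gw
    if (abs(tau_new - tau) < tol) return(tau_new)
    tau <- tau_new
  }
  stop("segment WSS fixed point did not converge")    # unreachable for Carreau
}

# invert tau = mu(gamma) * gamma for gamma (monotone for Carreau with n < 1)
invert_shear <- function(tau, rheology) {
  if (tau <= 0) return(0)
  f <- function(g) carreau_viscosity(g, rheology) * g - tau
  hi <- max(1, tau / rheology$mu_inf * 2)
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(0, hi), tol = 1e-14 * max(1, hi))$root
}

#' Segment wall shear stress (exact generalized Poiseuille solution)
#'
#' Verification oracle for [segment_wss()]: in fully developed pipe flow the
#' shear stress varies linearly with radius, tau(r) = tau_w r / R, so the
#' flow for a given wall stress follows from the Rabinowitsch integral
#'   Q(tau_w) = (pi R^3 / tau_w^3) * Int_0^tau_w tau^2 gamma(tau) d tau,
#' where gamma(tau) inverts the Carreau constitutive law. The wall stress is
#' the root of Q(tau_w) = Q. Exact (to quadrature/root tolerance) for any
#' generalized Newtonian fluid; reduces to 8 mu vbar / D when Newtonian.
#'
#' @inheritParams segment_wss
#' @return wall shear stress in Pa
#' @export
segment_wss_exact <- function(flow, diameter, rheology = rheology_model()) {
  stopifnot(flow >= 0, diameter > 0)
  if (flow == 0) return(0)
  R <- diameter / 2000
  gl <- pracma::gaussLegendre(48, 0, 1)
  Qof <- function(tauw) {
    tt <- tauw * gl$x
    gam <- vapply(tt, invert_shear, 0, rheology = rheology)
    int <- tauw * sum(gl$w * tt^2 * gam)
    pi * R^3 / tauw^3 * int
  }
  tau0 <- segment_wss(flow, diameter, rheology)
  lo <- tau0 / 4; hi <- tau0 * 8
  while (Qof(lo) > flow) lo <- lo / 2
  while (Qof(hi) < flow) hi <- hi * 2
  stats::uniroot(function(t) Qof(t) - flow, c(lo, hi),
                 tol = 1e-13 * tau0)$root
}

#' Segment-wise low-WSS area ratio of a network
#'
#' Applies the low-WSS threshold segment by segment: the ALS approximation is
#' the summed lateral area of segments whose fully developed wall shear falls
#' below the threshold, as a percentage of the total lateral area.
#'
#' @param graph a [network_from_anatomy()] result
#' @param rheology a [rheology_model()]
#' @param threshold Pa
#' @param exact use [segment_wss_exact()] instead of the Newtonian-profile
#'   approximation
#' @return ALS in percent
#' @export
network_als <- function(graph, rheology = rheology_model(), threshold = 0.1,
                        exact = FALSE) {
  g <- graph$segments
  f <- if (exact) segment_wss_exact else segment_wss
  tau <- mapply(function(q, d) f(q, d, rheology), g$flow, g$diameter)
  100 * sum(g$lateral_area[tau < threshold]) / sum(g$lateral_area)
}

#' Network metrics report
#'
#' Same summary statistics as the 3D pipeline ([metrics_report()]) computed
#' from the reduced-order network: segment WSS, area-weighted SA-WSS and the
#' segment-wise ALS.
#'
#' @inheritParams network_als
#' @param scenario optional scenario metadata
#' @export
network_metrics <- function(graph, rheology = rheology_model(),
                            threshold = 0.1, exact = FALSE, scenario = NULL) {
  g <- graph$segments
  f <- if (exact) segment_wss_exact else segment_wss
  tau <- mapply(function(q, d) f(q, d, rheology), g$flow, g$diameter)
  structure(list(
    sa_wss = sum(tau * g$lateral_area) / sum(g$lateral_area),
    als = 100 * sum(g$lateral_area[tau < threshold]) / sum(g$lateral_area),
    threshold = threshold,
    M = sum(tau < threshold), N = nrow(g),
    A_W = sum(g$lateral_area),
    max_mu_nw = max(carreau_viscosity(
      8 * (g$flow / (pi * (g$diameter / 1000)^2 / 4)) / (g$diameter / 1000),
      rheology)),
    per_vessel = data.frame(vessel = g$vessel, s0 = g$s0, s1 = g$s1,
                            wss = tau, flow = g$flow),
    q_in = sum(graph$inflows), q_out = sum(graph$inflows),
    converged = TRUE, n_cells = nrow(g), t_final = 0,
    scenario = scenario,
    method = "network1d"
  ), class = "metrics_report")
}
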