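# Wall-shear statistics. The two summary quantities of the study are the
# area-weighted space-averaged WSS,
#     SA-WSS = (1/A_W) sum_i WSS_i dA_i,
# and the low-WSS area ratio,
#     ALS = 100% * (1/A_W) sum_{i : WSS_i < WSS_T} dA_i,
# with threshold WSS_T = 0.1 Pa. A_W is the physical wall (lateral surfaces
# plus the ligated SV cap); open inlet/outlet port disks are not wall.

#' Extract the wall-shear field from a flow solution
#'
#' Recomputes the per-face WSS on the triangulated wall by sampling the
#' velocity field at two offsets along the inward normal, fitting the
#' tangential profile through zero at the wall, and evaluating the Carreau
#' viscosity at the resulting wall shear rate: WSS_i = mu(gamma_w) * gamma_w,
#' the magnitude of the tangential traction.
#'
#' @param solution a [solve_steady_flow()] result
#' @param mesh the [generate_mesh()] the solution was computed on
#' @return object of class `wss_field`: a data frame with one row per surface
#'   face (area mm^2, wss Pa, wall shear rate 1/s, near-wall viscosity Pa s,
#'   patch, vessel, wall flag) with attribute `A_W`
#' @export
compute_wss <- function(solution, mesh) {
  stopifnot(inherits(solution, "flow_solution"), inherits(mesh, "labeled_mesh"))
  if (is.null(solution$fields$u)) {       # degenerate zero-inflow solution
    fld <- solution$wall
  } else {
    surf <- mesh$surface
    rheo <- solution$rheology
    pr <- cpp_wss_probe(solution$fields$u, solution$fields$v, solution$fields$w,
                        solution$fields$viscosity,
                        as.integer(mesh$cell_class), mesh$origin, mesh$h,
                        mesh$dims, surf$centroid / 1000, surf$normal_in,
                        solution$settings$probe_delta[1] * mesh$h,
                        solution$settings$probe_delta[2] * mesh$h,
                        list(mu0 = rheo$mu0, mu_inf = rheo$mu_inf,
                             lambda = rheo$lambda, n = rheo$n))
    fld <- data.frame(wss = pr$wss, gamma_w = pr$gamma_w, mu_nw = pr$mu_nw,
                      area = surf$area, patch = surf$patch,
                      vessel = surf$vessel, wall = mesh$wall)
  }
  as_wss_field(fld)
}

as_wss_field <- function(df) {
  stopifnot(all(c("wss", "area", "wall") %in% names(df)))
  structure(df, class = c("wss_field", "data.frame"),
            A_W = sum(df$area[df$wall]))
}

wall_subset <- function(field) field[field$wall, , drop = FALSE]

#' Space-averaged wall shear stress
#'
#' Area-weighted mean of the WSS over the wall, `sum(WSS_i dA_i) / A_W`.
#'
#' @param field a [compute_wss()] result (or any data frame with `wss`,
#'   `area` and `wall` columns)
#' @return SA-WSS in Pa
#' @export
space_averaged_wss <- function(field) {
  w <- wall_subset(field)
  if (nrow(w) == 0 || sum(w$area) <= 0) stop("empty wall: SA-WSS undefined")
  sum(w$wss * w$area) / sum(w$area)
}

#' Low-WSS area ratio (ALS)
#'
#' Percentage of the wall area exposed to WSS strictly below the threshold.
#'
#' @param field a [compute_wss()] result
#' @param threshold low-WSS threshold WSS_T in Pa (0.1 Pa by default)
#' @return ALS in percent (0--100)
#' @export
low_wss_area_ratio <- function(field, threshold = 0.1) {
  stopifnot(threshold > 0)
  w <- wall_subset(field)
  if (nrow(w) == 0) return(0)
  100 * sum(w$area[w$wss < threshold]) / sum(w$area)
}

#' Near-wall viscosity statistics over a wall region
#'
#' Summaries of the Carreau viscosity in the first near-wall layer of the
#' selected region. Stagnant regions approach the zero-shear viscosity mu0;
#' briskly perfused walls sit near the high-shear branch.
#'
#' @param field a [compute_wss()] result
#' @param region vessel name(s) (e.g. `"SV"`) and/or patch labels; faces
#'   matching either selector are included. `NULL` selects the whole wall.
#' @return list with `max`, `mean`, `median` near-wall viscosity (Pa s) and
#'   the face count `n`
#' @export
viscosity_statistics <- function(field, region = NULL) {
  w <- wall_subset(field)
  if (!is.null(region)) {
    sel <- w$vessel %in% region | w$patch %in% region
    w <- w[sel, , drop = FALSE]
  }
  if (nrow(w) == 0) stop("empty wall region selection")
  list(max = max(w$mu_nw), mean = mean(w$mu_nw),
       median = stats::median(w$mu_nw), n = nrow(w))
}

#' Area-weighted Jaccard overlap of the low-WSS and high-viscosity wall sets
#'
#' Measures the co-location of clot-prone wall regions: the set of faces with
#' WSS below `wss_threshold` versus the set with near-wall viscosity above
#' `mu_threshold`.
#'
#' @param field a [compute_wss()] result
#' @param wss_threshold Pa
#' @param mu_threshold Pa s
#' @return Jaccard index in `[0, 1]`
#' @export
low_wss_high_viscosity_overlap <- function(field, wss_threshold = 0.1,
                                           mu_threshold) {
  w <- wall_subset(field)
  a <- w$wss < wss_threshold
  b <- w$mu_nw > mu_threshold
  inter <- sum(w$area[a & b])
  uni <- sum(w$area[a | b])
  if (uni <= 0) return(NA_real_)
  inter / uni
}

#' Assemble a metrics report for one scenario
#'
#' @param solution a [solve_steady_flow()] result
#' @param mesh the mesh it was solved on
#' @param scenario optional scenario metadata (list or `scenario_spec`)
#' @param threshold low-WSS threshold (Pa)
#' @return object of class `metrics_report`
#' @export
metrics_report <- function(solution, mesh, scenario = NULL, threshold = 0.1) {
  field <- compute_wss(solution, mesh)
  w <- wall_subset(field)
  per_vessel <- do.call(rbind, lapply(split(w, w$vessel), function(d) {
    data.frame(vessel = d$vessel[1],
               area = sum(d$area),
               sa_wss = sum(d$wss * d$area) / sum(d$area),
               als = 100 * sum(d$area[d$wss < threshold]) / sum(d$area),
               max_mu_nw = max(d$mu_nw))
  }))
  rownames(per_vessel) <- NULL
  structure(list(
    sa_wss = space_averaged_wss(field),
    als = low_wss_area_ratio(field, threshold),
    threshold = threshold,
    M = sum(w$wss < threshold),
    N = nrow(w),
    A_W = attr(field, "A_W"),
    max_mu_nw = max(w$mu_nw),
    per_vessel = per_vessel,
    q_in = solution$q_in, q_out = solution$q_out,
    converged = solution$converged,
    n_cells = solution$n_free_cells,
    t_final = solution$t_final,
    scenario = scenario,
    method = "3d"
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics [%s]: SA-WSS %.3f Pa, ALS %.2f%% (threshold %.2g Pa)\n",
              x$method, x$sa_wss, x$als, x$threshold))
  cat(sprintf("  wall: %d faces, %.0f mm^2; low-WSS faces M = %d; max near-wall viscosity %.4g Pa s\n",
              x$N, x$A_W, x$M, x$max_mu_nw))
  invisible(x)
}
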