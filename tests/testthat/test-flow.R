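test_that("parabolic inlet profile has the analytic shape and mean", {
  port <- list(center = c(0, 0, 0), normal = c(-1, 0, 0), radius = 0.005)
  # rim and peak
  expect_equal(drop(parabolic_inlet_profile(0.1, port, c(0, 0.005, 0))),
               c(0, 0, 0))
  expect_equal(parabolic_inlet_profile(0.1, port, c(0, 0, 0))[1, ],
               c(0.2, 0, 0))
  # area-average equals the mean velocity within 0.5% (disk quadrature)
  g <- expand.grid(y = seq(-0.005, 0.005, length.out = 301),
                   z = seq(-0.005, 0.005, length.out = 301))
  g <- g[g$y^2 + g$z^2 <= 0.005^2, ]
  vel <- parabolic_inlet_profile(0.1, port, cbind(0, g$y, g$z))
  expect_equal(mean(vel[, 1]), 0.1, tolerance = 0.005)
  expect_error(parabolic_inlet_profile(0.1, port, c(0.01, 0, 0)), "planar")
})

test_that("boundary conditions reproduce the scenario inflows", {
  pre <- build_boundary_conditions(build_anatomy(1, condition = "preoperative"))
  q <- function(bc, port, d_mm) {
    v <- bc$inlets$velocity[bc$inlets$port == port]
    v * pi * (d_mm / 1000)^2 / 4 * 1e6         # mL/s
  }
  expect_equal(q(pre, "sv_inlet", 10.12), 7.15, tolerance = 0.01)
  expect_equal(q(pre, "smv_inlet", 11.875), 5.56, tolerance = 0.01)
  expect_equal(q(pre, "lgv_inlet", 6.0), 2.21, tolerance = 0.01)
  expect_equal(q(pre, "imv_inlet", 4.1), 1.06, tolerance = 0.01)
  expect_equal(pre$outlet_pressure, 3333.06, tolerance = 1e-4)

  post <- build_boundary_conditions(build_anatomy(1, condition = "postoperative"))
  expect_false("sv_inlet" %in% post$inlets$port)
  total <- q(post, "smv_inlet", 11.875) + q(post, "lgv_inlet", 6.0) +
    q(post, "imv_inlet", 4.1)
  expect_equal(total, 8.82, tolerance = 0.01)

  comp <- build_boundary_conditions(build_anatomy(1, condition = "postoperative"),
                                    flow_scale = 1.3)
  expect_equal(comp$inlets$velocity, post$inlets$velocity * 1.3)
})

test_that("Newtonian straight-tube flow matches Poiseuille wall shear", {
  tv <- tube_validation()
  sol <- tv$sol
  tau_an <- 8 * 0.0035 * 0.0889 / 0.010
  w <- sol$wall
  x <- tv$mesh$surface$centroid[, 1]
  sel <- w$wall & x > 30 & x < 90          # fully developed region
  dev <- w$wss[sel] / tau_an - 1
  expect_lt(abs(mean(dev)), 0.03)
  expect_lt(abs(sum(w$wss[sel] * w$area[sel]) / sum(w$area[sel]) / tau_an - 1), 0.03)
  # mass conservation
  expect_lt(abs(sol$q_out - sol$q_in) / sol$q_in, 0.005)
  expect_equal(sol$q_in, 0.0889 * pi * 0.005^2, tolerance = 1e-6)
})

test_that("the flow field is mirror-symmetric about the construction plane", {
  tv <- tube_validation()
  g <- tv$sol$grid
  nz <- g$dims[3]
  u <- array(tv$sol$fields$u, c(g$dims[1] + 1, g$dims[2], nz))
  asym <- max(abs(u[, , nz:1] - u)) / mean(abs(u[u != 0]))
  expect_lt(asym, 0.01)
})

test_that("outlet pressure shifts pressure only, not velocity or WSS", {
  a <- mini_tube(outlet_mmHg = 25)
  b <- mini_tube(outlet_mmHg = 0)
  expect_equal(a$sol$fields$u, b$sol$fields$u, tolerance = 1e-12)
  expect_equal(a$sol$wall$wss, b$sol$wall$wss, tolerance = 1e-12)
  expect_equal(a$sol$outlet_pressure - b$sol$outlet_pressure, 25 * 133.3224,
               tolerance = 1e-6)
})

test_that("viscosity and wall shear are mutually consistent at convergence", {
  tv <- mini_tube()
  w <- tv$sol$wall
  # WSS_i is exactly mu(gamma_w) * gamma_w by the constitutive law
  expect_equal(w$wss, carreau_viscosity(w$gamma_w, tv$rheology) * w$gamma_w,
               tolerance = 1e-12)
  # viscosity bounded by the Carreau limits everywhere
  mu <- tv$sol$fields$viscosity
  expect_true(all(mu >= tv$rheology$mu_inf - 1e-12 & mu <= tv$rheology$mu0 + 1e-12))
  # no-slip: sampled velocity magnitude at the wall itself is tiny
  expect_true(tv$sol$converged)
})

test_that("zero total inflow returns the exact quiescent solution with a warning", {
  model <- tube_geometry(diameter = 6, length = 12)
  mesh <- generate_mesh(model, mesh_settings(min_element_size = 1))
  bcs <- tube_boundary_conditions(velocity = 0)
  expect_warning(sol <- solve_steady_flow(mesh, bcs), "zero total inflow")
  expect_equal(sol$sa_wss, 0)
  expect_equal(sol$als, 100)
  expect_true(all(sol$wall$wss == 0))
})

test_that("an inlet without a prescribed velocity is an error", {
  model <- tube_geometry(diameter = 6, length = 12)
  mesh <- generate_mesh(model, mesh_settings(min_element_size = 1))
  bad <- tube_boundary_conditions()
  bad$inlets$port <- "elsewhere"
  expect_error(solve_steady_flow(mesh, bad), "no inlet velocity")
})
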