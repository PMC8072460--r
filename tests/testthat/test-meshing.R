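test_that("mesh settings presets carry the documented resolutions", {
  desk <- mesh_settings("desk")
  expect_equal(desk$min_element_size, 0.7)
  paper <- mesh_settings("paper")
  expect_equal(paper$min_element_size, 0.08)
  expect_equal(paper$first_layer_thickness, 0.05)
  expect_error(mesh_settings("cluster"), "preset")
  expect_error(mesh_settings(min_element_size = -1), "min_element_size")
})

test_that("voxel mesh of a tube is labeled, consistent and deterministic", {
  model <- tube_geometry(diameter = 6, length = 20)
  ms <- mesh_settings(min_element_size = 0.75, core_element_size = 0.75)
  mesh <- generate_mesh(model, ms)
  expect_gt(mesh$n_interior, 0)
  # every boundary face carries exactly one patch label
  expect_true(all(mesh$surface$patch %in% c("wall", "inlet", "outlet")))
  expect_true(all(mesh$surface$area > 0))
  # A_W is exactly the sum of wall-face areas (caps included, ports excluded)
  expect_identical(mesh$A_W, sum(mesh$surface$area[mesh$wall]))
  # deterministic meshing: regeneration is bit-identical
  mesh2 <- generate_mesh(model, ms)
  expect_identical(mesh$cell_class, mesh2$cell_class)
  expect_identical(mesh$surface$vertices, mesh2$surface$vertices)
})

test_that("tube wall area is within 2% of the analytic cylinder", {
  model <- tube_geometry(diameter = 10, length = 100)
  mesh <- generate_mesh(model, mesh_settings(min_element_size = 1))
  expect_equal(mesh$A_W, 1000 * pi, tolerance = 0.02)
  expect_lt(surface_closure_defect(mesh$surface), 1e-6 * sum(mesh$surface$area))
})

test_that("refining the tessellation changes the wall area by < 0.5%", {
  model <- tube_geometry(diameter = 10, length = 100)
  a1 <- generate_mesh(model, mesh_settings(n_theta = 28))$A_W
  a2 <- generate_mesh(model, mesh_settings(n_theta = 36, ring_step = 1))$A_W
  expect_lt(abs(a2 - a1) / a1, 0.005)
})

test_that("convergence report tabulates resolutions and is deterministic", {
  cfg <- build_anatomy(1)
  # fake evaluator: cheap, resolution-dependent
  ev <- function(config, settings, ...) 0.4 + 0.01 * settings$min_element_size
  one <- mesh_convergence_report(cfg, list(mesh_settings()), evaluator = ev)
  expect_equal(nrow(one), 1)
  expect_true(is.na(one$rel_change[1]))
  two <- mesh_convergence_report(
    cfg, list(mesh_settings(min_element_size = 1.2),
              mesh_settings(min_element_size = 1.0)), evaluator = ev)
  expect_equal(two$rel_change[2], abs(diff(two$sa_wss)) / two$sa_wss[1])
  # identical settings twice: identical SA-WSS through the real pipeline
  mini <- mini_tube()
  real <- function(config, settings, ...) {
    mesh <- generate_mesh(mini$model, settings)
    solve_steady_flow(mesh, mini$bcs, mini$rheology)$sa_wss
  }
  ms <- mesh_settings(min_element_size = 0.75, core_element_size = 0.75)
  rep2 <- mesh_convergence_report(cfg, list(ms, ms), evaluator = real)
  expect_identical(rep2$sa_wss[1], rep2$sa_wss[2])
})

test_that("the desk resolution is certified by a refinement study", {
  cfg <- build_anatomy(1, condition = "postoperative")
  tab <- mesh_convergence_report(cfg, list(
    mesh_settings(min_element_size = 0.8, core_element_size = 0.8),
    mesh_settings()))
  expect_lt(tab$rel_change[2], 0.02)
})
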