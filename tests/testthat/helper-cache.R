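# session-level cache so expensive solves run once per test session
.pvs_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .pvs_cache))
    assign(name, force(expr), envir = .pvs_cache)
  get(name, envir = .pvs_cache)
}

# straight-tube Newtonian validation run (Poiseuille reference); tessellated
# finely so surface faceting does not confound the solver comparison
tube_validation <- function() {
  cached("tube_validation", {
    model <- tube_geometry(diameter = 10, length = 100)
    mesh <- generate_mesh(model, mesh_settings(min_element_size = 0.5,
                                               core_element_size = 0.5,
                                               n_theta = 56, ring_step = 0.6))
    rh <- newtonian_model(mu = 0.0035)
    bcs <- tube_boundary_conditions(velocity = 0.0889)
    sol <- solve_steady_flow(mesh, bcs, rheology = rh)
    list(model = model, mesh = mesh, sol = sol, rheology = rh, bcs = bcs)
  })
}

# small tube for cheap solver behaviour tests
mini_tube <- function(outlet_mmHg = 25) {
  cached(paste0("mini_tube_", outlet_mmHg), {
    model <- tube_geometry(diameter = 6, length = 24)
    mesh <- generate_mesh(model, mesh_settings(min_element_size = 0.75,
                                               core_element_size = 0.75))
    rh <- rheology_model()
    bcs <- tube_boundary_conditions(velocity = 0.06,
                                    outlet_pressure_mmHg = outlet_mmHg)
    sol <- solve_steady_flow(mesh, bcs, rheology = rh)
    list(model = model, mesh = mesh, sol = sol, rheology = rh, bcs = bcs)
  })
}

# a synthetic wall-shear field for the metric-oracle tests
synthetic_wss_field <- function(n = 500, seed = 42) {
  set.seed(seed)
  df <- data.frame(
    wss = stats::rlnorm(n, log(0.15), 1),
    gamma_w = stats::rlnorm(n, log(20), 1),
    mu_nw = stats::rlnorm(n, log(0.008), 0.5),
    area = stats::runif(n, 0.2, 2),
    patch = sample(c("wall", "wall", "wall", "sv_cap", "pv_outlet"), n, TRUE),
    vessel = sample(c("PV", "SV", "SMV", "LGV", "IMV"), n, TRUE)
  )
  df$wall <- pvshemo:::wall_faces(df$patch)
  pvshemo:::as_wss_field(df)
}
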