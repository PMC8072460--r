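test_that("Carreau viscosity matches its analytic limits and is shear-thinning", {
  rh <- rheology_model()
  expect_equal(carreau_viscosity(0, rh), 0.056)
  expect_equal(carreau_viscosity(1e9, rh), 0.00345, tolerance = 1e-4)
  # strictly decreasing and bounded over a wide shear-rate sweep
  g <- 10^seq(-3, 6, length.out = 200)
  mu <- carreau_viscosity(g, rh)
  expect_true(all(diff(mu) < 0))
  expect_true(all(mu <= 0.056 & mu >= 0.00345))
  # representative wall shear rate of the preoperative splenic vein
  expect_equal(carreau_viscosity(70.3, rh), 0.005027, tolerance = 1e-3)
  expect_error(carreau_viscosity(-1, rh), "non-negative")
})

test_that("rheology constructors validate their parameters", {
  expect_error(rheology_model(mu0 = 0.001, mu_inf = 0.002), "mu_inf")
  expect_error(rheology_model(n = 1.2), "shear-thinning")
  nw <- newtonian_model(0.004)
  expect_equal(carreau_viscosity(c(0, 50, 5000), nw), rep(0.004, 3))
})
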