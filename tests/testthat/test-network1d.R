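test_that("segment flows satisfy Kirchhoff conservation from the inlets", {
  g <- network_from_anatomy(build_anatomy(1, condition = "preoperative"))
  segs <- g$segments
  pv_out <- segs$flow[segs$vessel == "PV" & segs$s1 == max(segs$s1[segs$vessel == "PV"])]
  expect_equal(pv_out * 1e6, 15.97, tolerance = 0.01)
  expect_equal(pv_out, sum(g$inflows))
  # at the splenoportal junction: SV + SMV flows meet the PV exactly
  sv0 <- segs$flow[segs$vessel == "SV" & segs$s0 == 0]
  smv0 <- segs$flow[segs$vessel == "SMV" & segs$s0 == 0]
  pv0 <- segs$flow[segs$vessel == "PV" & segs$s0 == 0]
  expect_equal(sv0 + smv0, pv0, tolerance = 1e-14)
  # each junction adds exactly the tributary inflow
  sv_far <- segs$flow[segs$vessel == "SV" & segs$s0 == 60]
  expect_equal(segs$flow[segs$vessel == "SV" & segs$s0 == 30] - sv_far,
               unname(g$inflows["IMV"]), tolerance = 1e-14)
})

test_that("postoperative stumps carry exactly zero flow", {
  g1 <- network_from_anatomy(build_anatomy(1, condition = "postoperative"))
  stump <- g1$segments[g1$segments$vessel == "SV" & g1$segments$s0 == 60, ]
  expect_identical(stump$flow, 0)
  expect_equal(stump$length, 113.5 - 60)
  # type 4: nothing drains into the SV, the whole vessel is a dead end
  g4 <- network_from_anatomy(build_anatomy(4, condition = "postoperative"))
  expect_true(all(g4$segments$flow[g4$segments$vessel == "SV"] == 0))
})

test_that("segment WSS reduces to the Newtonian closed form", {
  nw <- newtonian_model(mu = 0.004)
  D <- 8; Q <- 2e-6
  vbar <- Q / (pi * (D / 1000)^2 / 4)
  tau_ref <- 8 * 0.004 * vbar / (D / 1000)
  expect_equal(segment_wss(Q, D, nw), tau_ref, tolerance = 1e-12)
  expect_equal(segment_wss_exact(Q, D, nw), tau_ref, tolerance = 1e-9)
  expect_equal(segment_wss(0, D, nw), 0)
  expect_equal(segment_wss_exact(0, D, nw), 0)
})

test_that("Carreau segment WSS matches the frozen preoperative SV value", {
  rh <- rheology_model()
  Q_sv <- 0.0889 * pi * 0.01012^2 / 4
  vbar <- 0.0889; D <- 0.01012
  expect_equal(8 * vbar / D, 70.28, tolerance = 1e-3)
  tau <- segment_wss(Q_sv, 10.12, rh)
  expect_equal(tau, 0.3533, tolerance = 1e-3)
  # exact generalized Poiseuille: blunter profile, higher wall shear, but
  # within 15% of the parabolic-profile approximation at these conditions
  tau_ex <- segment_wss_exact(Q_sv, 10.12, rh)
  expect_gt(tau_ex, tau)
  expect_lt(abs(tau_ex - tau) / tau, 0.15)
})

test_that("exact segment WSS is strictly increasing in flow", {
  rh <- rheology_model()
  flows <- c(0.2, 0.5, 1, 2, 5, 10) * 1e-6
  tau <- vapply(flows, segment_wss_exact, 0, diameter = 10.12, rheology = rh)
  expect_true(all(diff(tau) > 0))
})

test_that("network ALS separates pre- from postoperative conditions", {
  rh <- rheology_model()
  pre <- network_from_anatomy(build_anatomy(1, condition = "preoperative"))
  expect_lt(network_als(pre, rh), 5)
  post1 <- network_from_anatomy(build_anatomy(1, condition = "postoperative"))
  post4 <- network_from_anatomy(build_anatomy(4, condition = "postoperative"))
  expect_gte(network_als(post4, rh), network_als(post1, rh))
  # all segments above threshold: zero ratio
  expect_equal(network_als(pre, rh, threshold = 1e-6), 0)
})

test_that("network metrics report mirrors the 3D report schema", {
  g <- network_from_anatomy(build_anatomy(2, condition = "postoperative"))
  rep <- network_metrics(g)
  expect_equal(rep$method, "network1d")
  expect_true(rep$M <= rep$N)
  expect_gte(rep$als, 0); expect_lte(rep$als, 100)
  expect_equal(rep$A_W, sum(g$segments$lateral_area))
})

test_that("curved mid-SV segment contributes its arc length to the network", {
  straight <- network_from_anatomy(build_anatomy(1, "D+", "postoperative"))
  curved <- network_from_anatomy(build_anatomy(1, c("D+", "curved"), "postoperative"))
  seg_s <- straight$segments[straight$segments$vessel == "SV" &
                             straight$segments$s0 == 30, ]
  seg_c <- curved$segments[curved$segments$vessel == "SV" &
                           curved$segments$s0 == 30, ]
  expect_equal(seg_s$length, 50)
  expect_equal(seg_c$length, 20 + 25 * pi, tolerance = 1e-3)
})
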