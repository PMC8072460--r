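test_that("a swept cylinder reproduces the analytic tube area", {
  model <- tube_geometry(diameter = 10, length = 100)
  surf <- centerline_to_surface(model, n_theta = 64, ring_step = 0.5)
  lateral <- surface_area(surf, "wall")
  expect_equal(lateral, pi * 10 * 100, tolerance = 0.01)
  # port disks
  expect_equal(surface_area(surf, "inlet"), pi * 25, tolerance = 0.01)
  expect_true(surface_is_watertight(surf))
  expect_lt(surface_closure_defect(surf), 1e-6 * sum(surf$area))
})

test_that("pre- and postoperative models expose the correct ports", {
  pre <- centerline_to_surface(build_centerlines(build_anatomy(1, condition = "preoperative")))
  post <- centerline_to_surface(build_centerlines(build_anatomy(1, condition = "postoperative")))
  expect_setequal(unique(pre$patch),
                  c("wall", "sv_inlet", "smv_inlet", "lgv_inlet", "imv_inlet",
                    "pv_outlet"))
  expect_setequal(unique(post$patch),
                  c("wall", "sv_cap", "smv_inlet", "lgv_inlet", "imv_inlet",
                    "pv_outlet"))
  # the ligated cap counts as wall area, open ports do not
  expect_true(all(pvshemo:::wall_faces(c("wall", "sv_cap"))))
  expect_false(any(pvshemo:::wall_faces(c("sv_inlet", "pv_outlet"))))
})

test_that("the baseline surface is mirror-symmetric about the construction plane", {
  surf <- centerline_to_surface(build_centerlines(build_anatomy(1)))
  z <- sort(surf$vertices[, 3])
  expect_equal(z, sort(-z), tolerance = 1e-9)
})

test_that("junction-clipped wall area tracks the analytic tube-union estimate", {
  cfg <- build_anatomy(1, condition = "preoperative")
  m <- build_centerlines(cfg)
  surf <- centerline_to_surface(m, n_theta = 48, ring_step = 0.6)
  wall_area <- surface_area(surf, "wall")
  v <- cfg$vessels
  # analytic: full lateral areas, minus the tributary portion inside the host
  # (about one host radius of tributary length) and the hole cut in the host
  # (an ellipse of the tributary cross-section widened by the 70 deg angle),
  # and minus the trunk ends swallowed at the splenoportal junction
  lat <- function(d, L) pi * d * L
  est <- lat(v$PV$diameter, v$PV$length) + lat(v$SV$diameter, v$SV$length) +
    lat(v$SMV$diameter, v$SMV$length) + lat(v$LGV$diameter, v$LGV$length) +
    lat(v$IMV$diameter, v$IMV$length)
  sin70 <- sin(70 * pi / 180)
  est <- est -
    lat(v$IMV$diameter, v$SV$diameter / 2) - pi * (v$IMV$diameter / 2)^2 / sin70 -
    lat(v$LGV$diameter, v$SV$diameter / 2) - pi * (v$LGV$diameter / 2)^2 / sin70 -
    lat(v$SV$diameter, v$PV$diameter / 2) - lat(v$SMV$diameter, v$PV$diameter / 2)
  expect_equal(wall_area, est, tolerance = 0.05)
})
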