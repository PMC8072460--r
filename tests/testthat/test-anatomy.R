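test_that("literature means reproduce the baseline vessel parameters exactly", {
  expect_equal(mean_of_literature(c(12.9, 13.3, 13.9, 12.9, 14.1)), 13.42)
  expect_equal(mean_of_literature(c(70, 73.4)), 71.7)
  expect_equal(mean_of_literature(5.5), 5.5)
  expect_error(mean_of_literature(numeric(0)), "no literature")
  expect_error(mean_of_literature(c(1, -2)), "positive")

  tab <- pvs_vessel_table()
  ref <- data.frame(
    vessel = c("PV", "SV", "SMV", "LGV", "IMV"),
    diameter = c(13.42, 10.12, 11.875, 6.0, 4.1),
    length = c(71.7, 113.5, 60.8, 50, 59.7))
  expect_equal(tab[c("vessel", "diameter", "length")], ref)
  expect_equal(sv_diameter_variation(), 2.625)
})

test_that("baseline configuration carries the reference angles and distances", {
  cfg <- build_anatomy(1, character(), "preoperative")
  expect_equal(cfg$angle_PV_vertical, 29)
  expect_equal(cfg$angle_PV_SV, 113)
  expect_equal(cfg$angle_SV_SMV, 96)
  expect_equal(cfg$angle_IMV_trunk, 70)
  expect_equal(cfg$dist_IMV_junction, 60)
  expect_equal(cfg$hosts, list(IMV = "SV", LGV = "SV"))
})

test_that("each variation tag changes exactly one scalar of the configuration", {
  base <- build_anatomy(1, character(), "postoperative")
  scalar_state <- function(cfg) {
    c(unlist(lapply(cfg$vessels, function(v) c(v$diameter, v$length))),
      cfg$angle_PV_SV, cfg$angle_SV_SMV, cfg$angle_IMV_trunk,
      cfg$angle_LGV_trunk, cfg$dist_IMV_junction, cfg$dist_LGV_junction,
      cfg$dist_LGV_on_PV, cfg$dist_IMV_on_SMV, as.numeric(cfg$sv_curved))
  }
  expected <- list(
    "A-" = c(tag = "angle_IMV_trunk", value = 50),
    "A+" = c(tag = "angle_IMV_trunk", value = 90),
    "B-" = c(tag = "angle_PV_SV", value = 103),
    "B+" = c(tag = "angle_PV_SV", value = 123),
    "D-" = c(tag = "dist_IMV_junction", value = 40),
    "D+" = c(tag = "dist_IMV_junction", value = 80))
  for (tag in names(expected)) {
    cfg <- build_anatomy(1, tag, "postoperative")
    expect_equal(sum(scalar_state(cfg) != scalar_state(base)), 1, label = tag)
    expect_equal(cfg[[expected[[tag]][["tag"]]]],
                 as.numeric(expected[[tag]][["value"]]), label = tag)
  }
  expect_equal(build_anatomy(1, "C+", "postoperative")$vessels$SV$diameter, 12.745)
  expect_equal(build_anatomy(1, "C-", "postoperative")$vessels$SV$diameter, 7.495)
})

test_that("conflicting or ill-formed variation sets are rejected", {
  expect_error(build_anatomy(1, c("C-", "C+")), "conflicting")
  expect_error(build_anatomy(1, "E+"), "unknown variation")
  expect_error(build_anatomy(5), "anatomy_type")
  expect_error(build_anatomy(1, "curved"), "D\\+")
  expect_silent(build_anatomy(1, c("D+", "curved")))
})

test_that("anatomy types map tributaries to their hosts", {
  hosts <- list(`1` = c(IMV = "SV", LGV = "SV"),
                `2` = c(IMV = "SV", LGV = "PV"),
                `3` = c(IMV = "SMV", LGV = "SV"),
                `4` = c(IMV = "SMV", LGV = "PV"))
  for (ty in 1:4) {
    cfg <- build_anatomy(ty)
    expect_equal(unlist(cfg$hosts), hosts[[as.character(ty)]], label = ty)
    m <- build_centerlines(cfg)
    expect_equal(m$junctions$IMV$host, unname(hosts[[as.character(ty)]]["IMV"]))
    expect_equal(m$junctions$LGV$host, unname(hosts[[as.character(ty)]]["LGV"]))
  }
})

test_that("centerlines reproduce the configured junction geometry", {
  m <- build_centerlines(build_anatomy(1))
  expect_equal(m$junctions$IMV$point, c(60, 0, 0))
  expect_equal(m$junctions$LGV$point, c(30, 0, 0))
  # splenoportal angles from the generated points, within 0.1 degree
  dir_away <- function(v, from_start = TRUE) {
    p <- v$points
    d <- if (from_start) p[1, ] - p[nrow(p), ] else p[nrow(p), ] - p[1, ]
    d / sqrt(sum(d^2))
  }
  ang <- function(a, b) acos(sum(a * b)) * 180 / pi
  sv <- dir_away(m$vessels$SV)                 # junction -> SV inlet
  pv <- dir_away(m$vessels$PV, from_start = FALSE)
  smv <- dir_away(m$vessels$SMV)
  expect_lt(abs(ang(sv, pv) - 113), 0.1)
  expect_lt(abs(ang(sv, smv) - 96), 0.1)

  # junction placement outside the host vessel is a geometry error
  bad <- build_anatomy(1)
  bad$dist_IMV_junction <- 150
  expect_error(build_centerlines(bad), "outside")
})

test_that("postoperative SV proximal end is a cap, preoperative an inlet", {
  pre <- build_centerlines(build_anatomy(1, condition = "preoperative"))
  post <- build_centerlines(build_anatomy(1, condition = "postoperative"))
  expect_equal(pre$vessels$SV$port_start$kind, "inlet")
  expect_equal(post$vessels$SV$port_start$kind, "cap")
  expect_equal(post$vessels$SV$port_start$label, "sv_cap")
  # stump retains the full SV length
  expect_equal(post$vessels$SV$arc_length, 113.5)
})

test_that("curved mid-SV construction has the prescribed arc geometry", {
  cfg <- build_anatomy(1, c("D+", "curved"), "postoperative")
  m <- build_curved_sv(cfg)
  pts <- m$vessels$SV$points
  # extract the mid segment between the junctions at x = 80 and x = 30
  seg <- pts[pts[, 1] <= 80 + 1e-6 & pts[, 1] >= 30 - 1e-6, , drop = FALSE]
  seg <- seg[seg[, 2] < 1e-6, , drop = FALSE]
  df <- distance_factor(seg)
  expect_equal(df$L, 20 + 25 * pi, tolerance = 1e-3)
  expect_equal(df$D, 50, tolerance = 1e-9)
  expect_equal(df$DF, (20 + 25 * pi) / 50, tolerance = 1e-3)
  # end tangents collinear with the SV axis
  i80 <- which.min(abs(pts[, 1] - 80) + abs(pts[, 2]))
  t80 <- pts[i80 - 1, ] - pts[i80, ]
  expect_lt(abs(t80[2] / t80[1]), 1e-6)
  # without D+ the mid segment is not 50 mm: geometry error
  expect_error(build_curved_sv(build_anatomy(1)), "50 mm")
})

test_that("distance factor behaves analytically", {
  straight <- cbind(seq(0, 10, length.out = 21), 0, 0)
  expect_equal(distance_factor(straight)$DF, 1.0)
  th <- seq(0, pi, length.out = 721)
  semi <- cbind(cos(th), sin(th), 0)
  expect_equal(distance_factor(semi)$DF, pi / 2, tolerance = 1e-5)
  expect_error(distance_factor(semi[c(1, 1), ]), "coincident")
  expect_error(distance_factor(semi[1, , drop = FALSE]), "two points")
})

test_that("anatomy configurations round-trip through YAML", {
  skip_if_not_installed("yaml")
  cfg <- build_anatomy(3, c("C+", "D-"), "postoperative")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_anatomy_yaml(cfg, path)
  cfg2 <- read_anatomy_yaml(path)
  expect_equal(cfg2$vessels$SV$diameter, cfg$vessels$SV$diameter)
  expect_equal(cfg2$dist_IMV_junction, cfg$dist_IMV_junction)
  expect_equal(cfg2$hosts, cfg$hosts)
})
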