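make_field <- function(wss, area, patch = "wall") {
  df <- data.frame(wss = wss, area = area, patch = patch, vessel = "SV",
                   gamma_w = wss / 0.005, mu_nw = 0.005)
  df$wall <- pvshemo:::wall_faces(df$patch)
  pvshemo:::as_wss_field(df)
}

test_that("space-averaged WSS is the area-weighted mean", {
  expect_equal(space_averaged_wss(make_field(c(0.2, 0.4), c(1, 3))), 0.35)
  expect_equal(space_averaged_wss(make_field(rep(0.7, 9), runif(9))), 0.7)
  expect_error(space_averaged_wss(make_field(1, 1, patch = "pv_outlet")),
               "empty wall")
})

test_that("low-WSS area ratio counts strictly sub-threshold area", {
  expect_equal(low_wss_area_ratio(make_field(rep(0.2, 5), rep(1, 5)), 0.1), 0)
  expect_equal(low_wss_area_ratio(make_field(c(0.05, 0.5), c(2, 2)), 0.1), 50)
  # faces exactly at the threshold are not counted (strict inequality)
  expect_equal(low_wss_area_ratio(make_field(c(0.1, 0.09), c(1, 1)), 0.1), 50)
  expect_error(low_wss_area_ratio(make_field(1, 1), threshold = 0), "threshold")
})

test_that("ALS is monotone in the threshold with the correct limits", {
  f <- synthetic_wss_field()
  thr <- c(1e-9, 0.01, 0.05, 0.1, 0.3, 1, 10, 1e6)
  als <- vapply(thr, function(t) low_wss_area_ratio(f, t), 0)
  expect_true(all(diff(als) >= 0))
  expect_equal(als[1], 0)
  expect_equal(als[length(als)], 100)
})

test_that("vectorized statistics equal brute-force face loops", {
  f <- synthetic_wss_field()
  w <- f[f$wall, ]
  num <- 0; den <- 0; low <- 0
  for (i in seq_len(nrow(w))) {
    num <- num + w$wss[i] * w$area[i]
    den <- den + w$area[i]
    if (w$wss[i] < 0.1) low <- low + w$area[i]
  }
  expect_equal(space_averaged_wss(f), num / den, tolerance = 1e-14)
  expect_equal(low_wss_area_ratio(f, 0.1), 100 * low / den, tolerance = 1e-14)
})

test_that("statistics are invariant to face order and consistent unit scaling", {
  f <- synthetic_wss_field()
  perm <- sample(nrow(f))
  fp <- pvshemo:::as_wss_field(f[perm, ])
  expect_equal(space_averaged_wss(fp), space_averaged_wss(f))
  expect_equal(low_wss_area_ratio(fp), low_wss_area_ratio(f))
  # rescaling all areas (mm^2 -> m^2) leaves both statistics unchanged
  fs <- f; fs$area <- fs$area * 1e-6
  fs <- pvshemo:::as_wss_field(fs)
  expect_equal(space_averaged_wss(fs), space_averaged_wss(f))
  expect_equal(low_wss_area_ratio(fs), low_wss_area_ratio(f))
})

test_that("viscosity statistics select wall regions", {
  f <- synthetic_wss_field()
  all_stats <- viscosity_statistics(f)
  expect_true(all_stats$max >= all_stats$median)
  sv <- viscosity_statistics(f, "SV")
  expect_lte(sv$n, all_stats$n)
  expect_error(viscosity_statistics(f, "ABSENT"), "empty")
})

test_that("Jaccard overlap behaves at its extremes", {
  f <- make_field(c(0.05, 0.05, 0.5, 0.5), rep(1, 4))
  f$mu_nw <- c(0.05, 0.05, 0.003, 0.003)
  f <- pvshemo:::as_wss_field(f)
  expect_equal(low_wss_high_viscosity_overlap(f, 0.1, 0.01), 1)
  f$mu_nw <- c(0.003, 0.003, 0.05, 0.05)
  f <- pvshemo:::as_wss_field(f)
  expect_equal(low_wss_high_viscosity_overlap(f, 0.1, 0.01), 0)
})

test_that("metrics report aggregates a solved scenario coherently", {
  tv <- mini_tube()
  rep <- metrics_report(tv$sol, tv$mesh)
  expect_equal(rep$sa_wss, space_averaged_wss(compute_wss(tv$sol, tv$mesh)))
  expect_true(rep$M <= rep$N)
  expect_gte(rep$als, 0); expect_lte(rep$als, 100)
  expect_equal(rep$A_W, tv$mesh$A_W)
  # compute_wss re-derives the same field the solver reported
  f <- compute_wss(tv$sol, tv$mesh)
  expect_equal(f$wss, tv$sol$wall$wss, tolerance = 1e-12)
})
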