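test_that("the canonical study matrix enumerates every scenario once", {
  m <- study_matrix()
  labels <- vapply(m, function(s) s$label, "")
  expect_equal(length(m), 27)                 # 8 types + 18 variations + comp
  expect_false(anyDuplicated(labels) > 0)
  expect_equal(sum(grepl("curved", labels)), 2)
  expect_equal(sum(vapply(m, function(s) s$flow_scale, 0) == 1.3), 1)
  # subsets
  expect_equal(length(study_matrix("types")), 8)
  expect_equal(length(study_matrix("variations")), 18)
  expect_equal(length(study_matrix("compensation")), 1)
})

test_that("an empty matrix yields an empty report", {
  rep <- run_study(list(), verbose = FALSE)
  expect_s3_class(rep, "study_report")
  expect_null(rep$results)
})

test_that("the reduced-order method runs the matrix quickly and caches", {
  scen <- lapply(study_matrix("types", "postoperative"), function(s) {
    s$method <- "network1d"; s
  })
  dir <- withr::local_tempdir()
  rep1 <- run_study(scen, cache_dir = dir, verbose = FALSE)
  expect_equal(nrow(rep1$results), 4)
  expect_true(all(rep1$results$method == "network1d"))
  expect_false(any(rep1$results$failed))
  # rerun with resume: results identical, nothing re-solved
  files_before <- file.info(list.files(dir, full.names = TRUE))$mtime
  rep2 <- run_study(scen, cache_dir = dir, verbose = FALSE)
  files_after <- file.info(list.files(dir, full.names = TRUE))$mtime
  expect_equal(rep2$results$als, rep1$results$als)
  expect_identical(files_before, files_after)
})

test_that("trend checks report missing scenarios as not evaluable", {
  scen <- lapply(study_matrix("types", "postoperative"), function(s) {
    s$method <- "network1d"; s
  })
  rep <- run_study(scen, cache_dir = withr::local_tempdir(), verbose = FALSE)
  tc <- trend_checks(rep)
  expect_true(is.na(tc$pass[tc$check == "+30% tributary flow decreases postop ALS"]))
  expect_false(is.na(tc$pass[grepl("ordering", tc$check)]))
})

test_that("exported tables mirror the canonical schema and JSON round-trips", {
  scen <- lapply(study_matrix(), function(s) { s$method <- "network1d"; s })
  rep <- run_study(scen, cache_dir = withr::local_tempdir(), verbose = FALSE)
  dir <- withr::local_tempdir()
  export_tables(rep, dir)
  ty <- utils::read.csv(file.path(dir, "table_types.csv"), check.names = FALSE)
  expect_equal(names(ty), c("Type", "Condition", "SA-WSS(Pa)", "ALS(%)"))
  expect_equal(nrow(ty), 8)
  va <- utils::read.csv(file.path(dir, "table_variations.csv"), check.names = FALSE)
  expect_equal(nrow(va), 18)
  expect_true(all(va$Condition %in% c("Pre", "Post")))
  rt <- read_study_json(file.path(dir, "study_report.json"))
  expect_equal(rt$results$als, rep$results$als)
  expect_equal(rt$results$label, rep$results$label)
})

test_that("scenario failures are recorded, never dropped", {
  bad <- scenario_spec(1, character(), "preoperative")
  bad$anatomy_type <- 99                      # breaks downstream construction
  rep <- run_study(list(bad), cache_dir = withr::local_tempdir(),
                   verbose = FALSE)
  expect_equal(nrow(rep$results), 1)
  expect_true(rep$results$failed)
  expect_match(rep$results$error, "anatomy_type")
})
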