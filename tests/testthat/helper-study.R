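# The full study matrix is solved once per test session (per-scenario disk
# cache under the session temp directory); several acceptance blocks read
# from the same report.
study_results <- function() {
  cached("study_report", {
    run_study(study_matrix(),
              cache_dir = file.path(tempdir(), "pvshemo-test-cache"),
              verbose = FALSE)
  })
}

# published reference values the scaled-down study is compared against
reference_tables <- function() {
  list(
    sa_wss = c(
      type1_pre = 0.469, type1_pos = 0.252, type2_pre = 0.443,
      type2_pos = 0.236, type3_pre = 0.450, type3_pos = 0.237,
      type4_pre = 0.427, type4_pos = 0.215,
      type1_Am_pre = 0.468, type1_Am_pos = 0.248,
      type1_Ap_pre = 0.469, type1_Ap_pos = 0.253,
      type1_Bm_pre = 0.475, type1_Bm_pos = 0.251,
      type1_Bp_pre = 0.463, type1_Bp_pos = 0.252,
      type1_Cm_pre = 0.492, type1_Cm_pos = 0.290,
      type1_Cp_pre = 0.471, type1_Cp_pos = 0.226,
      type1_Dm_pre = 0.463, type1_Dm_pos = 0.244,
      type1_Dp_pre = 0.473, type1_Dp_pos = 0.258,
      type1_Dpcurved_pre = 0.514, type1_Dpcurved_pos = 0.237),
    als = c(
      type1_pre = 0.74, type1_pos = 21.28, type2_pre = 0.99,
      type2_pos = 23.06, type3_pre = 0.73, type3_pos = 26.48,
      type4_pre = 0.86, type4_pos = 35.19,
      type1_Am_pre = 0.69, type1_Am_pos = 21.54,
      type1_Ap_pre = 0.79, type1_Ap_pos = 20.64,
      type1_Bm_pre = 0.62, type1_Bm_pos = 21.29,
      type1_Bp_pre = 0.70, type1_Bp_pos = 21.32,
      type1_Cm_pre = 0.60, type1_Cm_pos = 13.65,
      type1_Cp_pre = 0.84, type1_Cp_pos = 29.39,
      type1_Dm_pre = 0.90, type1_Dm_pos = 25.12,
      type1_Dp_pre = 0.66, type1_Dp_pos = 15.79,
      type1_Dpcurved_pre = 2.81, type1_Dpcurved_pos = 23.56,
      type1_pos_fs1.30 = 19.10)
  )
}

study_value <- function(report, label, column) {
  r <- report$results
  r[[column]][r$label == label]
}

# full wall-shear field of the type-1 postoperative model (for co-location
# statistics that need per-face data)
type1_post_field <- function() {
  cached("type1_post_field", {
    run_scenario(scenario_spec(1, character(), "postoperative"))$field
  })
}
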