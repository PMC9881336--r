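test_that("TRC files round-trip a synthetic trial", {
  out <- generate_trial(asym_params(n_strides = 3), participant_id = "RT1")
  path <- withr::local_tempfile(fileext = ".trc")
  write_trc(out$trial, path)
  back <- read_trial(path, format = "trc", participant_id = "RT1",
                     belt_speed = out$trial$belt_speed)
  expect_equal(back$sampling_rate, out$trial$sampling_rate)
  for (side in c("left", "right")) {
    for (mk in GAIT_MARKERS) {
      expect_equal(marker_xyz(back, mk, side), marker_xyz(out$trial, mk, side),
                   tolerance = 1e-8)
    }
  }
})

test_that("long CSV files round-trip with metadata", {
  out <- generate_trial(asym_params(n_strides = 3), participant_id = "RT2",
                        group = "stroke", paretic_side = "right")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(out$trial, path)
  back <- read_trial(path, format = "csv")
  expect_equal(back$participant_id, "RT2")
  expect_equal(back$group, "stroke")
  expect_equal(back$paretic_side, "right")
  expect_equal(back$belt_speed, out$trial$belt_speed)
  expect_equal(marker_xyz(back, "lateral_malleolus", "left"),
               marker_xyz(out$trial, "lateral_malleolus", "left"),
               tolerance = 1e-9)
})

test_that("millimetre units are converted to metres on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "#participant_id=U1", "#sampling_rate=100", "#units=mm",
    "trial_id,time_s,marker,side,x,y,z",
    "U1,0.00,lateral_malleolus,right,1000,0,0",
    "U1,0.01,lateral_malleolus,right,1000,0,0"
  ), path)
  tr <- read_trial(path, format = "csv")
  expect_equal(marker_xyz(tr, "lateral_malleolus", "right")[1, ],
               c(x = 1, y = 0, z = 0))
})

test_that("axis remapping is an orthonormal transform", {
  out <- generate_trial(asym_params(n_strides = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(out$trial, path)
  tr <- read_trial(path, format = "csv", axis_map = c(x = "y", y = "-x", z = "z"))
  a0 <- marker_xyz(out$trial, "lateral_malleolus", "left")
  b0 <- marker_xyz(out$trial, "fifth_metatarsal", "left")
  a1 <- marker_xyz(tr, "lateral_malleolus", "left")
  b1 <- marker_xyz(tr, "fifth_metatarsal", "left")
  expect_equal(sqrt(rowSums((a1 - b1)^2)), sqrt(rowSums((a0 - b0)^2)),
               tolerance = 1e-9)
  expect_error(read_trial(path, format = "csv",
                          axis_map = c(x = "x", y = "x", z = "z")),
               "permutation")
})

test_that("a trial without iliac crests loads and only hip hiking is missing", {
  out <- generate_trial(asym_params(n_strides = 8),
                        drop_markers = c("iliac_crest.left", "iliac_crest.right"))
  rec <- compute_gait_metrics(out$trial, filter_cutoff = NULL)
  expect_true(is.na(rec$hip_hike_deg))
  expect_false(anyNA(rec[, c("sla", "dlsta", "slsta", "knee_flex_deg",
                             "tla_deg", "circumduction_m")]))
})

test_that("metadata reading validates ranges, duplicates and speeds", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "participant_id,group,paretic_side,age,le_fugl_meyer,speed_1,speed_2,speed_3,speed_4",
    "A,stroke,left,66,18,0.80,0.90,1.10,1.30",
    "B,stroke,right,71,19,0.70,0.80,0.90,-"
  ), path)
  meta <- read_metadata(path)
  expect_equal(meta$le_fugl_meyer, c(18, 19))
  expect_equal(meta$speeds[[1]], c(0.80, 0.90, 1.10, 1.30))
  expect_equal(meta$speeds[[2]], c(0.70, 0.80, 0.90))  # "-" cell dropped

  writeLines(c("participant_id,le_fugl_meyer,speed_1", "A,40,0.8"), path)
  expect_error(read_metadata(path), "0-34")
  writeLines(c("participant_id,le_fugl_meyer,speed_1", "A,20,0.8", "A,21,0.9"), path)
  expect_error(read_metadata(path), "duplicate")
})

test_that("metrics tables round-trip, preserve column order and flag duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  recs <- tibble::tibble(
    participant_id = c("A", "A", "B"), group = c("stroke", "stroke", "neurotypical"),
    speed_mps = c(0.8, 1.0, 1.1),
    sla = c(0.21, 0.18, 0.02), dlsta = c(0.3, 0.28, 0.01), slsta = c(0.1, 0.09, 0.005),
    knee_flex_deg = c(41.2, 44.8, 63.1), tla_deg = c(12.5, 13.7, 22.3),
    circumduction_m = c(0.031, 0.029, 0.006), hip_hike_deg = c(NA, 6.2, 1.1),
    n_strides = c(24L, 25L, 28L)
  )
  write_metrics_table(recs, path)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  expect_equal(gsub('"', "", header),
               c("participant_id", "group", "speed_mps", "sla", "dlsta", "slsta",
                 "knee_flex_deg", "tla_deg", "circumduction_m", "hip_hike_deg",
                 "n_strides"))
  back <- read_metrics_table(path)
  expect_true(is.na(back$hip_hike_deg[1]))
  expect_equal(back$knee_flex_deg, recs$knee_flex_deg, tolerance = 1e-9)

  write_metrics_table(recs[0, ], path)
  expect_equal(nrow(read_metrics_table(path)), 0)

  dup <- recs; dup$speed_mps[2] <- 0.8
  expect_error(write_metrics_table(dup, path), "duplicate")
})

test_that("ground truth writes as JSON and c3d input is gated", {
  out <- generate_trial(gait_params(n_strides = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(out$truth, path)
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(gt$metrics$sla, 0)
  expect_equal(gt$params$stride_time, out$truth$params$stride_time)
  expect_error(read_trial(path, format = "c3d"), "C3D")
})

test_that("YAML mapping configs feed read_trial", {
  cfg_path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "axis_map:", "  x: y", "  y: '-x'", "  z: z",
    "marker_name_map:", "  ANK: lateral_malleolus"
  ), cfg_path)
  cfg <- read_mapping_config(cfg_path)
  expect_equal(unname(cfg$axis_map["y"]), "-x")
  expect_equal(unname(cfg$marker_name_map[["ANK"]]), "lateral_malleolus")
})
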