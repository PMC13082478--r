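small_cfg <- function(..., seed = 1L)
  phantom_config(shape = c(48, 48, 24), n_studies = 3, n_lesions = 2,
                 diam_range_mm = c(4, 9), seed = seed, ...)

test_that("flat trajectories render identical masks and seeds reproduce bits", {
  traj <- data.frame(type = c("flat", "flat"), pct = 0, t_event = NA)
  ph <- generate_phantom(small_cfg(trajectories = traj, seed = 5))
  expect_identical(ph$volumes[[1]]$data, ph$volumes[[2]]$data)
  expect_identical(ph$volumes[[1]]$data, ph$volumes[[3]]$data)

  ph2 <- generate_phantom(small_cfg(trajectories = traj, seed = 5))
  for (t in 1:3) expect_identical(ph$volumes[[t]]$data, ph2$volumes[[t]]$data)
  ph3 <- generate_phantom(small_cfg(trajectories = traj, seed = 6))
  expect_false(identical(ph$volumes[[1]]$data, ph3$volumes[[1]]$data))
})

test_that("a growing lesion measures its analytic diameter within a voxel", {
  traj <- data.frame(type = "grow", pct = 30, t_event = NA)
  cfg <- phantom_config(shape = c(48, 48, 24), n_studies = 3, n_lesions = 1,
                        diam_range_mm = c(8, 8), trajectories = traj, seed = 2)
  ph <- generate_phantom(cfg)
  expect_equal(ph$truth$true_diam_mm[ph$truth$study_index == 1], 10.4)
  les <- extract_lesions(ph$volumes[[2]])
  expect_length(les, 1)
  expect_lt(abs(les[[1]]$dmax$longest_mm - 10.4), 1)
})

test_that("placement respects separation or fails loudly", {
  cfg <- phantom_config(shape = c(30, 30, 16), n_studies = 3, n_lesions = 6,
                        diam_range_mm = c(8, 10), seed = 3)
  expect_error(generate_phantom(cfg), "separation|too small")

  ph <- generate_phantom(small_cfg(seed = 11))
  centers <- unique(ph$truth[, c("lesion", "center_x_mm", "center_y_mm", "center_z_mm")])
  dmax_per <- tapply(ph$truth$true_diam_mm, ph$truth$lesion, max)
  for (i in seq_len(nrow(centers) - 1)) for (j in (i + 1):nrow(centers)) {
    sep <- sqrt(sum((centers[i, 2:4] - centers[j, 2:4])^2))
    expect_gte(sep, 2 * max(dmax_per[[i]], dmax_per[[j]]))
  }
})

test_that("simulated reader detection follows the logistic model", {
  # empirical detection rate at d == midpoint is ~0.5
  truth <- data.frame(patient_id = "P", lesion = 1:1000, study_index = 0,
                      center_x_mm = 0, center_y_mm = 0, center_z_mm = 0,
                      true_diam_mm = 5, trajectory = "flat", true_label = "NA")
  r <- simulate_reader(truth, detect_midpoint_mm = 5, detect_slope = 1,
                       noise_sd_mm = 0, seed = 77)
  phat <- nrow(r) / 1000
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / 1000) + 0.01)

  # far above midpoint: essentially always detected
  truth$true_diam_mm <- 12
  r2 <- simulate_reader(truth, detect_midpoint_mm = 3, detect_slope = 1,
                        noise_sd_mm = 0.5, seed = 78)
  expect_gt(nrow(r2) / 1000, 0.99)
})

test_that("segmenter degradation modes behave as configured", {
  ph <- generate_phantom(small_cfg(seed = 21))
  # all parameters zero: identity
  same <- simulate_segmenter(ph, small_miss_midpoint_mm = 0, boundary_jitter_vox = 0,
                             fp_rate_per_study = 0, seed = 1)
  for (t in 1:3) expect_identical(same[[t]]$data, ph$volumes[[t]]$data)

  # false positive count across many studies is Poisson-consistent
  n_fp <- 0L; n_studies <- 0L
  for (s in 1:17) {
    phs <- generate_phantom(small_cfg(seed = 500 + s,
      trajectories = data.frame(type = c("flat", "flat"), pct = 0, t_event = NA)))
    deg <- simulate_segmenter(phs, small_miss_midpoint_mm = 0,
                              boundary_jitter_vox = 0, fp_rate_per_study = 2,
                              seed = 600 + s)
    for (t in 1:3) {
      n_fp <- n_fp + (length(extract_lesions(deg[[t]])) - 2L)
      n_studies <- n_studies + 1L
    }
  }
  lambda <- 2 * n_studies
  expect_lt(abs(n_fp - lambda), 4 * sqrt(lambda))

  # one-voxel jitter keeps strong overlap with the truth
  traj <- data.frame(type = "flat", pct = 0, t_event = NA)
  cfg <- phantom_config(shape = c(48, 48, 24), n_studies = 3, n_lesions = 1,
                        diam_range_mm = c(10, 10), trajectories = traj, seed = 31)
  ph2 <- generate_phantom(cfg)
  deg2 <- simulate_segmenter(ph2, small_miss_midpoint_mm = 0, boundary_jitter_vox = 1,
                             fp_rate_per_study = 0, seed = 32)
  expect_gt(dice_patient(deg2, ph2$volumes)$dsc, 0.7)
})

test_that("phantoms write a complete, reloadable directory", {
  dir <- file.path(withr::local_tempdir(), "ph")
  ph <- generate_phantom(small_cfg(seed = 41))
  write_phantom(ph, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  v <- read_label_volume(file.path(dir, "study_00.nii.gz"))
  expect_identical(v$data, ph$volumes[[1]]$data)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 41)
})

test_that("end-to-end pipeline recovers every trajectory-implied label", {
  traj <- data.frame(type = c("grow", "shrink", "vanish", "flat"),
                     pct = c(30, 40, 0, 0), t_event = c(NA, NA, 1, NA))
  cfg <- phantom_config(shape = c(80, 80, 40), n_studies = 3, n_lesions = 4,
                        diam_range_mm = c(9, 9), trajectories = traj, seed = 71)
  ph <- generate_phantom(cfg)
  series <- lapply(seq_along(ph$volumes), function(i)
    list(study_index = i - 1L, lesions = extract_lesions(ph$volumes[[i]])))
  tracks <- build_tracks(series)
  expect_length(tracks, 4)
  for (tr in tracks) {
    resp <- classify_track(tr)
    les0 <- series[[1]]$lesions[[which(vapply(series[[1]]$lesions,
      function(l) l$lesion_id, integer(1)) == tr$measurements$lesion_id[1])]]
    tt <- ph$truth[ph$truth$study_index == 0, ]
    d2 <- sqrt((tt$center_x_mm - les0$centroid_mm[1])^2 +
               (tt$center_y_mm - les0$centroid_mm[2])^2 +
               (tt$center_z_mm - les0$centroid_mm[3])^2)
    lesion_truth <- ph$truth[ph$truth$lesion == tt$lesion[which.min(d2)], ]
    for (t in 1:2) {
      expect_equal(resp$label[resp$study_index == t],
                   lesion_truth$true_label[lesion_truth$study_index == t],
                   info = paste("trajectory", lesion_truth$trajectory[1], "t", t))
    }
  }
})
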