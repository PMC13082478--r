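#' Phantom configuration
#'
#' The phantom emulates the cohort shape of a longitudinal brain-metastasis
#' series: 3-8 studies per patient at roughly quarterly intervals, a handful
#' of well-separated ellipsoidal enhancing lesions per patient with
#' equatorial diameters spanning both the sub-5 mm and measurable strata
#' (default 3-15 mm, bracketing a typical ~9 mm average), rendered on a
#' 1 mm-in-plane, 1 mm-slice grid. Each lesion follows one trajectory:
#' `flat`, `grow` (compounding `pct` percent per study), `shrink`
#' (compounding), `vanish` (disappears at study `t_event`) or `appear`
#' (absent before `t_event`).
#'
#' @param shape,spacing grid geometry (see [image_grid()]).
#' @param n_studies studies per patient, 3..8.
#' @param n_lesions lesions per patient.
#' @param diam_range_mm range baseline equatorial diameters are drawn from.
#' @param trajectories optional data.frame (`type`, `pct`, `t_event`), one
#'   row per lesion; sampled when `NULL`.
#' @param study_interval_days days between consecutive studies.
#' @param z_axis_ratio through-plane to in-plane semi-axis ratio of the
#'   rendered ellipsoids (1 = spheres; equatorial DMAX is unaffected).
#' @param seed RNG seed driving every random choice.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(96, 96, 48), spacing = c(1, 1, 1),
                           n_studies = 4L, n_lesions = 3L,
                           diam_range_mm = c(3, 15), trajectories = NULL,
                           study_interval_days = 90, z_axis_ratio = 1,
                           seed = 1L) {
  if (n_studies < 3L || n_studies > 8L)
    stop("n_studies must be 3..8 (longitudinal series of 3 to 8 MRIs)")
  if (any(diam_range_mm <= 0)) stop("diameters must be positive")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 n_studies = as.integer(n_studies),
                 n_lesions = as.integer(n_lesions),
                 diam_range_mm = as.numeric(diam_range_mm),
                 trajectories = trajectories,
                 study_interval_days = study_interval_days,
                 z_axis_ratio = z_axis_ratio, seed = as.integer(seed)),
            class = "phantom_config")
}

sample_trajectories <- function(n) {
  types <- sample(c("flat", "grow", "shrink", "vanish", "appear"), n,
                  replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.15, 0.15))
  data.frame(type = types,
             pct = ifelse(types == "grow", stats::runif(n, 25, 40),
                   ifelse(types == "shrink", stats::runif(n, 31, 60), 0)),
             t_event = ifelse(types %in% c("vanish", "appear"),
                              sample(1:2, n, replace = TRUE), NA_integer_))
}

true_diameter_at <- function(traj, d0, t) {
  switch(traj$type,
         flat = d0,
         grow = d0 * (1 + traj$pct / 100)^t,
         shrink = d0 * (1 - traj$pct / 100)^t,
         vanish = if (t < traj$t_event) d0 else 0,
         appear = if (t < traj$t_event) 0 else d0,
         stop("unknown trajectory type ", traj$type))
}

# Closed-form response label implied by the trajectory itself — kept
# independent of classify_track so label recovery is a real check.
true_label_at <- function(traj, t, cfg = response_config()) {
  if (t == 0L) return(if (traj$type == "appear" && traj$t_event > 0) "absent" else "NA")
  switch(traj$type,
         flat = "SD",
         grow = if (((1 + traj$pct / 100)^t - 1) * 100 > cfg$pd_threshold_pct) "PD" else "SD",
         shrink = if (((1 - traj$pct / 100)^t - 1) * 100 <= cfg$pr_threshold_pct) "PR" else "SD",
         vanish = if (t < traj$t_event) "SD" else "CR",
         appear = if (t < traj$t_event) "absent" else if (t == traj$t_event) "NEW" else "SD")
}

render_ellipsoid <- function(data, grid, center_mm, diam_mm, z_ratio, value = 1L) {
  if (diam_mm <= 0) return(data)
  a <- diam_mm / 2
  c_ax <- a * z_ratio
  sp <- grid$spacing
  lo <-pmax(1L, floor(center_mm / sp - c(a, a, c_ax) / sp) + 1L)
  hi <- pmin(grid$shape, ceiling(center_mm / sp + c(a, a, c_ax) / sp) + 1L)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx <- ((xs - 1) * sp[1] - center_mm[1]) / a
  dy <- ((ys - 1) * sp[2] - center_mm[2]) / a
  dz <- ((zs - 1) * sp[3] - center_mm[3]) / c_ax
  inside <- outer(outer(dx^2, dy^2, "+"), dz^2, "+") <= 1 + 1e-12
  sub <- data[xs, ys, zs, drop = FALSE]
  sub[inside] <- value
  data[xs, ys, zs] <- sub
  data
}

# Pairwise separation: centers i, j at least 2 x max(own max diameters)
# apart, so lesions never become confluent at any timepoint.
place_centers <- function(cfg, max_diam_per_lesion) {
  ord <- order(-max_diam_per_lesion)      # place the bulkiest first
  margin <- max_diam_per_lesion / 2 + 2
  centers <- matrix(NA_real_, cfg$n_lesions, 3)
  for (i in ord) {
    lo <- rep(margin[i], 3)
    hi <- (cfg$shape - 1) * cfg$spacing - margin[i]
    if (any(hi <= lo))
      stop("grid too small for a lesion of diameter ", round(max_diam_per_lesion[i], 1),
           " mm; enlarge the phantom grid")
    placed <- FALSE
    done <- which(!is.na(centers[, 1]))
    for (attempt in seq_len(1000L)) {
      cand <- stats::runif(3, lo, hi)
      sep_ok <- length(done) == 0L ||
        all(sqrt(rowSums(sweep(centers[done, , drop = FALSE], 2, cand)^2)) >=
              2 * pmax(max_diam_per_lesion[done], max_diam_per_lesion[i]))
      if (sep_ok) {
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place lesion ", i,
                      " with >= 2x max-diameter separation after 1000 attempts; ",
                      "enlarge the grid or shrink the lesions")
  }
  centers
}

#' Generate a longitudinal lesion phantom
#'
#' Renders one patient's series of label volumes with known lesion centers,
#' per-timepoint equatorial diameters and trajectory-implied response
#' labels. Lesions are digital ellipsoids placed with at least twice the
#' maximum diameter between centers (no confluence); generation is
#' bit-reproducible for a given seed.
#'
#' @param cfg a [phantom_config()].
#' @param patient_id patient identifier stamped on the volumes.
#' @return List with `volumes` (one [label_volume()] per study), `truth`
#'   (data.frame: lesion, study_index, center mm, true_diam_mm, trajectory,
#'   true_label), `dates` (`Date` per study), and `config`.
#' @export
generate_phantom <- function(cfg = phantom_config(), patient_id = "PHANTOM-1") {
  stopifnot(inherits(cfg, "phantom_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  traj <- cfg$trajectories
  if (is.null(traj)) traj <- sample_trajectories(cfg$n_lesions)
  stopifnot(nrow(traj) == cfg$n_lesions)
  d0 <- stats::runif(cfg$n_lesions, cfg$diam_range_mm[1], cfg$diam_range_mm[2])

  diam <- matrix(0, cfg$n_lesions, cfg$n_studies)
  for (i in seq_len(cfg$n_lesions)) for (t in seq_len(cfg$n_studies))
    diam[i, t] <- true_diameter_at(traj[i, ], d0[i], t - 1L)
  centers <- place_centers(cfg, pmax(apply(diam, 1, max), 1))

  grid <- image_grid(cfg$shape, cfg$spacing)
  volumes <- vector("list", cfg$n_studies)
  for (t in seq_len(cfg$n_studies)) {
    data <- array(0L, dim = cfg$shape)
    for (i in seq_len(cfg$n_lesions))
      data <- render_ellipsoid(data, grid, centers[i, ], diam[i, t],
                               cfg$z_axis_ratio, value = 1L)
    volumes[[t]] <- label_volume(data, grid, study_index = t - 1L,
                                 patient_id = patient_id)
  }

  dates <- as.Date("2020-01-01") + (seq_len(cfg$n_studies) - 1L) * cfg$study_interval_days
  for (t in seq_len(cfg$n_studies)) volumes[[t]]$study_date <- dates[t]

  truth <- do.call(rbind, lapply(seq_len(cfg$n_lesions), function(i) {
    data.frame(patient_id = patient_id, lesion = i,
               study_index = seq_len(cfg$n_studies) - 1L,
               center_x_mm = centers[i, 1], center_y_mm = centers[i, 2],
               center_z_mm = centers[i, 3],
               true_diam_mm = diam[i, ],
               trajectory = traj$type[i],
               true_label = vapply(seq_len(cfg$n_studies) - 1L,
                                   function(t) true_label_at(traj[i, ], t), character(1)))
  }))
  list(volumes = volumes, truth = truth, dates = dates, config = cfg)
}

#' Simulate a human reader over phantom truth
#'
#' Each truly present lesion is detected with probability
#' `plogis((d - detect_midpoint_mm) / detect_slope)` (small lesions are
#' missed more often, emulating observed reader behavior); detected lesions
#' receive Gaussian measurement noise on both diameters. A non-positive
#' midpoint yields a perfect detector.
#'
#' @param truth phantom truth table (see [generate_phantom()]).
#' @param detect_midpoint_mm diameter at which detection probability is 0.5.
#' @param detect_slope logistic scale in mm.
#' @param noise_sd_mm SD of additive measurement noise.
#' @param seed RNG seed.
#' @param reader_id label stamped on the measurements.
#' @return Reader measurement data.frame (see [read_reader_csv()]).
#' @export
simulate_reader <- function(truth, detect_midpoint_mm = 3, detect_slope = 1,
                            noise_sd_mm = 0.5, seed = 1L, reader_id = "R1") {
  stopifnot(detect_slope > 0, noise_sd_mm >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pres <- truth[truth$true_diam_mm > 0, , drop = FALSE]
  p <- if (detect_midpoint_mm <= 0) rep(1, nrow(pres)) else
    stats::plogis((pres$true_diam_mm - detect_midpoint_mm) / detect_slope)
  hit <- stats::runif(nrow(pres)) < p
  det <- pres[hit, , drop = FALSE]
  data.frame(reader_id = reader_id,
             patient_id = det$patient_id,
             study_index = det$study_index,
             lesion_ref = det$lesion,
             longest_mm = pmax(0, det$true_diam_mm + stats::rnorm(nrow(det), 0, noise_sd_mm)),
             perpendicular_mm = pmax(0, det$true_diam_mm + stats::rnorm(nrow(det), 0, noise_sd_mm)))
}

#' Simulate a degraded segmentation model
#'
#' Re-renders each study with three STU-Net-like error modes: truly present
#' lesions are dropped with probability
#' `plogis((small_miss_midpoint_mm - d) / miss_slope)` (small lesions miss
#' more), kept lesions have their radius jittered by up to
#' `boundary_jitter_vox` voxels, and `Poisson(fp_rate_per_study)` spurious
#' small blobs are added within the placement region. All parameters at 0
#' reproduce the input exactly.
#'
#' @param phantom output of [generate_phantom()].
#' @param small_miss_midpoint_mm diameter with 50% miss probability
#'   (<= 0 disables misses).
#' @param miss_slope logistic scale in mm.
#' @param boundary_jitter_vox maximum radius jitter, voxels.
#' @param fp_rate_per_study expected spurious lesions per study.
#' @param seed RNG seed.
#' @return List of degraded [label_volume()]s, one per study, with a
#'   `dropped` attribute (data.frame lesion/study of missed lesions).
#' @export
simulate_segmenter <- function(phantom, small_miss_midpoint_mm = 4,
                               miss_slope = 1, boundary_jitter_vox = 1,
                               fp_rate_per_study = 0.5, seed = 1L) {
  stopifnot(miss_slope > 0, boundary_jitter_vox >= 0, fp_rate_per_study >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cfg <- phantom$config
  grid <- phantom$volumes[[1]]$grid
  truth <- phantom$truth
  lesions <- unique(truth$lesion)
  centers <- truth[match(lesions, truth$lesion),
                   c("center_x_mm", "center_y_mm", "center_z_mm")]
  dropped <- list()
  out <- vector("list", length(phantom$volumes))
  for (t in seq_along(phantom$volumes)) {
    tt <- t - 1L
    data <- array(0L, dim = grid$shape)
    for (i in seq_along(lesions)) {
      d <- truth$true_diam_mm[truth$lesion == lesions[i] & truth$study_index == tt]
      if (d <= 0) next
      pmiss <- if (small_miss_midpoint_mm <= 0) 0 else
        stats::plogis((small_miss_midpoint_mm - d) / miss_slope)
      if (stats::runif(1) < pmiss) {
        dropped[[length(dropped) + 1L]] <- data.frame(lesion = lesions[i], study_index = tt)
        next
      }
      jit <- if (boundary_jitter_vox > 0)
        sample(seq(-boundary_jitter_vox, boundary_jitter_vox), 1L) else 0L
      dj <- max(d + 2 * jit * min(grid$spacing[1:2]), min(grid$spacing))
      data <- render_ellipsoid(data, grid, as.numeric(centers[i, ]), dj,
                               cfg$z_axis_ratio, value = 1L)
    }
    n_fp <- if (fp_rate_per_study > 0) stats::rpois(1, fp_rate_per_study) else 0L
    if (n_fp > 0) {
      lo <- rep(6, 3); hi <- (grid$shape - 1) * grid$spacing - 6
      for (f in seq_len(n_fp)) {
        for (attempt in 1:100) {
          cand <- stats::runif(3, lo, hi)
          dist_ok <- all(sqrt(rowSums(sweep(as.matrix(centers), 2, cand)^2)) >
                           max(truth$true_diam_mm) / 2 + 4)
          if (dist_ok) break
        }
        data <- render_ellipsoid(data, grid, cand, stats::runif(1, 2, 4),
                                 cfg$z_axis_ratio, value = 1L)
      }
    }
    vol <- phantom$volumes[[t]]
    vol$data <- data
    out[[t]] <- vol
  }
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(lesion = integer(0), study_index = integer(0))
  out
}

#' Write a phantom to disk
#'
#' NIfTI volumes, a truth CSV, and a JSON manifest recording the seed and
#' configuration, so any run can be reproduced exactly.
#'
#' @param phantom output of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(phantom$volumes))
  for (t in seq_along(phantom$volumes)) {
    paths[t] <- file.path(dir, sprintf("study_%02d.nii.gz", t - 1L))
    write_label_volume(phantom$volumes[[t]], paths[t])
  }
  utils::write.csv(phantom$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- phantom$config
  manifest <- list(tool = "neurotrackr", seed = cfg$seed,
                   shape = cfg$shape, spacing = cfg$spacing,
                   n_studies = cfg$n_studies, n_lesions = cfg$n_lesions,
                   diam_range_mm = cfg$diam_range_mm,
                   study_interval_days = cfg$study_interval_days,
                   dates = as.character(phantom$dates), volumes = basename(paths))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
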