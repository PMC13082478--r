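#' Per-lesion response assessment configuration
#'
#' Thresholds for the modified per-lesion RANO-BM rules: progressive disease
#' (PD) when the longest diameter grows more than `pd_threshold_pct` over
#' the nadir, partial response (PR) when it falls to `pr_threshold_pct` or
#' below relative to baseline, complete response (CR) on disappearance. The
#' conventional >= 5 mm absolute-change requirement is deliberately dropped:
#' sub-5 mm lesions are assessed here. The observation endpoint defaults to
#' 12 months after the first study.
#'
#' @param pd_threshold_pct positive percent growth over nadir defining PD.
#' @param pr_threshold_pct negative percent change from baseline defining PR.
#' @param endpoint_months observation endpoint, months after the first study.
#' @return A `response_config` list.
#' @export
response_config <- function(pd_threshold_pct = 20, pr_threshold_pct = -30,
                            endpoint_months = 12) {
  if (!(pd_threshold_pct > 0 && pr_threshold_pct < 0))
    stop("need pd_threshold_pct > 0 > pr_threshold_pct")
  structure(list(pd_threshold_pct = pd_threshold_pct,
                 pr_threshold_pct = pr_threshold_pct,
                 endpoint_months = endpoint_months),
            class = "response_config")
}

RESPONSE_LEVELS <- c("CR", "PR", "SD", "PD", "NEW", "NA")

#' Classify a lesion track's response at every timepoint
#'
#' Per-lesion adaptation of RANO-BM target-lesion logic collapsed to a
#' single lesion: the baseline is the longest diameter at first appearance;
#' the nadir at time t is the smallest longest diameter over present
#' timepoints strictly before t (baseline included). At each timepoint
#' after the first: PD if growth over the nadir exceeds the PD threshold
#' (or the lesion reappears after an absence — CR is reversible, and any
#' regrowth from a zero-diameter nadir is PD); else CR if the lesion is
#' absent or measures 0; else PR if the change from baseline is at or below
#' the PR threshold; else SD. The first timepoint is labelled NA for tracks
#' present at the series baseline and NEW for tracks appearing later.
#'
#' @param track a [build_tracks()] track.
#' @param cfg a [response_config()].
#' @param baseline_study study index of the series baseline (default 0);
#'   tracks with `first_seen` beyond it are NEW at first appearance.
#' @return `data.frame(study_index, label, basis_pct_from_baseline,
#'   basis_pct_from_nadir)`, one row per track measurement.
#' @export
classify_track <- function(track, cfg = response_config(), baseline_study = 0L) {
  meas <- track$measurements
  if (is.null(meas) || nrow(meas) == 0L) stop("empty track")
  present <- !is.na(meas$lesion_id) & !is.na(meas$longest_mm)
  if (!present[1]) stop("track must start with a present measurement")

  n <- nrow(meas)
  label <- character(n)
  pct_base <- rep(NA_real_, n)
  pct_nadir <- rep(NA_real_, n)
  baseline_d <- meas$longest_mm[1]
  label[1] <- if (track$first_seen > baseline_study) "NEW" else "NA"

  if (n > 1L) for (t in 2:n) {
    prior <- seq_len(t - 1L)
    prior_present <- prior[present[prior]]
    had_absence <- any(!present[prior] | meas$longest_mm[prior] == 0, na.rm = TRUE)
    nadir_d <- min(meas$longest_mm[prior_present])
    curr <- meas$longest_mm[t]
    is_present <- present[t] && curr > 0
    if (is_present) {
      pct_base[t] <- percent_change(curr, baseline_d)
      pct_nadir[t] <- percent_change(curr, nadir_d)
    }
    label[t] <-
      if (!is_present) "CR"
      else if (had_absence) "PD"                         # reappearance after CR
      else if (nadir_d == 0) "PD"                        # regrowth from zero nadir
      else if (pct_nadir[t] > cfg$pd_threshold_pct) "PD"
      else if (baseline_d > 0 && pct_base[t] <= cfg$pr_threshold_pct) "PR"
      else "SD"
  }
  data.frame(study_index = meas$study_index, label = label,
             basis_pct_from_baseline = pct_base,
             basis_pct_from_nadir = pct_nadir)
}

#' Response at the observation endpoint
#'
#' Returns the track's response label at the latest study falling within
#' `endpoint_months` after the series' first study (months are converted to
#' days as months/12 x 365.25), or at the last available study when
#' follow-up is shorter. A track with no classified timepoint beyond its
#' first measurement returns NA.
#'
#' @param track a classified track, or one to classify with `cfg`.
#' @param cfg a [response_config()].
#' @param study_dates `Date` vector of study dates.
#' @param study_indices study indices aligned with `study_dates` (defaults
#'   to `0:(n-1)`).
#' @param baseline_study forwarded to [classify_track()].
#' @return One-row data.frame (study_index, label, ...) or `NA` label row.
#' @export
endpoint_response <- function(track, cfg = response_config(), study_dates,
                              study_indices = seq_along(study_dates) - 1L,
                              baseline_study = 0L) {
  if (length(study_dates) != length(study_indices))
    stop("study_dates and study_indices lengths differ")
  study_dates <- as.Date(study_dates)
  resp <- classify_track(track, cfg, baseline_study = baseline_study)
  cutoff <- min(study_dates) + cfg$endpoint_months / 12 * 365.25
  eligible_idx <- study_indices[study_dates <= cutoff]
  cand <- resp[resp$study_index %in% eligible_idx &
                 resp$study_index > resp$study_index[1], , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(study_index = NA_integer_, label = "NA",
                      basis_pct_from_baseline = NA_real_,
                      basis_pct_from_nadir = NA_real_))
  cand <- cand[which.max(cand$study_index), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}
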