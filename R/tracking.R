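#' Percent change between two diameters
#'
#' `100 * (curr - prior) / prior`; undefined (NA) when the prior diameter is
#' not positive.
#'
#' @param curr_mm,prior_mm diameters in mm.
#' @return Signed percent change, or `NA_real_` if `prior_mm <= 0`.
#' @export
percent_change <- function(curr_mm, prior_mm) {
  ifelse(!is.na(prior_mm) & prior_mm > 0 & !is.na(curr_mm),
         100 * (curr_mm - prior_mm) / prior_mm, NA_real_)
}

pair_score_matrix <- function(prev, curr, gate_mm) {
  np <- length(prev); nc <- length(curr)
  S <- matrix(-Inf, np, nc)
  if (np == 0L || nc == 0L) return(S)
  lin_prev <- lapply(prev, lesion_linear_idx)
  lin_curr <- lapply(curr, lesion_linear_idx)
  for (i in seq_len(np)) {
    for (j in seq_len(nc)) {
      ov <- length(intersect(lin_prev[[i]], lin_curr[[j]]))
      d <- sqrt(sum((prev[[i]]$centroid_mm - curr[[j]]$centroid_mm)^2))
      if (ov > 0) {
        S[i, j] <- ov * 1e6 - d          # overlap dominates, distance breaks ties
      } else if (d <= gate_mm) {
        S[i, j] <- (gate_mm - d) + 1e-6  # gated rescue for overlap-free pairs
      }
    }
  }
  S
}

#' Match lesions between two timepoints
#'
#' Globally optimal one-to-one assignment between the lesions of two
#' co-registered studies. The score of a pair is its voxel overlap count;
#' among equal-overlap solutions the smaller centroid distance wins.
#' Overlap-free pairs are admissible only within a centroid-distance gate
#' (default 10 mm), which rescues small lesions whose registered footprints
#' barely miss. Leftover lesions are reported unmatched.
#'
#' @param prev,curr lists of lesions (from [extract_lesions()]) on a common
#'   grid.
#' @param gate_mm centroid-distance gate for overlap-free matches.
#' @return A `lesion_matching`: list with `pairs` (2-column matrix of
#'   (prev_lesion_id, curr_lesion_id)), `unmatched_prev`, `unmatched_curr`.
#' @export
match_lesions <- function(prev, curr, gate_mm = 10.0) {
  S <- pair_score_matrix(prev, curr, gate_mm)
  m <- solve_max_matching(S)
  ids_prev <- vapply(prev, function(l) l$lesion_id, integer(1))
  ids_curr <- vapply(curr, function(l) l$lesion_id, integer(1))
  pairs <- cbind(prev_lesion_id = ids_prev[m[, 1]],
                 curr_lesion_id = ids_curr[m[, 2]])
  structure(list(pairs = pairs,
                 unmatched_prev = setdiff(ids_prev, pairs[, 1]),
                 unmatched_curr = setdiff(ids_curr, pairs[, 2]),
                 prev_idx = m[, 1], curr_idx = m[, 2]),
            class = "lesion_matching")
}

empty_measurement_row <- function(study_index) {
  data.frame(study_index = study_index, lesion_id = NA_integer_,
             longest_mm = NA_real_, perpendicular_mm = NA_real_,
             pct_change_long = NA_real_, pct_change_perp = NA_real_)
}

measurement_row <- function(study_index, lesion) {
  dp <- if (is.null(lesion$dmax)) dmax(lesion) else lesion$dmax
  data.frame(study_index = study_index, lesion_id = lesion$lesion_id,
             longest_mm = dp$longest_mm, perpendicular_mm = dp$perpendicular_mm,
             pct_change_long = NA_real_, pct_change_perp = NA_real_)
}

#' Build longitudinal lesion tracks
#'
#' Chains [match_lesions()] between consecutive studies of one patient. A
#' current-study lesion with no match opens a new track (`first_seen` = that
#' study); a track with no match records an absent measurement and stays
#' eligible to re-match at later studies via its last known lesion footprint
#' (supporting vanish-and-regrow patterns). Per-diameter percent changes are
#' computed against the immediately prior study of the track. Track ids are
#' assigned by (first_seen, descending volume at first appearance).
#'
#' @param series list of `list(study_index =, lesions =)` entries with
#'   strictly increasing study indices, all lesions on a common grid.
#' @param gate_mm forwarded to [match_lesions()].
#' @param patient_id patient identifier for the resulting tracks.
#' @return List of `lesion_track` objects, each with `track_id`,
#'   `patient_id`, `first_seen`, `measurements` (one data.frame row per
#'   study since first appearance) and an empty `response` slot (see
#'   [classify_track()]).
#' @export
build_tracks <- function(series, gate_mm = 10.0, patient_id = NULL) {
  if (length(series) == 0L) stop("series must contain at least one study")
  idx <- vapply(series, function(s) as.integer(s$study_index), integer(1))
  if (anyDuplicated(idx)) stop("duplicate study_index in series")
  if (is.unsorted(idx, strictly = TRUE)) stop("study indices must be strictly increasing")
  if (is.null(patient_id)) {
    patient_id <- "P0"
    for (s in series) for (l in s$lesions) {
      if (!is.null(l$patient_id)) patient_id <- l$patient_id
    }
  }

  tracks <- list()   # each: list(first_seen, footprint (lesion), measurements, first_volume)
  for (s in seq_along(series)) {
    t <- idx[s]
    curr <- series[[s]]$lesions
    if (length(tracks) == 0L) {
      for (l in curr) {
        tracks[[length(tracks) + 1L]] <- list(first_seen = t, footprint = l,
                                              first_volume = l$volume_mm3,
                                              measurements = measurement_row(t, l))
      }
      next
    }
    footprints <- lapply(seq_along(tracks), function(k) {
      fp <- tracks[[k]]$footprint
      fp$lesion_id <- k               # relabel so matching reports track slots
      fp
    })
    m <- match_lesions(footprints, curr, gate_mm = gate_mm)
    matched_curr <- integer(0)
    assigned <- rep(NA_integer_, length(tracks))
    if (nrow(m$pairs) > 0L) {
      assigned[m$pairs[, 1]] <- m$curr_idx
      matched_curr <- m$curr_idx
    }
    for (k in seq_along(tracks)) {
      if (!is.na(assigned[k])) {
        l <- curr[[assigned[k]]]
        tracks[[k]]$measurements <- rbind(tracks[[k]]$measurements,
                                          measurement_row(t, l))
        tracks[[k]]$footprint <- l
      } else {
        tracks[[k]]$measurements <- rbind(tracks[[k]]$measurements,
                                          empty_measurement_row(t))
      }
    }
    for (j in setdiff(seq_along(curr), matched_curr)) {
      l <- curr[[j]]
      tracks[[length(tracks) + 1L]] <- list(first_seen = t, footprint = l,
                                            first_volume = l$volume_mm3,
                                            measurements = measurement_row(t, l))
    }
  }

  fs <- vapply(tracks, function(tr) tr$first_seen, integer(1))
  fv <- vapply(tracks, function(tr) tr$first_volume, numeric(1))
  ord <- order(fs, -fv)
  out <- vector("list", length(tracks))
  for (r in seq_along(ord)) {
    tr <- tracks[[ord[r]]]
    meas <- tr$measurements
    rownames(meas) <- NULL
    meas$pct_change_long <- c(NA_real_, percent_change(
      meas$longest_mm[-1], meas$longest_mm[-nrow(meas)]))
    meas$pct_change_perp <- c(NA_real_, percent_change(
      meas$perpendicular_mm[-1], meas$perpendicular_mm[-nrow(meas)]))
    out[[r]] <- structure(list(track_id = r, patient_id = patient_id,
                               first_seen = tr$first_seen,
                               measurements = meas, response = NULL),
                          class = "lesion_track")
  }
  out
}

#' @export
print.lesion_track <- function(x, ...) {
  pres <- sum(!is.na(x$measurements$lesion_id))
  cat(sprintf("<lesion_track #%d> patient %s, first seen study %d, %d/%d present\n",
              x$track_id, x$patient_id, x$first_seen, pres, nrow(x$measurements)))
  invisible(x)
}
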