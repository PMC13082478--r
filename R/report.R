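fmt1 <- function(x) ifelse(is.na(x), "", sprintf("%.1f", x))

#' Export the lesion tool card
#'
#' One CSV row per (track, study) from each track's first appearance
#' onward: longitudinally aligned lesions with their orthogonal diameters
#' (0.1 mm), percent changes versus the prior study (0.1), and the
#' per-lesion response label. Absent timepoints keep their row with empty
#' diameter cells. Rows are ordered (patient, track, study); the dialect is
#' comma-separated UTF-8 with "." decimals and ISO-8601 dates.
#'
#' @param tracks list of classified tracks (see [classify_track()]; tracks
#'   without a `response` slot get empty response cells).
#' @param path output CSV path.
#' @param study_dates optional `Date` vector, aligned via `study_indices`.
#' @param study_indices study indices matching `study_dates`.
#' @param series_labels optional character vector of series descriptions,
#'   aligned like `study_dates`.
#' @return The exported data.frame, invisibly.
#' @export
export_lesion_card <- function(tracks, path, study_dates = NULL,
                               study_indices = seq_along(study_dates) - 1L,
                               series_labels = NULL) {
  rows <- lapply(tracks, function(tr) {
    meas <- tr$measurements
    resp <- tr$response
    lab <- rep("", nrow(meas))
    if (!is.null(resp))
      lab <- resp$label[match(meas$study_index, resp$study_index)]
    dates <- rep("", nrow(meas))
    series <- rep("", nrow(meas))
    if (!is.null(study_dates)) {
      j <- match(meas$study_index, study_indices)
      dates <- ifelse(is.na(j), "", format(as.Date(study_dates)[j], "%Y-%m-%d"))
      if (!is.null(series_labels)) series <- ifelse(is.na(j), "", series_labels[j])
    }
    data.frame(patient_id = tr$patient_id, track_id = tr$track_id,
               study_index = meas$study_index, study_date = dates,
               series_label = series,
               longest_mm = fmt1(meas$longest_mm),
               perpendicular_mm = fmt1(meas$perpendicular_mm),
               pct_change_long = fmt1(meas$pct_change_long),
               pct_change_perp = fmt1(meas$pct_change_perp),
               response_label = lab)
  })
  card <- do.call(rbind, rows)
  if (is.null(card)) card <- data.frame(patient_id = character(0), track_id = integer(0),
                                        study_index = integer(0), study_date = character(0),
                                        series_label = character(0), longest_mm = character(0),
                                        perpendicular_mm = character(0),
                                        pct_change_long = character(0),
                                        pct_change_perp = character(0),
                                        response_label = character(0))
  card <- card[order(card$patient_id, card$track_id, card$study_index), ]
  rownames(card) <- NULL
  utils::write.csv(card, path, row.names = FALSE, quote = FALSE)
  invisible(card)
}

#' Export the treatment-response curve table
#'
#' Long-format CSV (`track_id`, `study_index`, `longest_mm`) of present
#' measurements, ready for plotting per-lesion diameter trajectories.
#'
#' @param tracks list of tracks.
#' @param path output CSV path.
#' @return The exported data.frame, invisibly.
#' @export
export_response_curve_table <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    meas <- tr$measurements[!is.na(tr$measurements$lesion_id), , drop = FALSE]
    if (nrow(meas) == 0L) return(NULL)
    data.frame(track_id = tr$track_id, study_index = meas$study_index,
               longest_mm = meas$longest_mm)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(track_id = integer(0), study_index = integer(0),
                                      longest_mm = numeric(0))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
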