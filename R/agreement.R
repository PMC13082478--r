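#' Read a reader measurement table
#'
#' CSV with columns `reader_id, patient_id, study_index, lesion_ref,
#' longest_mm, perpendicular_mm`. `lesion_ref` is the shared
#' reference-lesion id; an empty value marks a reader-only finding.
#'
#' @param path CSV path.
#' @return data.frame of reader measurements.
#' @export
read_reader_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("reader_id", "patient_id", "study_index", "lesion_ref",
            "longest_mm", "perpendicular_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("reader CSV is missing columns: ", paste(miss, collapse = ", "))
  if (any(df$longest_mm < 0 | df$perpendicular_mm < 0, na.rm = TRUE))
    stop("diameters must be >= 0")
  df
}

meas_key <- function(df) paste(df$patient_id, df$study_index, df$lesion_ref, sep = "|")

#' Build the consensus reference standard from two readers
#'
#' Lesions found by both readers get their diameters averaged; lesions
#' found by only one reader are kept only when present in the adjudication
#' table (with the adjudicated diameters), mirroring a third-reader
#' verification of disagreements. Single-reader lesions absent from the
#' adjudication are flagged and excluded (returned in the `"flagged"`
#' attribute).
#'
#' @param r1,r2 reader measurement data.frames (see [read_reader_csv()]).
#' @param adjudication adjudicator's measurements for disputed lesions
#'   (same columns; may be empty).
#' @return data.frame reference standard with columns `patient_id`,
#'   `study_index`, `lesion_ref`, `longest_mm`, `perpendicular_mm`,
#'   `source` (`"both"`/`"adjudicated"`), `found_by`.
#' @export
build_consensus <- function(r1, r2, adjudication = NULL) {
  k1 <- meas_key(r1); k2 <- meas_key(r2)
  ka <- if (!is.null(adjudication) && nrow(adjudication)) meas_key(adjudication) else character(0)

  both <- intersect(k1, k2)
  rows <- list()
  for (k in both) {
    a <- r1[match(k, k1), ]; b <- r2[match(k, k2), ]
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = a$patient_id, study_index = a$study_index,
      lesion_ref = a$lesion_ref,
      longest_mm = (a$longest_mm + b$longest_mm) / 2,
      perpendicular_mm = (a$perpendicular_mm + b$perpendicular_mm) / 2,
      source = "both", found_by = "R1+R2")
  }
  flagged <- character(0)
  s1 <- r1[!(k1 %in% both), , drop = FALSE]
  s2 <- r2[!(k2 %in% both), , drop = FALSE]
  s1$.by <- rep("R1", nrow(s1))
  s2$.by <- rep("R2", nrow(s2))
  single <- rbind(s1, s2)
  for (i in seq_len(nrow(single))) {
    k <- meas_key(single[i, ])
    j <- match(k, ka)
    if (is.na(j)) {
      flagged <- c(flagged, k)
      next
    }
    ad <- adjudication[j, ]
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = ad$patient_id, study_index = ad$study_index,
      lesion_ref = ad$lesion_ref,
      longest_mm = ad$longest_mm, perpendicular_mm = ad$perpendicular_mm,
      source = "adjudicated", found_by = single$.by[i])
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), study_index = integer(0),
               lesion_ref = character(0), longest_mm = numeric(0),
               perpendicular_mm = numeric(0), source = character(0),
               found_by = character(0))
  out <- out[order(out$patient_id, out$study_index, out$lesion_ref), ]
  rownames(out) <- NULL
  if (length(flagged))
    warning(length(flagged), " single-reader lesion(s) lacked adjudication; excluded")
  attr(out, "flagged") <- flagged
  out
}

#' Reader detection metrics against the consensus
#'
#' Matches a reader's findings to the consensus reference by shared
#' reference-lesion id: consensus lesions found by the reader are TP,
#' reader findings outside the consensus FP, consensus lesions the reader
#' missed FN.
#'
#' @param reader reader measurement data.frame.
#' @param consensus reference standard (see [build_consensus()]).
#' @return As [detection_metrics()], plus `tp`, `fp`, `fn`.
#' @export
reader_detection_metrics <- function(reader, consensus) {
  kr <- unique(meas_key(reader))
  kc <- unique(meas_key(consensus))
  tp <- sum(kr %in% kc)
  fp <- sum(!(kr %in% kc))
  fn <- sum(!(kc %in% kr))
  c(detection_metrics(tp, fp, fn), list(tp = tp, fp = fp, fn = fn))
}

# ICC(2,1): two-way random effects, absolute agreement, single measurement,
# via the classical mean-squares decomposition.
icc_2_1 <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  stopifnot(n >= 3L, k >= 2L)
  grand <- mean(mat)
  rowm <- rowMeans(mat); colm <- colMeans(mat)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  sst <- sum((mat - grand)^2)
  mse <- (sst - k * sum((rowm - grand)^2) - n * sum((colm - grand)^2)) /
    ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Paired inter-rater agreement statistics
#'
#' For paired diameter measurements of the same lesions by two readers
#' (single-reader lesions must already be excluded): the intraclass
#' correlation ICC(2,1) (two-way random effects, absolute agreement, single
#' measurement), the Spearman rank correlation (average ranks on ties), and
#' Bland-Altman parameters (mean difference r1 - r2 and mean +/- 1.96 SD
#' limits of agreement, no small-sample bias correction).
#'
#' @param pairs n x 2 matrix or data.frame of (r1_mm, r2_mm), n >= 3.
#' @return An `agreement_stats` list: `icc`, `spearman_rho`,
#'   `bland_altman` (`mean_diff_mm`, `loa_low_mm`, `loa_high_mm`),
#'   `n_pairs`.
#' @export
paired_agreement <- function(pairs) {
  m <- as.matrix(pairs)
  stopifnot(ncol(m) == 2L)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(m[, 1]) == 0 && stats::var(m[, 2]) == 0) {
    if (all(m[, 1] == m[, 2])) {
      # degenerate but unambiguous: identical constant readers agree perfectly
      icc <- 1; rho <- 1
      warning("zero variance in both readers; ICC/rho degenerate")
    } else stop("zero variance in both readers: ICC undefined")
  } else {
    icc <- icc_2_1(m)
    rho <- suppressWarnings(stats::cor(m[, 1], m[, 2], method = "spearman"))
  }
  d <- m[, 1] - m[, 2]
  md <- mean(d); sdd <- stats::sd(d)
  structure(list(icc = icc, spearman_rho = rho,
                 bland_altman = c(mean_diff_mm = md,
                                  loa_low_mm = md - 1.96 * sdd,
                                  loa_high_mm = md + 1.96 * sdd),
                 n_pairs = nrow(m)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> n = %d, ICC(2,1) = %.3f, rho = %.3f\n",
              x$n_pairs, x$icc, x$spearman_rho))
  cat(sprintf("  Bland-Altman: mean diff %.3f mm, LoA [%.3f, %.3f] mm\n",
              x$bland_altman[1], x$bland_altman[2], x$bland_altman[3]))
  invisible(x)
}

#' Relative paired difference (percent of the pair mean)
#'
#' `(r1 - r2) / mean(r1, r2) * 100`, the quantity plotted against lesion
#' size to show that disagreement shrinks as lesions grow.
#'
#' @param r1_mm,r2_mm paired diameters.
#' @return Percent differences (NA where the pair mean is 0).
#' @export
relative_difference_pct <- function(r1_mm, r2_mm) {
  mn <- (r1_mm + r2_mm) / 2
  ifelse(mn > 0, (r1_mm - r2_mm) / mn * 100, NA_real_)
}

#' Summarize lesions on which the readers disagreed
#'
#' Characterizes the discrepant subset (found by exactly one reader):
#' counts by reader, median and IQR of adjudicated DMAX, endpoint response
#' distribution, and the percentage that progressed.
#'
#' @param discrepant data.frame with columns `found_by` (`"R1"`/`"R2"`),
#'   `dmax_mm`, and optionally `endpoint` (CR/PR/SD/PD, NA when no
#'   follow-up exists).
#' @return A `discrepancy_summary` list: `n_discrepant`, `n_only_r1`,
#'   `n_only_r2`, `median_dmax_mm`, `iqr_dmax_mm`, `endpoint_counts`,
#'   `pct_pd`.
#' @export
summarize_discrepant <- function(discrepant) {
  if (is.null(discrepant) || nrow(discrepant) == 0L)
    return(structure(list(n_discrepant = 0L, n_only_r1 = 0L, n_only_r2 = 0L,
                          median_dmax_mm = NA_real_, iqr_dmax_mm = c(NA_real_, NA_real_),
                          endpoint_counts = c(CR = 0L, PR = 0L, SD = 0L, PD = 0L),
                          pct_pd = NA_real_),
                     class = "discrepancy_summary"))
  n1 <- sum(discrepant$found_by == "R1")
  n2 <- sum(discrepant$found_by == "R2")
  ep <- if ("endpoint" %in% names(discrepant)) discrepant$endpoint else rep(NA, nrow(discrepant))
  counts <- vapply(c("CR", "PR", "SD", "PD"),
                   function(l) sum(ep == l, na.rm = TRUE), integer(1))
  n <- nrow(discrepant)
  structure(list(n_discrepant = n, n_only_r1 = n1, n_only_r2 = n2,
                 median_dmax_mm = stats::median(discrepant$dmax_mm),
                 iqr_dmax_mm = unname(stats::quantile(discrepant$dmax_mm, c(0.25, 0.75))),
                 endpoint_counts = counts,
                 pct_pd = 100 * counts[["PD"]] / n),
            class = "discrepancy_summary")
}
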