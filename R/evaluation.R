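#' Match predicted against reference lesions
#'
#' Optimal one-to-one assignment between predicted and reference lesion
#' sets maximizing total voxel overlap. A pair counts as a true positive
#' only with at least `min_overlap` shared voxels (default 1 — the most
#' permissive criterion; no Dice or distance threshold). Unmatched
#' predictions are false positives, unmatched reference lesions false
#' negatives. Counts are stratified at a 5 mm longest-diameter boundary
#' (inclusive: >=5 mm is "measurable"); TP and FN strata follow the
#' REFERENCE lesion's diameter, FP strata the prediction's own.
#'
#' @param pred,ref lesion lists (from [extract_lesions()]) on the same grid.
#' @param min_overlap minimum shared voxels for a true positive.
#' @param size_threshold_mm stratum boundary.
#' @return A `detection_result`: list with `tp`, `fp`, `fn`, `pairs`
#'   (pred_id, ref_id), and `strata` (named list `all`, `ge5mm`, `lt5mm`,
#'   each `c(tp =, fp =, fn =)`).
#' @export
match_detections <- function(pred, ref, min_overlap = 1L, size_threshold_mm = 5.0) {
  if (length(pred) > 0L && length(ref) > 0L &&
      !grids_equal(pred[[1]]$grid, ref[[1]]$grid))
    stop("pred and ref lesions are on different grids")
  np <- length(pred); nr <- length(ref)
  S <- matrix(-Inf, np, nr)
  if (np > 0L && nr > 0L) {
    lp <- lapply(pred, lesion_linear_idx)
    lr <- lapply(ref, lesion_linear_idx)
    for (i in seq_len(np)) for (j in seq_len(nr)) {
      ov <- length(intersect(lp[[i]], lr[[j]]))
      if (ov >= min_overlap) S[i, j] <- ov
    }
  }
  m <- solve_max_matching(S)
  longest <- function(l) {
    if (is.null(l$dmax)) l$dmax <- dmax(l)
    l$dmax$longest_mm
  }
  stratum <- function(l) if (longest(l) >= size_threshold_mm) "ge5mm" else "lt5mm"

  strata <- list(all = c(tp = 0L, fp = 0L, fn = 0L),
                 ge5mm = c(tp = 0L, fp = 0L, fn = 0L),
                 lt5mm = c(tp = 0L, fp = 0L, fn = 0L))
  bump <- function(strata, s, what) {
    for (k in c("all", s)) strata[[k]][what] <- strata[[k]][what] + 1L
    strata
  }
  for (r in seq_len(nrow(m))) strata <- bump(strata, stratum(ref[[m[r, 2]]]), "tp")
  for (i in setdiff(seq_len(np), m[, 1])) strata <- bump(strata, stratum(pred[[i]]), "fp")
  for (j in setdiff(seq_len(nr), m[, 2])) strata <- bump(strata, stratum(ref[[j]]), "fn")

  pairs <- cbind(pred_id = vapply(pred[m[, 1]], function(l) l$lesion_id, integer(1)),
                 ref_id = vapply(ref[m[, 2]], function(l) l$lesion_id, integer(1)))
  structure(list(tp = strata$all[["tp"]], fp = strata$all[["fp"]],
                 fn = strata$all[["fn"]], pairs = pairs, strata = strata),
            class = "detection_result")
}

#' Precision, sensitivity and F1 from detection counts
#'
#' precision = TP/(TP+FP), sensitivity = TP/(TP+FN), F1 = their harmonic
#' mean. Values are kept at full precision; rounding is a presentation
#' concern. Undefined ratios (empty denominators) are returned as `NaN`.
#'
#' @param tp,fp,fn nonnegative counts; `tp` may also be a
#'   `detection_result` or a length-3 vector `c(tp, fp, fn)`.
#' @return List with `precision`, `sensitivity`, `f1` (and per-stratum
#'   data.frame `by_stratum` when given a `detection_result`).
#' @export
detection_metrics <- function(tp, fp = NULL, fn = NULL) {
  if (inherits(tp, "detection_result")) {
    res <- tp
    by <- do.call(rbind, lapply(names(res$strata), function(s) {
      cnt <- res$strata[[s]]
      m <- detection_metrics(cnt[["tp"]], cnt[["fp"]], cnt[["fn"]])
      data.frame(stratum = s, tp = cnt[["tp"]], fp = cnt[["fp"]], fn = cnt[["fn"]],
                 precision = m$precision, sensitivity = m$sensitivity, f1 = m$f1)
    }))
    out <- detection_metrics(res$tp, res$fp, res$fn)
    out$by_stratum <- by
    return(out)
  }
  if (is.null(fp) && length(tp) == 3L) { fn <- tp[[3]]; fp <- tp[[2]]; tp <- tp[[1]] }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp + fn == 0) warning("all-zero counts: metrics undefined")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NaN
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NaN
  f1 <- if (is.finite(precision) && is.finite(sensitivity) && precision + sensitivity > 0)
    2 * precision * sensitivity / (precision + sensitivity) else NaN
  list(precision = precision, sensitivity = sensitivity, f1 = f1)
}

#' Patient-wise Dice similarity coefficient
#'
#' Pools the foreground voxels of all of a patient's studies before
#' computing DSC = 2|A n B| / (|A| + |B|), giving one number per patient.
#' Pairs must share grids; a patient with both pooled masks empty has an
#' undefined DSC and raises an error.
#'
#' @param pred_volumes,ref_volumes equal-length lists of [label_volume()]s,
#'   paired by position.
#' @return List with `patient_id` and `dsc`.
#' @export
dice_patient <- function(pred_volumes, ref_volumes) {
  if (length(pred_volumes) != length(ref_volumes) || length(pred_volumes) == 0L)
    stop("need >= 1 paired study volumes")
  inter <- 0; a <- 0; b <- 0
  for (k in seq_along(pred_volumes)) {
    p <- pred_volumes[[k]]; r <- ref_volumes[[k]]
    if (!grids_equal(p$grid, r$grid)) stop("volume pair ", k, ": grid mismatch")
    pm <- p$data > 0L; rm <- r$data > 0L
    inter <- inter + sum(pm & rm)
    a <- a + sum(pm); b <- b + sum(rm)
  }
  if (a + b == 0) stop("both pooled masks empty: DSC undefined")
  list(patient_id = pred_volumes[[1]]$patient_id, dsc = 2 * inter / (a + b))
}

#' Cohort summary of patient-wise DSC
#'
#' @param dsc numeric vector of per-patient DSC values.
#' @return List with `median`, `iqr` (25th and 75th percentiles), `range`,
#'   `n`.
#' @export
dice_cohort <- function(dsc) {
  dsc <- as.numeric(dsc)
  list(median = stats::median(dsc),
       iqr = unname(stats::quantile(dsc, c(0.25, 0.75))),
       range = range(dsc), n = length(dsc))
}
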