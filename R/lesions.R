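connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 `6` = ord == 1, `18` = ord >= 1 & ord <= 2, `26` = ord >= 1)
  off <- off[keep, , drop = FALSE]
  # half neighborhood: one offset per unordered voxel pair
  off[off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 | (off[, 2] == 0 & off[, 1] > 0))),
      , drop = FALSE]
}

#' Decompose a label volume into distinct lesions
#'
#' Foreground voxels (any positive label, flattened to a single tissue
#' class) are grouped into 3D connected components under the chosen voxel
#' adjacency. Each component becomes one lesion with its voxel set, physical
#' centroid, volume and, by default, its axial maximum orthogonal diameters
#' (see [dmax()]). Lesions are ordered by descending volume, ties broken by
#' the lowest (z, y, x) centroid, and ids are assigned 1..N in that order.
#'
#' @param vol a [label_volume()].
#' @param connectivity 6 (face), 18 (face+edge) or 26 (face+edge+vertex,
#'   default: vertex-adjacent voxels merge, avoiding spurious splits across
#'   anti-aliased mask boundaries).
#' @param min_voxels drop components smaller than this many voxels
#'   (default 1, i.e. keep everything: sub-5 mm lesions are first-class here).
#' @param compute_dmax if `TRUE` (default) fill each lesion's `dmax`.
#' @return A list of `lesion` objects, possibly empty. Each lesion carries
#'   `lesion_id`, `study_index`, `voxels` (n x 3, 1-based indices),
#'   `centroid_mm`, `volume_mm3`, `dmax`, and the source `grid`.
#' @export
extract_lesions <- function(vol, connectivity = 26L, min_voxels = 1L,
                            compute_dmax = TRUE) {
  stopifnot(inherits(vol, "label_volume"))
  sh <- vol$grid$shape
  fg <- which(vol$data > 0L)
  if (length(fg) == 0L) return(list())

  coords <- arrayInd(fg, sh)
  fg_sorted <- fg                      # which() is already ascending
  off <- connectivity_offsets(connectivity)

  edges <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    nb <- sweep(coords, 2L, off[k, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= sh[1] &
          nb[, 2] >= 1L & nb[, 2] <= sh[2] &
          nb[, 3] >= 1L & nb[, 3] <= sh[3]
    if (!any(ok)) next
    nlin <- nb[ok, 1] + sh[1] * ((nb[ok, 2] - 1L) + sh[2] * (nb[ok, 3] - 1L))
    pos <- findInterval(nlin, fg_sorted)
    hit <- pos > 0L & fg_sorted[pmax(pos, 1L)] == nlin
    if (any(hit)) edges[[k]] <- cbind(which(ok)[hit], pos[hit])
  }
  edges <- do.call(rbind, edges)

  if (is.null(edges)) {
    membership <- seq_along(fg)
  } else {
    g <- igraph::make_graph(t(edges), n = length(fg), directed = FALSE)
    membership <- igraph::components(g)$membership
  }

  voxvol <- prod(vol$grid$spacing)
  comps <- split(seq_along(fg), membership)
  comps <- comps[lengths(comps) >= min_voxels]
  if (length(comps) == 0L) return(list())

  lesions <- lapply(comps, function(idx) {
    vx <- coords[idx, , drop = FALSE]
    cen0 <- colMeans(vx) - 1                         # 0-based voxel centroid
    cen_mm <- as.numeric(vol$grid$affine %*% c(cen0, 1))[1:3]
    structure(list(lesion_id = NA_integer_,
                   study_index = vol$study_index,
                   voxels = vx,
                   centroid_mm = cen_mm,
                   centroid_vox = cen0,
                   volume_mm3 = nrow(vx) * voxvol,
                   dmax = NULL,
                   grid = vol$grid),
              class = "lesion")
  })

  vols <- vapply(lesions, function(l) l$volume_mm3, numeric(1))
  cz <- vapply(lesions, function(l) l$centroid_vox[3], numeric(1))
  cy <- vapply(lesions, function(l) l$centroid_vox[2], numeric(1))
  cx <- vapply(lesions, function(l) l$centroid_vox[1], numeric(1))
  ord <- order(-vols, cz, cy, cx)
  lesions <- lesions[ord]
  for (i in seq_along(lesions)) {
    lesions[[i]]$lesion_id <- i
    if (compute_dmax) lesions[[i]]$dmax <- dmax(lesions[[i]], vol$grid)
  }
  names(lesions) <- NULL
  lesions
}

#' @export
print.lesion <- function(x, ...) {
  d <- if (is.null(x$dmax)) "unmeasured" else
    sprintf("%.1f x %.1f mm", x$dmax$longest_mm, x$dmax$perpendicular_mm)
  cat(sprintf("<lesion #%s> study %d, %d voxels (%.1f mm3), DMAX %s\n",
              x$lesion_id, x$study_index, nrow(x$voxels), x$volume_mm3, d))
  invisible(x)
}

#' Size class of a lesion
#'
#' Lesions are stratified by their longest axial diameter at a configurable
#' boundary (default 5 mm, inclusive: a lesion measuring exactly 5.0 mm is
#' "measurable").
#'
#' @param lesion a lesion with computed `dmax`.
#' @param threshold_mm stratum boundary in mm.
#' @return `"measurable"` or `"small"`.
#' @export
lesion_size_class <- function(lesion, threshold_mm = 5.0) {
  if (is.null(lesion$dmax)) stop("lesion has no computed dmax")
  if (lesion$dmax$longest_mm >= threshold_mm) "measurable" else "small"
}

lesion_linear_idx <- function(lesion) {
  sh <- lesion$grid$shape
  lesion$voxels[, 1] + sh[1] * ((lesion$voxels[, 2] - 1L) + sh[2] * (lesion$voxels[, 3] - 1L))
}
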