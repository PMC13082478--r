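# Axial orthogonal maximum diameters (DMAX).
#
# Distances are between voxel CENTERS, so a single-voxel lesion measures
# 0 mm; the perpendicular diameter is the caliper width (projection extent)
# of the cross-section orthogonal to the longest segment. Both choices are
# deterministic and oracle-checkable on a discrete grid.

# Farthest pair(s) of 2D points. The farthest pair is always attained on
# convex-hull vertices; the hull prunes the O(n^2) search when the
# cross-section is large. All pairs tying for the maximum are returned
# (canonically ordered endpoints) so the caller can break ties robustly.
farthest_pairs <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) return(list(d = 0, pairs = matrix(c(1L, 1L), ncol = 2)))
  cand <- seq_len(n)
  if (n > 60L) {
    h <- tryCatch(grDevices::chull(pts), error = function(e) NULL)
    if (!is.null(h) && length(h) >= 2L) cand <- sort(h)
  }
  P <- pts[cand, , drop = FALSE]
  D <- as.matrix(stats::dist(P))
  dmx <- max(D)
  hits <- which(D >= dmx - 1e-9 & upper.tri(D), arr.ind = TRUE)
  pairs <- matrix(0L, nrow(hits), 2)
  for (r in seq_len(nrow(hits))) {
    i <- cand[hits[r, 1]]; j <- cand[hits[r, 2]]
    a <- pts[i, ]; b <- pts[j, ]
    if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2])) { tmp <- i; i <- j; j <- tmp }
    pairs[r, ] <- c(i, j)
  }
  list(d = dmx, pairs = pairs)
}

vec_lt <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k] - 1e-12) return(TRUE)
    if (a[k] > b[k] + 1e-12) return(FALSE)
  }
  FALSE
}

#' Orthogonal diameters of one axial cross-section
#'
#' Computes the longest center-to-center distance between any two voxels of
#' a 2D cross-section (in mm, honoring anisotropic in-plane spacing) and the
#' caliper width of the voxel centers along the in-plane direction
#' orthogonal to that longest segment. When several pairs tie for the
#' longest distance, the largest caliper width among them is reported (so
#' the measurement is invariant under rigid rotations that permute the tied
#' pairs), with remaining ties broken by the lexicographically smallest
#' endpoint pair. A single voxel measures (0, 0).
#'
#' @param cross_section n x 2 matrix of (x, y) voxel indices.
#' @param in_plane_spacing 2 positive reals, mm/voxel along x and y.
#' @return List with `longest_mm`, `perpendicular_mm`, `endpoints_long`
#'   (2 x 2, mm), `endpoints_perp` (2 x 2, mm; the extreme caliper pair).
#' @export
slice_diameters <- function(cross_section, in_plane_spacing = c(1, 1)) {
  xy <- as.matrix(cross_section)
  if (nrow(xy) == 0L) stop("empty cross-section")
  stopifnot(ncol(xy) == 2L, length(in_plane_spacing) == 2L,
            all(in_plane_spacing > 0))
  pts <- cbind((xy[, 1] - 1) * in_plane_spacing[1],
               (xy[, 2] - 1) * in_plane_spacing[2])
  pts <- unique(pts)

  fp <- farthest_pairs(pts)
  if (fp$d == 0) {
    a <- pts[1, ]
    return(list(longest_mm = 0, perpendicular_mm = 0,
                endpoints_long = rbind(a, a), endpoints_perp = rbind(a, a)))
  }
  # among pairs tying for longest, report the largest caliper width, so the
  # result is invariant under rigid rotations that permute the tied pairs;
  # remaining ties resolve to the lexicographically smallest endpoint pair
  pick <- function(idx) {
    sub <- pts[idx, , drop = FALSE]
    sub[order(sub[, 1], sub[, 2])[1], ]
  }
  best <- NULL
  for (r in seq_len(nrow(fp$pairs))) {
    a <- pts[fp$pairs[r, 1], ]; b <- pts[fp$pairs[r, 2], ]
    u <- (b - a) / fp$d
    v <- c(-u[2], u[1])
    proj <- pts %*% v
    width <- as.numeric(max(proj) - min(proj))
    key <- c(a, b)
    if (is.null(best) || width > best$width + 1e-9 ||
        (width > best$width - 1e-9 && vec_lt(key, best$key))) {
      lo <- which(proj <= min(proj) + 1e-12)
      hi <- which(proj >= max(proj) - 1e-12)
      best <- list(width = width, key = key, a = a, b = b,
                   ep = unname(rbind(pick(lo), pick(hi))))
    }
  }
  list(longest_mm = fp$d,
       perpendicular_mm = best$width,
       endpoints_long = unname(rbind(best$a, best$b)),
       endpoints_perp = best$ep)
}

#' Maximum orthogonal diameters of a lesion in the axial plane
#'
#' Evaluates [slice_diameters()] on every axial slice (third voxel axis)
#' intersecting the lesion and returns the pair from the slice maximizing
#' the longest diameter, ties broken by the lowest slice index. The
#' through-plane extent never enters the measurement.
#'
#' @param lesion a lesion (from [extract_lesions()]) or any object with an
#'   n x 3 `voxels` matrix.
#' @param grid the [image_grid()] supplying in-plane spacing.
#' @return A `diameter_pair`: list with `longest_mm`, `perpendicular_mm`,
#'   `slice_index`, `endpoints_long`, `endpoints_perp`.
#' @export
dmax <- function(lesion, grid = lesion$grid) {
  vx <- lesion$voxels
  if (is.null(vx) || nrow(vx) == 0L) stop("empty lesion")
  sp <- grid$spacing[1:2]
  best <- NULL
  for (z in sort(unique(vx[, 3]))) {
    sl <- slice_diameters(vx[vx[, 3] == z, 1:2, drop = FALSE], sp)
    if (is.null(best) || sl$longest_mm > best$longest_mm + 1e-12) {
      best <- sl
      best$slice_index <- z
    }
  }
  structure(best, class = "diameter_pair")
}

#' @export
print.diameter_pair <- function(x, ...) {
  cat(sprintf("<diameter_pair> %.2f x %.2f mm on slice %d\n",
              x$longest_mm, x$perpendicular_mm, x$slice_index))
  invisible(x)
}
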