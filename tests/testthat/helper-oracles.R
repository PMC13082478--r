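# Independent oracles and small fixture builders. These deliberately avoid
# the package's own code paths (plain double loops, permutation search) so
# that agreement between the two routes is evidence, not tautology.

# O(n^2) farthest-pair distance between voxel centers, in mm.
oracle_longest <- function(xy, spacing = c(1, 1)) {
  pts <- cbind(xy[, 1] * spacing[1], xy[, 2] * spacing[2])
  n <- nrow(pts)
  if (n < 2L) return(0)
  best <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((pts[i, ] - pts[j, ])^2))
    if (d > best) best <- d
  }
  best
}

all_perms <- function(n) {
  gen <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (rest in gen(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  gen(seq_len(n))
}

# Exhaustive minimal-cost assignment over all permutations (n <= 7).
oracle_assignment <- function(cost) {
  n <- nrow(cost)
  best <- NULL; best_cost <- Inf
  for (p in all_perms(n)) {
    cst <- sum(cost[cbind(seq_len(n), p)])
    if (cst < best_cost - 1e-12) { best_cost <- cst; best <- p }
  }
  list(assignment = best, cost = best_cost)
}

# Random connected 2D blob grown by neighbor accretion.
random_blob_2d <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(c(0L, 0L), ncol = 2)
  key <- "0|0"
  while (nrow(pts) < n) {
    base <- pts[sample(nrow(pts), 1L), ]
    step <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))[sample(4L, 1L), ]
    cand <- base + step
    k <- paste(cand, collapse = "|")
    if (!(k %in% key)) {
      pts <- rbind(pts, cand)
      key <- c(key, k)
    }
  }
  pts
}

# Random connected 3D blob for component/conservation tests.
random_blob_3d <- function(n, seed, origin = c(5L, 5L, 5L)) {
  set.seed(seed)
  pts <- matrix(origin, ncol = 3)
  key <- paste(origin, collapse = "|")
  steps <- rbind(diag(3), -diag(3))
  while (nrow(pts) < n) {
    base <- pts[sample(nrow(pts), 1L), ]
    cand <- base + steps[sample(6L, 1L), ]
    if (any(cand < 1L)) next
    k <- paste(cand, collapse = "|")
    if (!(k %in% key)) {
      pts <- rbind(pts, cand)
      key <- c(key, k)
    }
  }
  pts
}

mk_volume <- function(shape, fg = NULL, spacing = c(1, 1, 1), value = 1L, ...) {
  d <- array(0L, dim = shape)
  if (!is.null(fg)) d[fg] <- value
  label_volume(d, image_grid(shape, spacing), ...)
}

# A digital sphere mask: voxel centers within diam/2 of center_vox (1-based).
add_sphere <- function(data, center_vox, diam_vox) {
  sh <- dim(data)
  r <- diam_vox / 2
  for (x in seq_len(sh[1])) for (y in seq_len(sh[2])) for (z in seq_len(sh[3])) {
    if (sum((c(x, y, z) - center_vox)^2) <= r^2 + 1e-9) data[x, y, z] <- 1L
  }
  data
}

make_lesion_at <- function(vol_shape, fg_idx, spacing = c(1, 1, 1), study = 0L) {
  v <- mk_volume(vol_shape, spacing = spacing, study_index = study)
  v$data[fg_idx] <- 1L
  v
}
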