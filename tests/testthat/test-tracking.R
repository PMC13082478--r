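test_that("assignment solver agrees with the exhaustive permutation oracle", {
  set.seed(123)
  for (k in 1:60) {
    n <- sample(2:6, 1)
    cost <- matrix(round(stats::runif(n * n, 0, 100), 3), n, n)
    got <- neurotrackr:::solve_assignment(cost)
    want <- oracle_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), got)]), want$cost, tolerance = 1e-9)
  }
})

test_that("identical lesion sets match to themselves", {
  v <- mk_volume(c(20, 20, 10))
  v$data[3:5, 3:5, 3:5] <- 1L
  v$data[12:16, 12:16, 4:7] <- 1L
  ls <- extract_lesions(v)
  m <- match_lesions(ls, ls)
  expect_equal(nrow(m$pairs), 2)
  expect_equal(m$pairs[, 1], m$pairs[, 2])
  expect_length(m$unmatched_prev, 0)
  expect_length(m$unmatched_curr, 0)
})

test_that("unmatched lesions are reported", {
  v <- mk_volume(c(10, 10, 10)); v$data[3:5, 3:5, 3:5] <- 1L
  ls <- extract_lesions(v)
  m <- match_lesions(ls, list())
  expect_equal(m$unmatched_prev, 1L)
  expect_equal(nrow(m$pairs), 0)
  m2 <- match_lesions(list(), ls)
  expect_equal(m2$unmatched_curr, 1L)
})

test_that("matching follows space, not list order, and respects the gate", {
  v1 <- mk_volume(c(30, 30, 10))
  v1$data[4:8, 4:8, 4:6] <- 1L       # big lesion A
  v1$data[20:22, 20:22, 4:6] <- 1L   # small lesion B
  prev <- extract_lesions(v1)        # id 1 = A (bigger)

  v2 <- mk_volume(c(30, 30, 10))
  v2$data[20:22, 20:22, 4:6] <- 1L   # B stationary (listed first after reorder)
  v2$data[4:8, 4:8, 4:6] <- 1L       # A stationary
  curr <- extract_lesions(v2)
  m <- match_lesions(prev, curr)
  # centroids decide: A matches A, B matches B regardless of id order
  for (r in seq_len(nrow(m$pairs))) {
    pl <- prev[[which(vapply(prev, function(l) l$lesion_id, integer(1)) == m$pairs[r, 1])]]
    cl <- curr[[which(vapply(curr, function(l) l$lesion_id, integer(1)) == m$pairs[r, 2])]]
    expect_lt(sqrt(sum((pl$centroid_mm - cl$centroid_mm)^2)), 1e-9)
  }

  # overlap-free pair beyond the gate stays unmatched
  v3 <- mk_volume(c(60, 30, 10)); v3$data[4:6, 4:6, 4:6] <- 1L
  v4 <- mk_volume(c(60, 30, 10)); v4$data[40:42, 4:6, 4:6] <- 1L
  m2 <- match_lesions(extract_lesions(v3), extract_lesions(v4), gate_mm = 10)
  expect_equal(nrow(m2$pairs), 0)
  # ... but within the gate it is rescued
  v5 <- mk_volume(c(60, 30, 10)); v5$data[9:11, 4:6, 4:6] <- 1L
  m3 <- match_lesions(extract_lesions(v3), extract_lesions(v5), gate_mm = 10)
  expect_equal(nrow(m3$pairs), 1)
})

test_that("exhaustive matching oracle on random small scenes", {
  # overlap-scored one-to-one matching equals brute force over injections
  set.seed(5)
  for (rep in 1:15) {
    np <- sample(1:3, 1); nc <- sample(1:3, 1)
    mk <- function(n, seed) {
      set.seed(seed)
      v <- mk_volume(c(26, 26, 8))
      placed <- 0
      while (placed < n) {
        x <- sample(3:23, 1); y <- sample(3:23, 1); z <- sample(2:6, 1)
        sub <- v$data[(x - 2):(x + 2), (y - 2):(y + 2), max(1, z - 1):min(8, z + 1)]
        if (all(sub == 0L)) {
          v$data[(x - 1):(x + 1), (y - 1):(y + 1), z] <- 1L
          placed <- placed + 1
        }
      }
      extract_lesions(v)
    }
    prev <- mk(np, 9000 + rep); curr <- mk(nc, 9500 + rep)
    m <- match_lesions(prev, curr, gate_mm = 12)
    # brute force: score every injective mapping with the same rule
    lin <- function(l) neurotrackr:::lesion_linear_idx(l)
    score1 <- function(i, j) {
      ov <- length(intersect(lin(prev[[i]]), lin(curr[[j]])))
      d <- sqrt(sum((prev[[i]]$centroid_mm - curr[[j]]$centroid_mm)^2))
      if (ov > 0) ov * 1e6 - d else if (d <= 12) (12 - d) + 1e-6 else NA
    }
    best <- -Inf
    for (rows in c(list(integer(0)), unlist(lapply(seq_len(min(np, nc)),
        function(k) combn(np, k, simplify = FALSE)), recursive = FALSE))) {
      k <- length(rows)
      if (k == 0) { best <- max(best, 0); next }
      for (cols in combn(nc, k, simplify = FALSE)) for (p in all_perms(k)) {
        s <- vapply(seq_len(k), function(t) {
          val <- score1(rows[t], cols[p[t]])
          if (is.na(val)) -Inf else val
        }, numeric(1))
        if (all(is.finite(s))) best <- max(best, sum(s))
      }
    }
    got <- 0
    for (r in seq_len(nrow(m$pairs))) got <- got + score1(m$prev_idx[r], m$curr_idx[r])
    expect_equal(got, best, tolerance = 1e-6)
  }
})

test_that("percent change arithmetic and undefined priors", {
  expect_equal(percent_change(12, 10), 20)
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(7, 10), -30)
  expect_true(is.na(percent_change(5, 0)))
  expect_true(is.na(percent_change(5, NA)))
})

test_that("tracks chain presence, absence and late appearance", {
  base <- function() mk_volume(c(30, 30, 10))
  vA <- function(v) { v$data[4:8, 4:8, 4:6] <- 1L; v }
  vB <- function(v) { v$data[20:23, 20:23, 4:6] <- 1L; v }

  s0 <- vA(base()); s1 <- vA(vB(base())); s2 <- vB(base())
  series <- lapply(0:2, function(i)
    list(study_index = i,
         lesions = extract_lesions(list(s0, s1, s2)[[i + 1]])))
  tracks <- build_tracks(series)
  expect_length(tracks, 2)

  tA <- tracks[[1]]   # first_seen 0, present 0,1, absent at 2
  expect_equal(tA$first_seen, 0L)
  expect_equal(tA$measurements$study_index, 0:2)
  expect_true(is.na(tA$measurements$lesion_id[3]))
  tB <- tracks[[2]]   # appears at 1
  expect_equal(tB$first_seen, 1L)
  expect_equal(sum(!is.na(tB$measurements$lesion_id)), 2)

  # percent change vs the prior study
  v0 <- base(); v0$data[10:14, 10:14, 4:6] <- 1L    # 5 voxels wide
  v1 <- base(); v1$data[10:16, 10:16, 4:6] <- 1L    # 7 voxels wide
  tr <- build_tracks(list(list(study_index = 0, lesions = extract_lesions(v0)),
                          list(study_index = 1, lesions = extract_lesions(v1))))[[1]]
  expect_equal(tr$measurements$pct_change_long[2],
               100 * (tr$measurements$longest_mm[2] - tr$measurements$longest_mm[1]) /
                 tr$measurements$longest_mm[1])
})

test_that("a vanished track re-matches on regrowth via its last footprint", {
  base <- function() mk_volume(c(30, 30, 10))
  v0 <- base(); v0$data[10:14, 10:14, 4:6] <- 1L
  v1 <- base()
  v2 <- base(); v2$data[11:13, 11:13, 4:6] <- 1L
  series <- lapply(0:2, function(i)
    list(study_index = i, lesions = extract_lesions(list(v0, v1, v2)[[i + 1]])))
  tracks <- build_tracks(series)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$measurements$study_index, 0:2)
  expect_true(is.na(tracks[[1]]$measurements$lesion_id[2]))
  expect_false(is.na(tracks[[1]]$measurements$lesion_id[3]))
})

test_that("present measurements are conserved and ids don't matter", {
  set.seed(77)
  for (rep in 1:5) {
    cfg <- phantom_config(shape = c(48, 48, 24), n_studies = 3,
                          n_lesions = 2, diam_range_mm = c(4, 9),
                          seed = 800 + rep)
    ph <- generate_phantom(cfg)
    series <- lapply(seq_along(ph$volumes), function(i)
      list(study_index = i - 1L, lesions = extract_lesions(ph$volumes[[i]])))
    tracks <- build_tracks(series)
    n_present <- sum(vapply(tracks, function(tr)
      sum(!is.na(tr$measurements$lesion_id)), integer(1)))
    n_lesions <- sum(vapply(series, function(s) length(s$lesions), integer(1)))
    expect_equal(n_present, n_lesions)
  }
})

test_that("tracking recovers phantom correspondences on 100 random phantoms", {
  ok <- TRUE
  for (rep in 1:100) {
    cfg <- phantom_config(shape = c(48, 48, 24), n_studies = 3, n_lesions = 2,
                          diam_range_mm = c(3, 6), seed = 20000 + rep)
    ph <- generate_phantom(cfg)
    series <- lapply(seq_along(ph$volumes), function(i)
      list(study_index = i - 1L, lesions = extract_lesions(ph$volumes[[i]])))
    tracks <- build_tracks(series)
    truth <- ph$truth
    # every track must stay glued to exactly one true lesion center
    for (tr in tracks) {
      centers <- NULL
      for (r in seq_len(nrow(tr$measurements))) {
        if (is.na(tr$measurements$lesion_id[r])) next
        si <- tr$measurements$study_index[r]
        les <- series[[si + 1]]$lesions[[
          which(vapply(series[[si + 1]]$lesions, function(l) l$lesion_id,
                       integer(1)) == tr$measurements$lesion_id[r])]]
        tt <- truth[truth$study_index == si & truth$true_diam_mm > 0, ]
        d2 <- sqrt((tt$center_x_mm - les$centroid_mm[1])^2 +
                   (tt$center_y_mm - les$centroid_mm[2])^2 +
                   (tt$center_z_mm - les$centroid_mm[3])^2)
        centers <- c(centers, tt$lesion[which.min(d2)])
      }
      if (length(unique(centers)) != 1L) ok <- FALSE
    }
    n_true_tracks <- length(unique(truth$lesion[truth$true_diam_mm > 0]))
    if (length(tracks) != n_true_tracks) ok <- FALSE
  }
  expect_true(ok)
})
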