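# Dense linear assignment (Jonker-Volgenant style shortest augmenting
# paths, O(n^3)). Written here because no assignment solver ships with the
# declared dependencies; verified against an exhaustive permutation oracle
# in the test suite.

# cost: square numeric matrix (finite). Returns for each row the assigned
# column, minimizing total cost.
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(n == ncol(cost), all(is.finite(cost)))
  if (n == 0L) return(integer(0))
  u <- numeric(n)            # row potentials
  v <- numeric(n + 1L)       # column potentials, n+1 = virtual column
  p <- integer(n + 1L)       # p[j] = row matched to column j (0 = free)

  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    way <- integer(n)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      red <- cost[i0, ] - u[i0] - v[seq_len(n)]
      upd <- !used[seq_len(n)] & red < minv
      minv[upd] <- red[upd]
      way[upd] <- j0
      free_j <- which(!used[seq_len(n)])
      if (length(free_j)) {
        j1 <- free_j[which.min(minv[free_j])]
        delta <- minv[j1]
      }
      usedj <- which(used)
      rows <- p[usedj]
      u[rows[rows > 0L]] <- u[rows[rows > 0L]] + delta
      v[usedj] <- v[usedj] - delta
      minv[!used[seq_len(n)]] <- minv[!used[seq_len(n)]] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {                 # augment along the alternating path
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j]] <- j
  assignment
}

# Maximize total score over a (possibly rectangular) score matrix, allowing
# units to stay unmatched (score 0). Entries = -Inf mark forbidden pairs.
# Returns a 2-column matrix of (row, col) matched pairs.
solve_max_matching <- function(score) {
  nr <- nrow(score); nc <- ncol(score)
  if (nr == 0L || nc == 0L) return(matrix(integer(0), ncol = 2))
  m <- nr + nc
  big <- max(1, abs(score[is.finite(score)]), na.rm = TRUE) * (m + 1)
  S <- matrix(0, m, m)
  sc <- score
  sc[!is.finite(sc)] <- -big
  S[seq_len(nr), seq_len(nc)] <- sc
  assign <- solve_assignment(-S)
  i <- seq_len(nr)
  j <- assign[i]
  keep <- j <= nc & is.finite(score[cbind(i, pmin(j, nc))]) &
    score[cbind(i, pmin(j, nc))] > 0
  cbind(row = i[keep], col = j[keep])
}
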