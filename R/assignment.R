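## Linear assignment (Hungarian / Kuhn-Munkres) via shortest augmenting
## paths with dual potentials, O(n^3). Written here because no LSAP solver
## ships with the supported package set; validated against brute-force
## permutation enumeration in the test suite.

# Minimize sum(cost[i, assign[i]]) over permutations; `cost` square.
solve_assignment_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) return(integer(0))
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1L)   # column potentials, index 1 = virtual column 0
  p <- integer(n + 1L)   # p[j+1] = row currently assigned to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0] - v[j + 1L]
        if (cur < minv[j + 1L]) {
          minv[j + 1L] <- cur
          way[j + 1L] <- j0
        }
        if (minv[j + 1L] < delta) {
          delta <- minv[j + 1L]
          j1 <- j
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) assign[p[j + 1L]] <- j
  assign
}

# Maximize total score over a (possibly rectangular) score matrix. Returns
# an integer vector over rows: the assigned column index, or NA for rows
# matched to padding. Padded entries carry zero score.
solve_assignment_max <- function(score) {
  nr <- nrow(score)
  nc <- ncol(score)
  if (nr == 0L || nc == 0L) return(rep(NA_integer_, nr))
  n <- max(nr, nc)
  big <- matrix(0, n, n)
  big[seq_len(nr), seq_len(nc)] <- score
  a <- solve_assignment_min(-big)
  out <- a[seq_len(nr)]
  out[out > nc] <- NA_integer_
  out
}
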