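## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's own code paths.

# per-pixel median via explicit neighborhood collection with reflect padding
oracle_median <- function(m, radius) {
  nr <- nrow(m)
  nc <- ncol(m)
  refl <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      vals <- c()
      for (dr in -radius:radius) {
        for (dc in -radius:radius) {
          vals <- c(vals, m[refl(r + dr, nr), refl(cc + dc, nc)])
        }
      }
      out[r, cc] <- median(vals)
    }
  }
  out
}

# per-pixel maximum across layers by explicit loop
oracle_mip <- function(stack) {
  out <- stack[[1]]
  for (r in seq_len(nrow(out))) {
    for (cc in seq_len(ncol(out))) {
      out[r, cc] <- max(vapply(stack, function(l) l[r, cc], numeric(1)))
    }
  }
  out
}

# exhaustive best-product path from a seed through a score-matrix chain.
# Paths extend while a positive transition exists; ties broken toward the
# lower cell label at every extension (candidates tried in ascending label
# order, strict improvement required to replace).
oracle_best_path <- function(matrices, seed_frame, seed_label) {
  T_frames <- length(matrices) + 1L
  # tracks extend as far as the chain allows; among paths of maximal length
  # the highest product wins
  best <- list(len = -1L, score = -Inf, labels = NULL)
  consider <- function(labels, logscore) {
    if (length(labels) > best$len ||
        (length(labels) == best$len && logscore > best$score + 1e-12)) {
      best <<- list(len = length(labels), score = logscore, labels = labels)
    }
  }
  recurse <- function(f, lab, labels, logscore) {
    if (f == T_frames - 1L) {
      consider(labels, logscore)
      return(invisible())
    }
    m <- matrices[[f + 1L]]
    row <- m[as.character(lab), , drop = FALSE]
    cols <- colnames(m)[order(as.integer(colnames(m)))]
    any_pos <- FALSE
    for (j in cols) {
      s <- row[1, j]
      if (s > 0) {
        any_pos <- TRUE
        recurse(f + 1L, j, c(labels, j), logscore + log(s))
      }
    }
    if (!any_pos) consider(labels, logscore)
    invisible()
  }
  recurse(seed_frame, as.character(seed_label), as.character(seed_label), 0)
  list(labels = as.integer(best$labels), log_score = best$score)
}

# brute-force maximum-score assignment by permutation enumeration
oracle_assignment_max <- function(score) {
  nr <- nrow(score)
  nc <- ncol(score)
  n <- max(nr, nc)
  big <- matrix(0, n, n)
  big[seq_len(nr), seq_len(nc)] <- score
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  best <- -Inf
  for (p in perms(seq_len(n))) {
    tot <- sum(big[cbind(seq_len(n), p)])
    if (tot > best) best <- tot
  }
  best
}

# random score-matrix chain: `sizes` = number of cells per frame
random_chain <- function(sizes, zero_frac = 0.3) {
  lapply(seq_len(length(sizes) - 1L), function(t) {
    m <- matrix(runif(sizes[t] * sizes[t + 1L]), sizes[t], sizes[t + 1L])
    m[runif(length(m)) < zero_frac] <- 0
    dimnames(m) <- list(as.character(seq_len(sizes[t])),
                        as.character(seq_len(sizes[t + 1L])))
    m
  })
}

# identity-like chain: k cells per frame, diagonal score `s`
diagonal_chain <- function(k, n_frames, s = 1) {
  lapply(seq_len(n_frames - 1L), function(t) {
    m <- diag(s, k, k)
    dimnames(m) <- list(as.character(seq_len(k)), as.character(seq_len(k)))
    m
  })
}
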