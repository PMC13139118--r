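#' Linkage parameters
#'
#' Thresholds governing trajectory linkage.
#'
#' @param T_truncated Score floor in `[0, 1]` below which a transition is
#'   treated as a disappearance (cell out of the field of view).
#' @param T_merge Score threshold in `[0, 1]` governing whether a track may
#'   enter a detection already occupied by another track; discounted
#'   geometrically per frame by [discount_threshold()] because accumulated
#'   scores are products.
#' @param end_threshold Minimum assignment score under which a Hungarian
#'   link is cut.
#' @param reroute_factor Factor (>= 1) by which a later-routed track's
#'   accumulated score must exceed an occupant's for the occupant to be
#'   reset and re-routed; 1 means strictly greater wins.
#'
#' @return A `linkage_params` list.
#' @export
linkage_params <- function(T_truncated = 0.001, T_merge = 0.875,
                           end_threshold = 0.001, reroute_factor = 1) {
  stopifnot(T_truncated >= 0, T_truncated <= 1,
            T_merge >= 0, T_merge <= 1,
            end_threshold >= 0, end_threshold <= 1,
            reroute_factor >= 1)
  structure(list(T_truncated = T_truncated, T_merge = T_merge,
                 end_threshold = end_threshold,
                 reroute_factor = reroute_factor),
            class = "linkage_params")
}

#' Geometric discount of the merge threshold
#'
#' The merge threshold applies to accumulated products of per-step scores,
#' which decay geometrically along a track; the comparable threshold at
#' frame `frame_number` of a track (1 = its birth frame) is therefore
#' `T_merge^(frame_number - 1)`.
#'
#' @param T_merge Merge threshold in `[0, 1]`.
#' @param frame_number Frame count from the track's birth, >= 1.
#'
#' @return The discounted threshold; 1 at `frame_number = 1`, strictly
#'   decreasing for `T_merge < 1`.
#' @examples
#' discount_threshold(0.875, 3)  # 0.875^2
#' @export
discount_threshold <- function(T_merge, frame_number) {
  if (any(frame_number < 1)) stop("frame_number must be >= 1", call. = FALSE)
  T_merge^(frame_number - 1)
}

## ------------------------------------------------------------------------
## internal helpers shared by the linkers

node_key <- function(frame, label) paste(frame, label, sep = ":")

# labels present at frame f (0-based) according to the matrix chain
labels_at_frame <- function(matrices, f) {
  T_frames <- length(matrices) + 1L
  nm <- if (f < T_frames - 1L) rownames(matrices[[f + 1L]]) else colnames(matrices[[T_frames - 1L]])
  if (is.null(nm)) character(0) else nm
}

validate_chain <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  for (t in seq_along(matrices)) {
    m <- matrices[[t]]
    stopifnot(is.matrix(m))
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)))
    if (t > 1L && !identical(colnames(matrices[[t - 1L]]), rownames(m))) {
      stop("inconsistent score-matrix chain at frame pair ", t - 1,
           call. = FALSE)
    }
    if (any(m < 0) || any(m > 1)) {
      stop("score-matrix entries must lie in [0, 1]", call. = FALSE)
    }
    matrices[[t]] <- m
  }
  matrices
}

# assemble a tracking_result object from per-track records
new_tracking_result <- function(tracks, method, params) {
  rows <- lapply(tracks, function(tr) {
    len <- length(tr$frames)
    steps <- c(NA_real_, tr$step_scores)
    acc <- c(1, cumprod(tr$step_scores))
    tibble::tibble(track_id = tr$id, frame = as.integer(tr$frames),
                   cell_label = as.integer(tr$labels),
                   step_score = steps[seq_len(len)],
                   accumulated_score = acc[seq_len(len)],
                   status = tr$status)
  })
  tb <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(track_id = integer(), frame = integer(),
                   cell_label = integer(), step_score = numeric(),
                   accumulated_score = numeric(), status = character())
  }
  structure(list(tracks = tb, method = method, params = params,
                 merge_log = NULL, reroute_log = NULL),
            class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  n <- dplyr::n_distinct(x$tracks$track_id)
  cat("<tracking_result> method = ", x$method, ", ", n, " trajectories, ",
      nrow(x$tracks), " nodes\n", sep = "")
  invisible(x)
}

#' Tidy a tracking result into its node table
#'
#' @param x A `tracking_result`.
#' @param ... Unused.
#' @return Tibble with one row per (track, frame) node: `track_id`, `frame`,
#'   `cell_label`, `step_score`, `accumulated_score`, `status`.
#' @exportS3Method generics::tidy
tidy.tracking_result <- function(x, ...) x$tracks

#' One-row summary of a tracking result
#'
#' @param x A `tracking_result`.
#' @param ... Unused.
#' @return Tibble with `method`, `n_tracks`, `avg_track_length`,
#'   `n_merged_nodes`, `n_rerouted`.
#' @exportS3Method generics::glance
glance.tracking_result <- function(x, ...) {
  lens <- dplyr::count(x$tracks, .data$track_id)$n
  tibble::tibble(
    method = x$method,
    n_tracks = length(lens),
    avg_track_length = if (length(lens)) mean(lens) else NA_real_,
    n_merged_nodes = if (is.null(x$merge_log)) 0L else nrow(x$merge_log),
    n_rerouted = if (is.null(x$reroute_log)) 0L else nrow(x$reroute_log)
  )
}

## ------------------------------------------------------------------------

#' Greedy frame-to-frame linkage
#'
#' Starts from every cell in the first frame and links, frame by frame, to
#' the next-frame candidate with the highest score. On an exact tie the
#' first (lowest-label) candidate is linked. Each detection can be passed by
#' only one trajectory; a track whose best candidates are already claimed
#' ends, and every unclaimed detection starts a new trajectory.
#'
#' @param matrices List of score matrices (rows = cells at `t`, columns =
#'   cells at `t + 1`, entries in `[0, 1]`).
#'
#' @return A `tracking_result`.
#' @export
link_greedy_delta <- function(matrices) {
  matrices <- validate_chain(matrices)
  T_frames <- length(matrices) + 1L
  tracks <- list()
  add_track <- function(f, lab) {
    tracks[[length(tracks) + 1L]] <<- list(id = length(tracks) + 1L,
                                           frames = f, labels = as.integer(lab),
                                           step_scores = numeric(0),
                                           status = "active")
    length(tracks)
  }
  for (lab in labels_at_frame(matrices, 0L)) add_track(0L, lab)
  for (t in seq_len(T_frames - 1L) - 1L) {
    m <- matrices[[t + 1L]]
    claimed <- character(0)
    for (k in seq_along(tracks)) {
      tr <- tracks[[k]]
      if (tr$status != "active" || tail(tr$frames, 1L) != t) next
      row <- stats::setNames(as.vector(m[as.character(tail(tr$labels, 1L)), ,
                                         drop = FALSE]), colnames(m))
      if (ncol(m) == 0L || all(row <= 0)) {
        tracks[[k]]$status <- "ended_zero_scores"
        next
      }
      avail <- setdiff(colnames(m)[row > 0], claimed)
      if (!length(avail)) {
        tracks[[k]]$status <- "ended_no_available_cell"
        next
      }
      best <- avail[which.max(row[avail])]
      claimed <- c(claimed, best)
      tracks[[k]]$frames <- c(tr$frames, t + 1L)
      tracks[[k]]$labels <- c(tr$labels, as.integer(best))
      tracks[[k]]$step_scores <- c(tr$step_scores, row[[best]])
    }
    for (lab in setdiff(colnames(m), claimed)) add_track(t + 1L, lab)
  }
  for (k in seq_along(tracks)) {
    if (tracks[[k]]$status == "active") tracks[[k]]$status <- "ended_last_frame"
  }
  new_tracking_result(tracks, "greedy", linkage_params())
}

#' Hungarian assignment linkage
#'
#' For every adjacent frame pair, solves the maximum-score one-to-one
#' assignment between current detections and next-frame detections.
#' Assignments scoring below `end_threshold` are cut, ending the track;
#' detections left unassigned start new trajectories.
#'
#' @inheritParams link_greedy_delta
#' @param params A [linkage_params()] object; `end_threshold` is the cut.
#'
#' @return A `tracking_result`.
#' @export
link_hungarian <- function(matrices, params = linkage_params()) {
  matrices <- validate_chain(matrices)
  T_frames <- length(matrices) + 1L
  tracks <- list()
  add_track <- function(f, lab) {
    tracks[[length(tracks) + 1L]] <<- list(id = length(tracks) + 1L,
                                           frames = f, labels = as.integer(lab),
                                           step_scores = numeric(0),
                                           status = "active")
  }
  for (lab in labels_at_frame(matrices, 0L)) add_track(0L, lab)
  for (t in seq_len(T_frames - 1L) - 1L) {
    m <- matrices[[t + 1L]]
    assign <- solve_assignment_max(m)
    linked_cols <- character(0)
    for (k in seq_along(tracks)) {
      tr <- tracks[[k]]
      if (tr$status != "active" || tail(tr$frames, 1L) != t) next
      i <- match(as.character(tail(tr$labels, 1L)), rownames(m))
      j <- if (length(i) && !is.na(i)) assign[i] else NA_integer_
      s <- if (!is.na(j)) m[i, j] else 0
      if (is.na(j) || s < params$end_threshold) {
        row_all_zero <- ncol(m) == 0L || all(m[i, ] <= 0)
        tracks[[k]]$status <- if (row_all_zero) "ended_zero_scores"
          else if (is.na(j) || s <= 0) "ended_no_available_cell"
          else "truncated_disappeared"
        next
      }
      linked_cols <- c(linked_cols, colnames(m)[j])
      tracks[[k]]$frames <- c(tr$frames, t + 1L)
      tracks[[k]]$labels <- c(tr$labels, as.integer(colnames(m)[j]))
      tracks[[k]]$step_scores <- c(tr$step_scores, s)
    }
    for (lab in setdiff(colnames(m), linked_cols)) add_track(t + 1L, lab)
  }
  for (k in seq_along(tracks)) {
    if (tracks[[k]]$status == "active") tracks[[k]]$status <- "ended_last_frame"
  }
  new_tracking_result(tracks, "hungarian", params)
}

## ------------------------------------------------------------------------
## Viterbi routing core. Forward dynamic programming in log space over the
## score-matrix chain (routing phase), then backward retrieval of the
## argmax path. `occ` is NULL for the basic algorithm; for the extended
## algorithm it is an environment mapping node keys to occupant entries
## list(track_id, acc_log, disc_log), consulted through merge Conditions 1
## and 2 with the geometrically discounted threshold.
route_track <- function(matrices, seed_frame, seed_label, params,
                        occ = NULL, init_acc_log = 0, forbidden = character(0),
                        reroute_allowed = TRUE) {
  T_frames <- length(matrices) + 1L
  eps <- 1e-12
  log_tm <- if (params$T_merge > 0) log(params$T_merge) else -Inf
  V <- stats::setNames(init_acc_log, as.character(seed_label))
  back <- vector("list", T_frames)   # back[[f+1]][label] = predecessor label
  vals <- vector("list", T_frames)
  vals[[seed_frame + 1L]] <- V
  end_frame <- seed_frame
  status <- "ended_last_frame"
  n_blocked <- 0L
  f <- seed_frame
  while (f < T_frames - 1L) {
    m <- matrices[[f + 1L]]
    frontier <- names(V)[order(as.integer(names(V)))]
    layer_rel <- (f + 1L) - seed_frame + 1L     # frame_number, birth = 1
    disc_log <- (layer_rel - 1L) * log_tm       # log discounted threshold
    newV <- numeric(0)
    newback <- character(0)
    saw_nonzero <- FALSE
    saw_linkable <- FALSE    # a transition >= T_truncated existed
    for (j in colnames(m)) {
      if (node_key(f + 1L, j) %in% forbidden) next
      occ_entries <- if (!is.null(occ)) occ$map[[node_key(f + 1L, j)]] else NULL
      best_v <- -Inf
      best_i <- NA_character_
      for (i in frontier) {
        s <- m[i, j]
        if (s <= 0) next
        saw_nonzero <- TRUE
        if (s < params$T_truncated) next
        saw_linkable <- TRUE
        v <- V[[i]] + log(s)
        if (!is.null(occ_entries) && length(occ_entries)) {
          occ_acc <- vapply(occ_entries, `[[`, numeric(1), "acc_log")
          occ_disc <- vapply(occ_entries, `[[`, numeric(1), "disc_log")
          cond1 <- v >= disc_log - eps
          cond2 <- all(occ_acc < occ_disc - eps)
          rr <- reroute_allowed &&
            v > log(params$reroute_factor) + max(occ_acc) + eps
          if (!cond1 && !cond2 && !rr) {
            n_blocked <- n_blocked + 1L
            next
          }
        }
        if (v > best_v + eps) {
          best_v <- v
          best_i <- i
        }
      }
      if (is.finite(best_v)) {
        newV[[j]] <- best_v
        newback[[j]] <- best_i
      }
    }
    if (!length(newV)) {
      status <- if (!saw_nonzero) "ended_zero_scores"
        else if (saw_linkable) "ended_no_available_cell"
        else "truncated_disappeared"
      break
    }
    V <- newV
    back[[f + 2L]] <- newback
    vals[[f + 2L]] <- newV
    f <- f + 1L
    end_frame <- f
  }
  # retrieval phase: best end node, ties toward the lower cell label
  endV <- vals[[end_frame + 1L]]
  ord <- order(as.integer(names(endV)))
  endV <- endV[ord]
  lab <- names(endV)[which.max(endV)]
  labels <- character(end_frame - seed_frame + 1L)
  labels[length(labels)] <- lab
  if (end_frame > seed_frame) {
    for (ff in end_frame:(seed_frame + 1L)) {
      lab <- back[[ff + 1L]][[lab]]
      labels[ff - seed_frame] <- lab
    }
  }
  frames <- seed_frame:end_frame
  steps <- if (length(frames) > 1L) {
    vapply(seq_len(length(frames) - 1L), function(k) {
      matrices[[frames[k] + 1L]][labels[k], labels[k + 1L]]
    }, numeric(1))
  } else numeric(0)
  acc_log <- init_acc_log + cumsum(c(0, log(pmax(steps, .Machine$double.xmin))))
  list(frames = frames, labels = labels, step_scores = steps,
       acc_log = acc_log, status = status, n_blocked = n_blocked)
}

#' Basic Viterbi linkage
#'
#' For each first-frame cell (and, iteratively, each detection not covered
#' by an existing trajectory), dynamic programming maximizes the product of
#' step scores over the whole score-matrix chain, followed by a backward
#' retrieval of the argmax path. No occupancy constraints are applied, so
#' after a cell merge independent tracks can collapse onto shared nodes.
#' The optional post-processing truncates a trajectory at the first step
#' whose score falls below the preceding step's score once the trajectory
#' has entered a node shared with another trajectory (status
#' `"truncated_postprocessed"`).
#'
#' @inheritParams link_hungarian
#' @param truncate Apply the shared-node truncation post-processing
#'   (default `TRUE`).
#'
#' @return A `tracking_result`.
#' @export
link_viterbi_basic <- function(matrices, params = linkage_params(),
                               truncate = TRUE) {
  matrices <- validate_chain(matrices)
  T_frames <- length(matrices) + 1L
  covered <- character(0)
  tracks <- list()
  for (f in seq_len(T_frames) - 1L) {
    for (lab in labels_at_frame(matrices, f)) {
      if (node_key(f, lab) %in% covered) next
      r <- route_track(matrices, f, lab, params, occ = NULL)
      covered <- union(covered, node_key(r$frames, r$labels))
      tracks[[length(tracks) + 1L]] <-
        list(id = length(tracks) + 1L, frames = r$frames,
             labels = as.integer(r$labels), step_scores = r$step_scores,
             status = r$status)
    }
  }
  if (truncate && length(tracks) > 1L) {
    keys <- unlist(lapply(tracks, function(tr) node_key(tr$frames, tr$labels)))
    shared <- names(which(table(keys) >= 2L))
    for (k in seq_along(tracks)) {
      tr <- tracks[[k]]
      nk <- node_key(tr$frames, tr$labels)
      ent <- which(nk %in% shared)
      if (!length(ent)) next
      len <- length(tr$frames)
      j0 <- max(2L, ent[1])
      cut <- NA_integer_
      for (j in seq(j0, len - 1L)) {
        if (j >= 2L && tr$step_scores[j] < tr$step_scores[j - 1L]) {
          cut <- j
          break
        }
      }
      if (!is.na(cut)) {
        tracks[[k]]$frames <- tr$frames[seq_len(cut)]
        tracks[[k]]$labels <- tr$labels[seq_len(cut)]
        tracks[[k]]$step_scores <- tr$step_scores[seq_len(cut - 1L)]
        tracks[[k]]$status <- "truncated_postprocessed"
      }
    }
  }
  new_tracking_result(tracks, "viterbi", params)
}

#' Extended Viterbi linkage with merge/split and reroute handling
#'
#' Routes trajectories sequentially — first-frame cells in ascending label
#' order, then every detection left uncovered, in frame order — each by the
#' forward/backward Viterbi phases of [link_viterbi_basic()], but consulting
#' a shared occupancy table: a detection already owned by other trajectories
#' is connectable only if the routing track's accumulated score is above the
#' discounted merge threshold (Condition 1), or all occupants' accumulated
#' scores at that node are below their discounted thresholds (Condition 2).
#' Transitions scoring below `T_truncated` are unavailable; a track whose
#' only continuations fall below the floor terminates as a disappearance.
#' Merged trajectories share nodes and split apart at the first layer where
#' their own best continuations diverge or the merge conditions fail. If a
#' later-routed track's accumulated score at a contested node strictly
#' exceeds `reroute_factor` times an occupant's, the occupant is reset at
#' the previous layer and re-routed with the contested node forbidden
#' (single sweep).
#'
#' @inheritParams link_hungarian
#'
#' @return A `tracking_result` whose `merge_log` records every shared node
#'   with the merge condition that admitted it, and `reroute_log` every
#'   reroute.
#' @examples
#' fix <- scripted_scenario("two_cells_cross_merge_split")
#' res <- link_viterbi_extended(fix$score_matrices)
#' glance(res)
#' @export
link_viterbi_extended <- function(matrices, params = linkage_params()) {
  matrices <- validate_chain(matrices)
  T_frames <- length(matrices) + 1L
  occ <- new.env(parent = emptyenv())
  occ$map <- list()
  tracks <- list()
  merge_log <- list()
  reroute_log <- list()
  blocked_total <- 0L
  log_tm <- if (params$T_merge > 0) log(params$T_merge) else -Inf

  register <- function(id, frames, labels, acc_log, birth_frame) {
    for (k in seq_along(frames)) {
      key <- node_key(frames[k], labels[k])
      disc <- (frames[k] - birth_frame) * log_tm
      occ$map[[key]] <- c(occ$map[[key]],
                          list(list(track_id = id, acc_log = acc_log[k],
                                    disc_log = disc)))
    }
  }
  unregister <- function(id, keys) {
    for (key in keys) {
      ent <- occ$map[[key]]
      keep <- vapply(ent, function(e) e$track_id != id, logical(1))
      occ$map[[key]] <- ent[keep]
      if (!length(occ$map[[key]])) occ$map[[key]] <- NULL
    }
  }

  route_and_place <- function(id, f0, lab0, init_acc = 0,
                              forbidden = character(0), allow_reroute = TRUE) {
    r <- route_track(matrices, f0, lab0, params, occ = occ,
                     init_acc_log = init_acc, forbidden = forbidden,
                     reroute_allowed = allow_reroute)
    blocked_total <<- blocked_total + r$n_blocked
    # resolve contested nodes before registering
    if (allow_reroute) {
      for (k in seq_along(r$frames)) {
        key <- node_key(r$frames[k], r$labels[k])
        ent <- occ$map[[key]]
        if (is.null(ent) || !length(ent)) next
        for (e in ent) {
          if (r$acc_log[k] > log(params$reroute_factor) + e$acc_log + 1e-12 &&
              can_reset(e$track_id, r$frames[k])) {
            reroute_occupant(e$track_id, r$frames[k], key)
            reroute_log[[length(reroute_log) + 1L]] <<-
              list(frame = r$frames[k], cell_label = as.integer(r$labels[k]),
                   winner = id, loser = e$track_id)
          } else {
            layer_rel <- r$frames[k] - f0 + 1L
            cond1 <- r$acc_log[k] >= (layer_rel - 1L) * log_tm - 1e-12
            cond2 <- all(vapply(ent, function(o) {
              o$acc_log < o$disc_log - 1e-12
            }, logical(1)))
            merge_log[[length(merge_log) + 1L]] <<-
              list(frame = r$frames[k], cell_label = as.integer(r$labels[k]),
                   track_id = id, other = e$track_id,
                   condition = if (cond1) 1L else if (cond2) 2L else NA_integer_)
          }
        }
      }
    }
    register(id, r$frames, r$labels, r$acc_log, f0)
    r
  }

  can_reset <- function(id, frame) {
    tr <- tracks[[id]]
    !is.null(tr) && length(tr$frames) > 0L && tr$frames[1] < frame
  }

  reroute_occupant <- function(id, frame, contested_key) {
    tr <- tracks[[id]]
    keep <- which(tr$frames < frame)
    drop_keys <- node_key(tr$frames[-keep], tr$labels[-keep])
    unregister(id, drop_keys)
    f0 <- tr$frames[max(keep)]
    lab0 <- tr$labels[max(keep)]
    init <- tr$acc_log[max(keep)]
    r <- route_track(matrices, f0, lab0, params, occ = occ,
                     init_acc_log = init, forbidden = contested_key,
                     reroute_allowed = FALSE)
    blocked_total <<- blocked_total + r$n_blocked
    # splice: keep prefix strictly before `frame`, then the re-routed tail
    nk <- length(keep)
    new_frames <- c(tr$frames[seq_len(nk - 1L)], r$frames)
    new_labels <- c(tr$labels[seq_len(nk - 1L)], r$labels)
    new_steps <- c(tr$step_scores[seq_len(nk - 1L)], r$step_scores)
    new_acc <- c(tr$acc_log[seq_len(nk - 1L)], r$acc_log)
    register(id, r$frames[-1L], r$labels[-1L], r$acc_log[-1L], tr$frames[1])
    tracks[[id]] <<- list(id = id, frames = new_frames,
                          labels = as.integer(new_labels),
                          step_scores = new_steps, acc_log = new_acc,
                          status = r$status)
  }

  add_routed <- function(f0, lab0) {
    id <- length(tracks) + 1L
    tracks[[id]] <<- list(id = id)  # reserve slot for can_reset()
    r <- route_and_place(id, f0, lab0)
    tracks[[id]] <<- list(id = id, frames = r$frames,
                          labels = as.integer(r$labels),
                          step_scores = r$step_scores, acc_log = r$acc_log,
                          status = r$status)
  }

  for (lab in labels_at_frame(matrices, 0L)) add_routed(0L, lab)
  # appearance pass: every detection not covered by any trajectory seeds one
  for (f in seq_len(T_frames - 1L)) {
    for (lab in labels_at_frame(matrices, f)) {
      if (!is.null(occ$map[[node_key(f, lab)]])) next
      add_routed(f, lab)
    }
  }

  res <- new_tracking_result(tracks, "viterbi_ext", params)
  res$n_blocked <- blocked_total
  res$merge_log <- if (length(merge_log)) {
    dplyr::bind_rows(lapply(merge_log, tibble::as_tibble))
  } else {
    tibble::tibble(frame = integer(), cell_label = integer(),
                   track_id = integer(), other = integer(),
                   condition = integer())
  }
  res$reroute_log <- if (length(reroute_log)) {
    dplyr::bind_rows(lapply(reroute_log, tibble::as_tibble))
  } else {
    tibble::tibble(frame = integer(), cell_label = integer(),
                   winner = integer(), loser = integer())
  }
  res
}

#' Link a score-matrix chain with a chosen method
#'
#' Convenience dispatcher over the four linkage algorithms.
#'
#' @inheritParams link_hungarian
#' @param method One of `"greedy"`, `"hungarian"`, `"viterbi"`,
#'   `"viterbi_ext"`.
#' @param ... Passed to the underlying linker.
#'
#' @return A `tracking_result`.
#' @export
link_tracks <- function(matrices, method = c("viterbi_ext", "greedy",
                                             "hungarian", "viterbi"),
                        params = linkage_params(), ...) {
  method <- match.arg(method)
  switch(method,
         greedy = link_greedy_delta(matrices),
         hungarian = link_hungarian(matrices, params),
         viterbi = link_viterbi_basic(matrices, params, ...),
         viterbi_ext = link_viterbi_extended(matrices, params))
}
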