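test_that("the merge-threshold discount follows its closed form", {
  expect_equal(discount_threshold(0.875, 1), 1)
  expect_equal(discount_threshold(0.875, 2), 0.875)
  expect_equal(discount_threshold(0.875, 3), 0.765625)
  expect_true(all(diff(discount_threshold(0.875, 1:50)) < 0))
  expect_error(discount_threshold(0.875, 0))
})

test_that("the assignment solver matches brute-force enumeration", {
  set.seed(9)
  for (k in 1:30) {
    nr <- sample(1:5, 1)
    nc <- sample(1:5, 1)
    m <- matrix(round(runif(nr * nc), 2), nr, nc)  # rounding induces ties
    a <- neutrack:::solve_assignment_max(m)
    got <- sum(m[cbind(which(!is.na(a)), a[!is.na(a)])])
    expect_equal(got, oracle_assignment_max(m), tolerance = 1e-9)
  }
  # the documented 2x2 swap: optimal total 1.0 beats the greedy 0.7
  swap <- matrix(c(0.6, 0.5, 0.5, 0.1), 2, 2)
  expect_equal(neutrack:::solve_assignment_max(swap), c(2L, 1L))
})

test_that("greedy linkage follows the first-candidate tie rule and claims", {
  mats <- diagonal_chain(3, 5)
  res <- link_greedy_delta(mats)
  tb <- tidy(res)
  expect_equal(dplyr::n_distinct(tb$track_id), 3)
  expect_true(all(dplyr::count(tb, .data$track_id)$n == 5))
  expect_true(all(tb$status == "ended_last_frame"))

  # a zero row ends the track at that frame
  z <- diagonal_chain(2, 4)
  z[[2]][1, ] <- 0
  tz <- tidy(link_greedy_delta(z))
  t1 <- tz[tz$track_id == 1, ]
  expect_equal(max(t1$frame), 1)
  expect_equal(unique(t1$status), "ended_zero_scores")

  # two rows sharing one best column: the first row takes it
  m <- matrix(c(0.9, 0.9, 0, 0.2), 2, 2,
              dimnames = list(c("1", "2"), c("1", "2")))
  tt <- tidy(link_greedy_delta(list(m)))
  expect_equal(tt$cell_label[tt$track_id == 1 & tt$frame == 1], 1L)
  expect_equal(tt$cell_label[tt$track_id == 2 & tt$frame == 1], 2L)
})

test_that("hungarian linkage finds the swap the greedy misses and cuts weak links", {
  swap <- list(matrix(c(0.6, 0.5, 0.5, 0.1), 2, 2,
                      dimnames = list(c("1", "2"), c("1", "2"))))
  h <- tidy(link_hungarian(swap))
  expect_equal(h$cell_label[h$track_id == 1 & h$frame == 1], 2L)
  expect_equal(h$cell_label[h$track_id == 2 & h$frame == 1], 1L)
  total_h <- sum(h$step_score, na.rm = TRUE)
  total_g <- sum(tidy(link_greedy_delta(swap))$step_score, na.rm = TRUE)
  expect_gt(total_h, total_g)
  expect_equal(total_h, 1.0)
  expect_equal(total_g, 0.7)

  # all scores below the end threshold terminate every track
  low <- list(matrix(0.0005, 2, 2, dimnames = list(c("1", "2"), c("1", "2"))))
  tl <- tidy(link_hungarian(low, linkage_params(end_threshold = 0.001)))
  expect_true(all(tl$frame[tl$track_id %in% 1:2] == 0))
  expect_setequal(unique(tl$status[tl$track_id %in% 1:2]),
                  "truncated_disappeared")
})

test_that("basic viterbi maximizes the product over the whole chain", {
  one <- diagonal_chain(1, 6)
  tb <- tidy(link_viterbi_basic(one, truncate = FALSE))
  expect_equal(tail(tb$accumulated_score, 1), 1)
  # greedy trap: first hop 0.9 then 0.1 (product 0.09) loses to 0.8 * 0.9
  m1 <- matrix(c(0.9, 0.8), 1, 2, dimnames = list("1", c("1", "2")))
  m2 <- matrix(c(0.1, 0, 0, 0.9), 2, 2,
               dimnames = list(c("1", "2"), c("1", "2")))
  tb2 <- tidy(link_viterbi_basic(list(m1, m2), truncate = FALSE))
  t1 <- tb2[tb2$track_id == 1, ]
  expect_equal(t1$cell_label, c(1L, 2L, 2L))
  expect_equal(tail(t1$accumulated_score, 1), 0.72)
})

test_that("basic and extended viterbi match exhaustive enumeration on small chains", {
  set.seed(10)
  params <- linkage_params(T_truncated = 0)
  n_checked_ext <- 0
  for (k in 1:40) {
    sizes <- sample(2:4, sample(3:5, 1), replace = TRUE)
    mats <- random_chain(sizes)
    res <- link_viterbi_basic(mats, params, truncate = FALSE)
    tb <- tidy(res)
    for (lab in seq_len(sizes[1])) {
      o <- oracle_best_path(mats, 0, lab)
      tr <- tb[tb$track_id == lab, ]
      expect_equal(tr$cell_label, o$labels)
      expect_equal(log(tail(tr$accumulated_score, 1)), o$log_score,
                   tolerance = 1e-9)
    }
    ext <- link_viterbi_extended(mats, params)
    if (ext$n_blocked == 0 && nrow(ext$merge_log) == 0 &&
        nrow(ext$reroute_log) == 0) {
      n_checked_ext <- n_checked_ext + 1
      te <- tidy(ext)
      for (lab in seq_len(sizes[1])) {
        o <- oracle_best_path(mats, 0, lab)
        tr <- te[te$track_id == lab, ]
        expect_equal(tr$cell_label, o$labels)
      }
    }
  }
  expect_gt(n_checked_ext, 0)
})

test_that("extended viterbi resolves the crossing merge/split; the baselines fail it", {
  fx <- scripted_scenario("two_cells_cross_merge_split")
  mats <- fx$score_matrices
  g <- fx$tracks

  res <- link_viterbi_extended(mats)
  tb <- tidy(res)
  expect_equal(dplyr::n_distinct(tb$track_id), 2)
  for (id in 1:2) {
    got <- tb[tb$track_id == id, ]
    want <- g[g$track_id == id, ]
    expect_equal(got$frame, want$frame)
    expect_equal(got$cell_label, want$label)   # full ground-truth linkage
  }
  # shared detection carried by both tracks during the merge interval
  shared <- tb[tb$frame %in% 4:6, ]
  expect_true(all(table(shared$frame) == 2))
  expect_true(all(!is.na(res$merge_log$condition)))

  # greedy loses the second cell at the collision
  tg <- tidy(link_greedy_delta(mats))
  expect_gt(dplyr::n_distinct(tg$track_id), 2)
  expect_equal(max(tg$frame[tg$track_id == 2]), 3)
  # basic viterbi collapses both tracks onto the same exit
  tv <- tidy(link_viterbi_basic(mats, truncate = FALSE))
  exit1 <- tv$cell_label[tv$track_id == 1 & tv$frame == 9]
  exit2 <- tv$cell_label[tv$track_id == 2 & tv$frame == 9]
  expect_equal(exit1, exit2)
})

test_that("basic-viterbi truncation cuts decreasing steps after shared entry", {
  fx <- scripted_scenario("two_cells_cross_merge_split")
  tt <- tidy(link_viterbi_basic(fx$score_matrices, truncate = TRUE))
  cut <- tt |>
    dplyr::filter(.data$status == "truncated_postprocessed") |>
    dplyr::distinct(.data$track_id)
  expect_equal(nrow(cut), 2)
  expect_lt(max(tt$frame[tt$track_id == 1]), 9)
})

test_that("sub-threshold scores terminate a track as disappeared", {
  mats <- diagonal_chain(1, 5, s = 0.9)
  mats[[3]][1, 1] <- 5e-4   # below the 0.001 floor at frame 2 -> 3
  tb <- tidy(link_viterbi_extended(mats))
  t1 <- tb[tb$track_id == 1, ]
  expect_equal(max(t1$frame), 2)
  expect_equal(unique(t1$status), "truncated_disappeared")
  # the stranded tail detections seed a new trajectory (appearance rule)
  expect_equal(dplyr::n_distinct(tb$track_id), 2)
  expect_equal(min(tb$frame[tb$track_id == 2]), 3)
})

test_that("an uncovered detection seeds a new trajectory at its frame", {
  mats <- diagonal_chain(1, 9, s = 0.9)   # frames 0..8
  # a second cell appears at frame 7 with no inbound scores
  mats[[7]] <- cbind(mats[[7]], `2` = 0)            # 6 -> 7 gains cell 2
  mats[[8]] <- rbind(mats[[8]], `2` = 0)            # 7 -> 8 row for cell 2
  mats[[8]] <- cbind(mats[[8]], `2` = c(0, 0.8))
  tb <- tidy(link_viterbi_extended(mats))
  expect_equal(dplyr::n_distinct(tb$track_id), 2)
  t2 <- tb[tb$track_id == 2, ]
  expect_equal(min(t2$frame), 7)
  expect_equal(max(t2$frame), 8)
})

test_that("a clearly better later track reroutes the earlier occupant", {
  m <- matrix(c(0.5, 0.9, 0.4, 0), 2, 2,
              dimnames = list(c("1", "2"), c("1", "2")))
  res <- link_viterbi_extended(list(m))
  tb <- tidy(res)
  expect_equal(nrow(res$reroute_log), 1)
  expect_equal(res$reroute_log$winner, 2L)
  expect_equal(res$reroute_log$loser, 1L)
  expect_equal(tb$cell_label[tb$track_id == 2 & tb$frame == 1], 1L)
  expect_equal(tb$cell_label[tb$track_id == 1 & tb$frame == 1], 2L)
})

test_that("linkage invariants: conservation, monotone accumulation, merge soundness", {
  set.seed(11)
  for (k in 1:10) {
    sizes <- sample(2:4, 4, replace = TRUE)
    mats <- random_chain(sizes, zero_frac = 0.4)
    for (method in c("greedy", "hungarian", "viterbi_ext")) {
      res <- link_tracks(mats, method = method)
      tb <- tidy(res)
      # conservation: every detection covered by >= 1 trajectory
      for (f in seq_along(sizes) - 1L) {
        labs <- as.integer(neutrack:::labels_at_frame(mats, f))
        expect_true(all(labs %in% tb$cell_label[tb$frame == f]))
      }
      # accumulated product is non-increasing and consistent in log space
      for (id in unique(tb$track_id)) {
        acc <- tb$accumulated_score[tb$track_id == id]
        steps <- tb$step_score[tb$track_id == id]
        expect_true(all(diff(acc) <= 1e-12))
        expect_equal(log(acc[length(acc)]),
                     sum(log(steps[-1])), tolerance = 1e-12)
      }
      if (method == "viterbi_ext") {
        expect_true(all(res$merge_log$condition %in% c(1L, 2L)))
      }
    }
  }
})

test_that("identity chains give every linker one full track per cell", {
  mats <- diagonal_chain(4, 6, s = 0.9)
  for (method in c("greedy", "hungarian", "viterbi", "viterbi_ext")) {
    tb <- tidy(link_tracks(mats, method = method))
    expect_equal(dplyr::n_distinct(tb$track_id), 4)
    expect_true(all(dplyr::count(tb, .data$track_id)$n == 6))
  }
})
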