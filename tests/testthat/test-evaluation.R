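# a simple two-track ground truth moving apart on parallel lines
make_gt <- function(n_frames = 10, n_tracks = 2, spacing = 40) {
  dplyr::bind_rows(lapply(seq_len(n_tracks), function(id) {
    tibble::tibble(track_id = id, frame = 0:(n_frames - 1),
                   x = 10 + 2 * (0:(n_frames - 1)),
                   y = spacing * id)
  }))
}

test_that("identification matches exact predictions and rejects distant ones", {
  gt <- make_gt()
  m <- match_identities(gt, gt, radius = 5)
  expect_equal(nrow(m$events), nrow(gt))
  expect_equal(m$matching$matched_gt, m$matching$track_id)
  far <- dplyr::mutate(gt, y = y + 1000)
  m2 <- match_identities(far, gt, radius = 5)
  expect_equal(nrow(m2$events), 0)
  expect_equal(nrow(m2$matching), 0)
})

test_that("majority matching assigns a drifting track to its dominant object", {
  gt <- make_gt(10)
  pred <- gt[gt$track_id == 1, ]
  # follow object 1 for 6 frames then object 2 for 4
  swap <- pred$frame >= 6
  pred$y[swap] <- 80
  m <- match_identities(pred, gt, radius = 5)
  expect_equal(m$matching$matched_gt, 1L)
  expect_equal(m$matching$n_support, 6L)
})

test_that("metrics are exact on perfect, half-correct, and mixed-length predictions", {
  gt <- make_gt()
  perfect <- compute_metrics(gt, gt, radius = 5)
  expect_equal(perfect$tp, 1)
  expect_equal(perfect$op, 1)
  expect_equal(perfect$fit, 0)
  expect_equal(perfect$fio, 0)
  expect_equal(perfect$avg_track_length, 10)

  # one 10-frame track correct in 5 frames contributes purity 0.5
  half <- gt[gt$track_id == 1, ]
  half$y[half$frame >= 5] <- 500   # off anything for 5 frames
  m <- compute_metrics(half, gt[gt$track_id == 1, ], radius = 5)
  expect_equal(m$tp, 0.5)
  expect_equal(m$op, 0.5)

  # predicted tracks of lengths 3 and 5 average 4
  p <- dplyr::bind_rows(gt[gt$track_id == 1 & gt$frame < 3, ],
                        gt[gt$track_id == 2 & gt$frame < 5, ])
  expect_equal(compute_metrics(p, gt, radius = 5)$avg_track_length, 4)
  expect_warning(
    empty <- compute_metrics(gt[0, ], gt, radius = 5), "empty")
  expect_equal(empty$tp, 0)
})

test_that("purities are invariant to predicted track relabeling", {
  gt <- make_gt()
  relab <- dplyr::mutate(gt, track_id = track_id + 100)
  a <- compute_metrics(gt, gt, radius = 5)
  b <- compute_metrics(relab, gt, radius = 5)
  expect_equal(a$tp, b$tp)
  expect_equal(a$op, b$op)
})

test_that("nested corruption degrades purities and inflates error rates monotonically", {
  gt <- make_gt(20)
  res <- lapply(c(0, 0.1, 0.3, 0.5), function(k) {
    compute_metrics(corrupt_tracks(gt, k), gt, radius = 5)
  })
  tp <- vapply(res, `[[`, numeric(1), "tp")
  op <- vapply(res, `[[`, numeric(1), "op")
  fit <- vapply(res, `[[`, numeric(1), "fit")
  fio <- vapply(res, `[[`, numeric(1), "fio")
  expect_true(all(diff(tp) <= 0))
  expect_true(all(diff(op) <= 0))
  expect_true(all(diff(fit) >= 0))
  expect_true(all(diff(fio) >= 0))
  expect_lt(tp[4], 1)
  expect_gt(fio[4], 0)
})

test_that("kruskal-wallis omnibus matches the hand-computed rank statistic", {
  d <- tibble::tibble(
    method = rep(c("a", "b", "c"), each = 3),
    metric = c(1, 2, 3, 101, 102, 103, 1, 2, 3)
  )
  cmp <- compare_methods(d, metrics = "metric", alpha = 0.1)
  # rank sums 10.5 / 24 / 10.5 on N = 9 with three tied pairs:
  # H = (12 / (9 * 10)) * sum(R^2 / 3) - 3 * 10, tie-corrected by
  # 1 - sum(t^3 - t) / (N^3 - N) = 0.975
  h_hand <- ((12 / 90) * (10.5^2 + 24^2 + 10.5^2) / 3 - 30) / 0.975
  expect_equal(cmp$omnibus$statistic, h_hand, tolerance = 1e-10)
  expect_lt(cmp$omnibus$p_value, 0.1)
  expect_equal(nrow(cmp$posthoc), 3)
  expect_true(all(cmp$posthoc$p_adjusted >= cmp$posthoc$p_value))
  # identical samples across methods -> p = 1, no post-hoc
  same <- tibble::tibble(method = rep(c("a", "b"), each = 3),
                         metric = rep(c(1, 2, 3), 2))
  cs <- compare_methods(same, metrics = "metric")
  expect_gt(cs$omnibus$p_value, 0.9)
  expect_equal(nrow(cs$posthoc), 0)
})

test_that("benjamini-hochberg adjustment follows the step-up formula", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               c(0.03, 0.03, 0.03))
  # dunn z for two groups equals the normalized mean-rank difference
  x <- c(1, 2, 3, 101, 102, 103)
  g <- factor(rep(c("a", "b"), each = 3))
  dz <- neutrack:::dunn_test(x, g)
  se <- sqrt((6 * 7 / 12) * (1 / 3 + 1 / 3))
  expect_equal(dz$z, (2 - 5) / se)
})
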