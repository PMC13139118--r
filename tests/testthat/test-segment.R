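test_that("reference segmenter labels 8-connected bright regions", {
  expect_equal(max(segment_reference(matrix(0, 16, 16))), 0L)
  # one rendered disc: labeled area close to the analytic disc area
  cells <- tibble::tibble(x = 15, y = 15, radius = 5)
  img <- 0.05 + neutrack:::render_cells(cells, c(32, 32))
  mask <- segment_reference(img, t = 0.1)
  expect_equal(max(mask), 1L)
  # analytic pixel count above threshold from the Gaussian rendering model:
  # profile = exp(-d^2 / 2 sigma^2) with sigma = radius / sqrt(2 log 5)
  cutoff <- min(img) + 0.1 * diff(range(img))
  d_cut <- (5 / sqrt(2 * log(5))) * sqrt(2 * log(1 / (cutoff - 0.05)))
  grid <- expand.grid(y = 0:31, x = 0:31)
  analytic <- sum((grid$x - 15)^2 + (grid$y - 15)^2 <= d_cut^2)
  expect_lt(abs(sum(mask > 0) - analytic) / analytic, 0.15)
  # two separated discs -> two labels
  two <- 0.05 + neutrack:::render_cells(
    tibble::tibble(x = c(8, 24), y = c(8, 24), radius = 4), c(32, 32))
  expect_equal(max(segment_reference(two, t = 0.1)), 2L)
  # diagonal adjacency is one component (8-connectivity)
  diagimg <- matrix(0, 8, 8)
  diagimg[cbind(2:5, 2:5)] <- 1
  expect_equal(max(segment_reference(diagimg, t = 0.5, min_area = 1)), 1L)
  # min_area suppresses specks and keeps labels contiguous
  speck <- matrix(0, 16, 16)
  speck[2, 2] <- 1
  speck[8:12, 8:12] <- 1
  m <- segment_reference(speck, t = 0.5, min_area = 5)
  expect_equal(sort(unique(as.vector(m))), c(0L, 1L))
})

test_that("raising the threshold never increases the foreground", {
  set.seed(6)
  f <- matrix(runif(400), 20, 20)
  fg <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
               function(t) sum(segment_reference(f, t, min_area = 1) > 0),
               numeric(1))
  expect_true(all(diff(fg) <= 0))
})

test_that("detections carry centroid and area", {
  expect_equal(nrow(extract_detections(matrix(0L, 4, 4))), 0)
  m <- matrix(0L, 4, 4)
  m[1:2, 1:2] <- 1L
  d <- extract_detections(m, frame_index = 7)
  expect_equal(d$x, 0.5)
  expect_equal(d$y, 0.5)
  expect_equal(d$area, 4L)
  expect_equal(d$frame, 7L)
  m[4, 4] <- 2L
  expect_equal(nrow(extract_detections(m)), 2)
})

test_that("segmentation evaluation follows the mutual-maximal matching rule", {
  m <- matrix(0L, 8, 8)
  m[2:3, 2:3] <- 1L
  m[6:7, 6:7] <- 2L
  same <- evaluate_segmentation(m, m)
  expect_equal(same$iou, 1)
  expect_equal(same$f1, 1)
  expect_equal(same$fn, 0L)
  expect_equal(same$n_under + same$n_over, 0L)

  other <- matrix(0L, 8, 8)
  other[2:3, 6:7] <- 1L
  disj <- evaluate_segmentation(other, m[, , drop = FALSE])
  expect_equal(disj$iou, 0)
  expect_equal(disj$true_pos, 0L)
  expect_equal(disj$fp, 1L)
  expect_equal(disj$fn, 2L)

  # one prediction spanning two truth squares: under-segmentation, and the
  # unmatched truth square becomes a false negative
  truth <- matrix(0L, 6, 10)
  truth[2:3, 2:3] <- 1L
  truth[2:3, 6:7] <- 2L
  pred <- matrix(0L, 6, 10)
  pred[2:3, 2:7] <- 1L
  r <- evaluate_segmentation(pred, truth)
  expect_equal(r$n_under, 1L)
  expect_equal(r$true_pos, 1L)
  expect_equal(r$fn, 1L)
  expect_equal(r$fp, 0L)
  # over-segmentation mirror image
  r2 <- evaluate_segmentation(truth, pred)
  expect_equal(r2$n_over, 1L)
  expect_error(evaluate_segmentation(matrix(0L, 2, 2), matrix(0L, 3, 3)),
               "mismatch")
})

test_that("IoU is symmetric and F1 is consistent with its counts", {
  set.seed(7)
  for (k in 1:5) {
    a <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
    b <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
    ab <- evaluate_segmentation(a, b)
    ba <- evaluate_segmentation(b, a)
    expect_equal(ab$iou, ba$iou)
    expect_equal(ab$f1,
                 2 * ab$true_pos / (2 * ab$true_pos + ab$fp + ab$fn),
                 tolerance = 1e-12)
  }
})

test_that("8:2 splits reproduce the ceiling-on-test convention", {
  expect_equal(split_train_test(240), c(train = 192L, test = 48L))
  expect_equal(split_train_test(192), c(train = 153L, test = 39L))
  expect_equal(sum(split_train_test(97)), 97L)
})

test_that("the segmenter recovers simulated masks at high IoU under default noise", {
  cfg <- sim_config(image_size = c(128, 128), n_frames = 3,
                    n_cells_initial = 4, min_separation = 26, seed = 13)
  sim <- simulate_sequence(cfg)
  ious <- vapply(1:3, function(i) {
    pred <- segment_reference(sim$frames[[i]], t = 0.1)
    evaluate_segmentation(pred, sim$masks[[i]])$iou
  }, numeric(1))
  expect_true(all(ious > 0.9))
})
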