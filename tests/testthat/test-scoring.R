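make_mask <- function(h, w, blocks) {
  m <- matrix(0L, h, w)
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    m[b$rows, b$cols] <- i
  }
  m
}

test_that("proxy prediction with radius 0 is the cell's own pixel set", {
  m <- make_mask(10, 10, list(list(rows = 2:4, cols = 2:4)))
  p <- proxy_predict(1, m, search_radius = 0)
  expect_setequal(p$pixels, which(m == 1L))
  p2 <- proxy_predict(1, m, search_radius = 2)
  expect_true(all(which(m == 1L) %in% p2$pixels))
  expect_gt(length(p2$pixels), length(p$pixels))
  expect_error(proxy_predict(9, m), "not present")
})

test_that("overlap scores count intersecting pixels and normalize to [0, 1]", {
  m1 <- make_mask(12, 12, list(list(rows = 2:4, cols = 2:4)))
  # prediction exactly equal to region 1 of the next frame
  p <- proxy_predict(1, m1, search_radius = 0)
  s <- overlap_score_matrix(list(p), m1)
  expect_equal(unname(s[1, 1]), 1)
  # disjoint from all regions -> zero row
  far <- make_mask(12, 12, list(list(rows = 9:11, cols = 9:11)))
  expect_true(all(overlap_score_matrix(list(p), far) == 0))
  # prediction of area 10 overlapping region 1 by 4 px, region 2 by 2 px
  pred <- list(source_label = 1L, pixels = which(make_mask(
    12, 12, list(list(rows = 3, cols = 1:10))) == 1L), dim = c(12L, 12L))
  targ <- make_mask(12, 12, list(list(rows = 2:3, cols = 2:5),
                                 list(rows = 3:4, cols = 8:9)))
  row <- overlap_score_matrix(list(pred), targ)
  expect_equal(unname(row[1, ]), c(0.4, 0.2))
  # brute-force oracle for the raw overlap on random masks
  set.seed(8)
  for (k in 1:5) {
    a <- matrix(sample(0:2, 100, replace = TRUE), 10, 10)
    b <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
    for (lab in intersect(1:2, unique(a[a > 0]))) {
      pr <- list(source_label = lab, pixels = which(a == lab), dim = dim(a))
      sm <- overlap_score_matrix(list(pr), b)
      for (j in colnames(sm)) {
        brute <- sum(a == lab & b == as.integer(j))
        expect_equal(unname(sm[1, j]) * length(pr$pixels), brute)
      }
      expect_true(all(sm >= 0 & sm <= 1))
    }
  }
})

test_that("normalization modes divide by pred, target, or union area", {
  pred <- list(source_label = 1L, pixels = 1:10, dim = c(10L, 10L))
  targ <- matrix(0L, 10, 10)
  targ[1:4] <- 1L   # overlap 4, target area 4, union 10
  expect_equal(unname(overlap_score_matrix(list(pred), targ, "pred")[1, 1]), 0.4)
  expect_equal(unname(overlap_score_matrix(list(pred), targ, "target")[1, 1]), 1)
  expect_equal(unname(overlap_score_matrix(list(pred), targ, "union")[1, 1]), 0.4)
})

test_that("a sequence of n frames yields n - 1 matrices, tolerating empty frames", {
  masks <- list(make_mask(16, 16, list(list(rows = 2:4, cols = 2:4))),
                make_mask(16, 16, list(list(rows = 3:5, cols = 3:5))))
  mats <- score_sequence(masks, search_radius = 3)
  expect_length(mats, 1)
  expect_gt(mats[[1]][1, 1], 0)
  empty <- matrix(0L, 16, 16)
  mats2 <- score_sequence(list(masks[[1]], empty, masks[[2]]), search_radius = 3)
  expect_length(mats2, 2)
  expect_equal(dim(mats2[[1]]), c(1L, 0L))
  expect_equal(dim(mats2[[2]]), c(0L, 1L))
  expect_error(score_sequence(list(empty)), "at least 2")
})

test_that("multi-blob external predictions keep the brightest component", {
  pm <- matrix(0, 10, 10)
  pm[2:3, 2:3] <- 1
  pm[7:8, 7:8] <- 1
  frame <- matrix(0.1, 10, 10)
  frame[7:8, 7:8] <- 0.9
  kept <- prune_prediction(pm, frame)
  expect_true(all(kept[7:8, 7:8]))
  expect_false(any(kept[2:3, 2:3]))
  one <- matrix(0, 10, 10)
  one[4:5, 4:5] <- 1
  expect_equal(prune_prediction(one, frame), one > 0)
})
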