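test_that("a static noise-free cell yields identical masks and one full track", {
  cfg <- sim_config(image_size = c(48, 48), n_frames = 3, n_cells_initial = 1,
                    cell_radius_range = c(4, 4), noise_sigma = 0,
                    speed_mean = 0, p_appear = 0, p_disappear = 0, seed = 3)
  out <- simulate_sequence(cfg)
  expect_length(out$frames, 3)
  expect_identical(out$masks[[1]], out$masks[[2]])
  expect_identical(out$masks[[2]], out$masks[[3]])
  expect_equal(dplyr::n_distinct(out$tracks$track_id), 1)
  expect_equal(nrow(out$tracks), 3)
})

test_that("identical seed and config give bit-identical output", {
  cfg <- sim_config(image_size = c(64, 64), n_frames = 6, n_cells_initial = 3,
                    seed = 11)
  a <- simulate_sequence(cfg)
  b <- simulate_sequence(cfg)
  expect_identical(a$frames, b$frames)
  expect_identical(a$masks, b$masks)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$events, b$events)
})

test_that("ground-truth centroids match labeled regions outside merges", {
  cfg <- sim_config(image_size = c(96, 96), n_frames = 8, n_cells_initial = 4,
                    min_separation = 24, noise_sigma = 0, p_appear = 0,
                    p_disappear = 0, seed = 5)
  out <- simulate_sequence(cfg)
  for (t in 0:7) {
    dets <- extract_detections(out$masks[[t + 1]], t)
    gt <- out$tracks[out$tracks$frame == t, ]
    joined <- dplyr::inner_join(gt, dets, by = c(frame = "frame", label = "label"))
    expect_equal(nrow(joined), nrow(gt))
    expect_true(all(sqrt((joined$x.x - joined$x.y)^2 +
                           (joined$y.x - joined$y.y)^2) <= 1))
  }
})

test_that("scripted merge reduces region count and split restores it", {
  ev <- list(sim_event("merge", 5, c(1, 2)), sim_event("split", 8, 2))
  cfg <- sim_config(image_size = c(96, 96), n_frames = 10, n_cells_initial = 2,
                    cell_radius_range = c(4, 4), noise_sigma = 0,
                    speed_mean = 1, p_appear = 0, p_disappear = 0,
                    scripted_events = ev, seed = 7)
  out <- simulate_sequence(cfg)
  n_regions <- vapply(out$masks, max, integer(1))
  expect_equal(n_regions[1:5], rep(2L, 5))     # frames 0-4
  expect_equal(n_regions[6:8], rep(1L, 3))     # merged frames 5-7
  expect_equal(n_regions[9:10], rep(2L, 2))    # split restores at frame 8
  # both tracks reference the shared detection during the merge interval
  merged <- out$tracks[out$tracks$frame %in% 5:7, ]
  expect_true(all(tapply(merged$label, merged$frame,
                         function(l) length(unique(l)) == 1)))
  expect_setequal(out$events$kind, c("merge", "split"))
})

test_that("infeasible packing is rejected", {
  expect_error(sim_config(image_size = c(32, 32), n_cells_initial = 40,
                          cell_radius_range = c(5, 5)),
               "cannot fit")
})

test_that("scripted scenarios have their defining shapes", {
  ap <- scripted_scenario("appear_midway")
  t2 <- ap$tracks[ap$tracks$track_id == 2, ]
  expect_equal(min(t2$frame), 3)
  di <- scripted_scenario("disappear_midway")
  expect_equal(max(di$tracks$frame[di$tracks$track_id == 2]), 4)
  dn <- scripted_scenario("dense_field")
  expect_equal(dplyr::n_distinct(dn$tracks$track_id), 6)
  expect_error(scripted_scenario("nope"))
})

test_that("the crossing scenario shares one detection during the merge", {
  fx <- scripted_scenario("two_cells_cross_merge_split")
  expect_length(fx$frames, 10)
  for (t in 4:6) expect_equal(max(fx$masks[[t + 1]]), 1L)
  for (t in c(0:3, 7:9)) expect_equal(max(fx$masks[[t + 1]]), 2L)
  expect_length(fx$score_matrices, 9)
  # ground truth: both tracks traverse the shared node then diverge
  g <- fx$tracks
  expect_equal(g$label[g$track_id == 1 & g$frame == 5],
               g$label[g$track_id == 2 & g$frame == 5])
  expect_false(g$label[g$track_id == 1 & g$frame == 8] ==
                 g$label[g$track_id == 2 & g$frame == 8])
})
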