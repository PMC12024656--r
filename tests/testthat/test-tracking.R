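test_that("spot detection recovers synthetic puncta with sub-pixel accuracy", {
  expect_equal(nrow(detect_spots(matrix(7, 64, 64), 0.1426)), 0)
  cm <- make_centriole_movie(n_frames = 1, cohesive_distance = 2.0,
                             snr = 10, width = 96, height = 96, seed = 3)
  sp <- detect_spots(get_frame(cm$movie, "centriole", 1), 0.1426)
  expect_equal(nrow(sp), 2)
  truth <- rbind(cm$truth$a[1, ], cm$truth$b[1, ])
  err <- apply(sp[, c("x", "y")], 1, function(p) {
    min(sqrt(colSums((t(truth) - p)^2)))
  })
  expect_lt(max(err), 0.25 * 0.1426)  # within a quarter pixel
  # two puncta at paper-like cohesive distance are still resolved
  cm2 <- make_centriole_movie(n_frames = 1, cohesive_distance = 0.7,
                              snr = 10, width = 96, height = 96, seed = 5)
  sp2 <- detect_spots(get_frame(cm2$movie, "centriole", 1), 0.1426)
  expect_equal(nrow(sp2), 2)
  expect_error(detect_spots(matrix(1, 8, 8), pixel_size = 1,
                            expected_diameter = 0.65), "under-resolved")
})

test_that("linking keeps identities, bridges short gaps, ends long ones", {
  two <- data.frame(x = c(1, 3), y = c(1, 1), quality = c(2, 1))
  frames <- rep(list(two), 10)
  tr <- link_pair(frames, max_distance = 5, gap_size = 3)
  expect_equal(tr$distance, rep(2, 10))
  expect_equal(tr$ax, rep(1, 10))

  # one spot missing for 3 frames: bridged; for 4 frames: track ends
  one <- two[1, , drop = FALSE]
  gap3 <- c(rep(list(two), 3), rep(list(one), 3), rep(list(two), 4))
  tr3 <- link_pair(gap3, max_distance = 5, gap_size = 3)
  expect_true(all(is.na(tr3$distance[4:6])))
  expect_equal(tr3$distance[7:10], rep(2, 4))
  gap4 <- c(rep(list(two), 3), rep(list(one), 4), rep(list(two), 3))
  tr4 <- link_pair(gap4, max_distance = 5, gap_size = 3)
  expect_true(all(is.na(tr4$distance[4:10])))

  crowd <- data.frame(x = 1:5, y = rep(1, 5), quality = 5:1)
  expect_error(link_pair(c(list(two), rep(list(crowd), 4))),
               "ambiguous")
})

test_that("tracking a scripted fracture movie reproduces ground truth", {
  cm <- make_centriole_movie(n_frames = 40, width = 128, height = 128,
                             frame_interval = 30, cohesive_distance = 0.8,
                             fracture = list(onset = 20, rate = 2,
                                             repair = 26),
                             snr = 5, seed = 11)
  tr <- track_centriole_pair(cm$movie)
  ok <- !is.na(tr$distance)
  expect_gt(sum(ok), 35)
  rms <- sqrt(mean((tr$distance[ok] - cm$truth$distance[ok])^2))
  expect_lt(rms, 0.1)
  # noiseless: tighter than 0.05 um RMS
  cm0 <- make_centriole_movie(n_frames = 20, cohesive_distance = 0.8,
                              snr = Inf, seed = 3)
  tr0 <- track_centriole_pair(cm0$movie)
  rms0 <- sqrt(mean((tr0$distance - cm0$truth$distance)^2, na.rm = TRUE))
  expect_lt(rms0, 0.05)
})

test_that("distance series uses frame times, omits gaps, never interpolates", {
  tr <- structure(data.frame(frame = 1:4,
                             ax = c(0, 0, NA, 0), ay = c(0, 0, NA, 0),
                             bx = c(0.8, 0.8, NA, 0.8), by = 0,
                             distance = c(0.8, 0.8, NA, 0.8)),
                  class = c("centriole_pair_track", "data.frame"))
  ser <- distance_series(tr, frame_interval = 6)
  expect_equal(ser$time, c(0, 6, 18))
  expect_equal(ser$distance, rep(0.8, 3))
  empty <- tr; empty$distance[] <- NA; empty$ax[] <- NA
  expect_equal(nrow(distance_series(empty, 6)), 0)
})

test_that("distance series is invariant under translation and rotation", {
  cm <- make_centriole_movie(n_frames = 8, cohesive_distance = 1.2,
                             snr = Inf, seed = 4)
  spots <- lapply(seq_len(8), function(ti) {
    detect_spots(get_frame(cm$movie, "centriole", ti), 0.1426)
  })
  base <- link_pair(spots)$distance
  moved <- lapply(spots, transform_spots, angle = 0.7, shift = c(5, -3),
                  pivot = c(4, 4))
  expect_equal(link_pair(moved)$distance, base, tolerance = 1e-9)
  # relabeling A/B (swapping spot order) never changes any distance
  swapped <- lapply(spots, function(s) s[rev(seq_len(nrow(s))), ])
  expect_equal(link_pair(swapped)$distance, base, tolerance = 1e-12)
})

test_that("migration statistics match their definitions", {
  straight <- data.frame(x = seq(0, 25, by = 5), y = 0)
  st <- track_migration_stats(straight, frame_interval = 60)
  expect_equal(st$speed, 5)
  expect_equal(st$directionality, 1)
  back_forth <- data.frame(x = c(0, 5, 0, 5, 0), y = 0)
  expect_equal(track_migration_stats(back_forth, 60)$directionality, 0)
  expect_error(track_migration_stats(straight[1, , drop = FALSE], 60),
               "two track points")
})

test_that("comet statistics attribute tracks to anchors by origin", {
  anchors <- cbind(x = c(0, 20), y = c(0, 0))
  mk_track <- function(id, x0, y0, step, n) {
    data.frame(track = id, frame = seq_len(n),
               x = x0 + step * (seq_len(n) - 1), y = y0)
  }
  tracks <- rbind(mk_track(1, 0.2, 0, 1, 5),
                  mk_track(2, 20.3, 0, 1, 5),
                  mk_track(3, 10, 5, 1, 5))   # origin far from both anchors
  cs <- comet_stats(tracks, anchors, origin_radius = 1, frame_interval = 5)
  expect_equal(cs$attributed, c(1L, 1L))
  expect_equal(cs$origin_counts, 2)
  expect_equal(cs$mean_speed, 0.2)  # 1 um per 5-s frame
  none <- comet_stats(mk_track(1, 50, 50, 1, 5), anchors, 1, 5)
  expect_equal(none$rate_per_cell, 0)
})
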