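test_that("generators are pure functions of parameters and seed", {
  a <- make_centriole_movie(n_frames = 5, snr = 8, seed = 11)
  b <- make_centriole_movie(n_frames = 5, snr = 8, seed = 11)
  expect_identical(a$movie$channels$centriole, b$movie$channels$centriole)
  c <- make_centriole_movie(n_frames = 5, snr = 8, seed = 12)
  expect_false(identical(a$movie$channels$centriole,
                         c$movie$channels$centriole))
  # generators do not disturb the global RNG stream
  set.seed(99); before <- stats::runif(1)
  set.seed(99); invisible(make_centriole_movie(n_frames = 2, seed = 5))
  expect_identical(stats::runif(1), before)
})

test_that("scripted fracture kinetics follow the piecewise-linear script", {
  cm <- make_centriole_movie(n_frames = 30, cohesive_distance = 0.8,
                             frame_interval = 6,
                             fracture = list(onset = 20, rate = 2),
                             snr = Inf, seed = 1)
  # 5 frames after onset at 6 s = 0.5 min; 0.5 * 2 um/min = 1 um
  expect_equal(cm$truth$distance[25], 0.8 + 1.0, tolerance = 1e-12)
  expect_equal(cm$truth$distance[1:20], rep(0.8, 20), tolerance = 1e-12)

  rep_cm <- make_centriole_movie(n_frames = 40, cohesive_distance = 0.8,
                                 frame_interval = 6,
                                 fracture = list(onset = 10, rate = 2,
                                                 repair = 20),
                                 snr = Inf, width = 96, height = 96, seed = 1)
  d <- rep_cm$truth$distance
  expect_equal(max(d), d[20], tolerance = 1e-12)   # peak at repair frame
  expect_equal(d[40], 0.8, tolerance = 1e-12)      # fully re-cohered
  expect_true(all(diff(d[20:30]) < 0))

  expect_error(make_centriole_movie(fracture = list(onset = 5, rate = -1)),
               "rate")
  expect_error(make_centriole_movie(n_frames = 200, frame_interval = 60,
                                    fracture = list(onset = 5, rate = 5),
                                    seed = 1),
               "field of view")
  expect_error(make_centriole_movie(snr = 0), "snr")
})

test_that("polarity movie encodes the stated gradient with exact oracle", {
  pm <- make_polarity_movie(gradient_ratio = 1, n_bins = 2, seed = 2)
  expect_equal(pm$truth$bin_ratios, c(1, 1), tolerance = 1e-9)
  pm2 <- make_polarity_movie(gradient_ratio = 2, n_bins = 2,
                             exclusion_radius = 0, centriole_s = numeric(0),
                             seed = 2)
  # closed form for a linear ramp over each half, uniform reference:
  # back = (3 + r) / (2 (1 + r)), front = (1 + 3 r) / (2 (1 + r))
  r <- 2
  expect_equal(pm2$truth$bin_ratios,
               c((3 + r) / (2 * (1 + r)), (1 + 3 * r) / (2 * (1 + r))),
               tolerance = 1e-6)
  # noiseless ramp is exactly linear along the axis inside the mask
  fr <- get_frame(pm2$movie, "polarity", 1)
  col <- fr[, 25][pm2$masks[1, , 25]]
  expect_equal(diff(col), rep(diff(col)[1], length(col) - 1),
               tolerance = 1e-9)
  expect_error(make_polarity_movie(gradient_ratio = 0), "positive")
})

test_that("FRAP generator honours limits and the default pre-bleach count", {
  fr0 <- make_frap_series(mobile_fraction = 0, n_post = 50, seed = 1)
  post <- fr0$bleached[6:55]
  expect_equal(post, rep(post[1], 50), tolerance = 1e-12)
  fr1 <- make_frap_series(mobile_fraction = 1, n_post = 5000, seed = 1)
  expect_equal(fr1$bleached[length(fr1$bleached)], fr1$bleached[1],
               tolerance = 1e-3)
  expect_equal(fr1$truth$bleach_frame, 6L)  # five pre-bleach frames
  expect_error(make_frap_series(mobile_fraction = 1.2), "mobile_fraction")
})

test_that("drift generator records its scripted shifts exactly", {
  z <- make_drift_sequence(n_frames = 4, shifts = c(0, 0), seed = 1)
  expect_equal(z$movie$channels$cells[1, , ], z$movie$channels$cells[3, , ],
               tolerance = 1e-12)
  s <- make_drift_sequence(n_frames = 5, shifts = c(0.5, 0.25), seed = 1)
  expect_equal(s$truth$shifts_px,
               matrix(c(0.5, 0.25), 4, 2, byrow = TRUE))
  expect_equal(nrow(s$truth$shifts_px), 5 - 1)
  expect_error(make_drift_sequence(shifts = c(0, 40), search_radius = 25),
               "search radius")
})

test_that("vessel generator ground truth uses exact pixel geometry", {
  mask <- matrix(FALSE, 16, 16); mask[1, 1] <- TRUE
  vi <- make_vessel_image(width = 16, height = 16, pixel_size = 1,
                          cells = cbind(x = c(3, 0), y = c(4, 0)),
                          n_vessels = 1, vessel_halfwidth = 0.1, seed = 7)
  # rebuild with a known mask: use the API directly on scripted positions
  res <- cell_vessel_stats(cbind(x = c(3, 0), y = c(4, 0)), mask, 1)
  expect_equal(res$distance, c(5, 0))  # 3-4-5 triangle; on-vessel cell
  expect_identical(res$inside, c(FALSE, TRUE))
  expect_error(make_vessel_image(n_vessels = 0), "at least one")
})
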