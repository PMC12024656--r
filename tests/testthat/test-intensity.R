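test_that("line profiles sample by bilinear interpolation at uniform steps", {
  img <- matrix(100, 60, 60)
  lp <- line_profile(img, c(0.5, 0.5), c(5.5, 0.5), 0.1426, step = 0.1)
  expect_equal(nrow(lp), 51)  # 5 um at 0.1 um steps
  expect_equal(lp$raw, rep(100, 51), tolerance = 1e-12)
  # a gradient image interpolates linearly along the line
  gimg <- matrix(rep(seq_len(60), each = 60), 60, 60)  # ramp along x
  gl <- line_profile(gimg, c(1, 2), c(4, 2), pixel_size = 1, step = 0.25)
  expect_equal(gl$raw, seq(2, 5, by = 0.25), tolerance = 1e-12)
  expect_error(line_profile(img, c(0, 0), c(50, 0), 0.1426), "bounds")
})

test_that("peak of a punctum-centered profile lies mid-line", {
  cm <- make_centriole_movie(n_frames = 1, cohesive_distance = 0,
                             snr = Inf, seed = 2)
  img <- get_frame(cm$movie, "centriole", 1)
  ctr <- cm$truth$a[1, ]
  lp <- line_profile(img, ctr - c(2.5, 0), ctr + c(2.5, 0), 0.1426,
                     step = 0.1)
  expect_equal(lp$position[which.max(lp$raw)], 2.5, tolerance = 0.1)
})

test_that("profile normalization pools the first and last four samples", {
  prof <- structure(
    data.frame(position = seq(0, 5, by = 0.5),
               raw = c(50, 50, 50, 50, 120, 200, 120, 50, 50, 50, 50)),
    class = c("line_profile", "data.frame"))
  np <- normalize_profile(prof, tail_count = 4)
  expect_equal(np$normalized[6], 4)  # peak 200 over pooled tail mean 50
  expect_equal(np$normalized[1], 1)
  const <- prof; const$raw <- rep(80, 11)
  expect_equal(normalize_profile(const)$normalized, rep(1, 11))
  short <- prof[1:7, ]
  expect_error(normalize_profile(short, tail_count = 4), "samples")
  # invariance under affine gain: scaling raw data cancels out
  scaled <- prof; scaled$raw <- prof$raw * 7.5
  expect_equal(normalize_profile(scaled)$normalized,
               np$normalized, tolerance = 1e-12)
})

test_that("centrosome intensity ratio takes the higher mean as divisor", {
  img <- matrix(0, 60, 60)
  img[20:40, 10:20] <- 100
  img[20:40, 40:50] <- 200
  px <- 0.1426
  p1 <- c(15, 30) * px; p2 <- c(45, 30) * px
  r <- centrosome_intensity_ratio(img, p1, p2, px, 0.35)
  expect_equal(r$ratio, 0.5)
  r_swap <- centrosome_intensity_ratio(img, p2, p1, px, 0.35)
  expect_equal(r_swap$ratio, r$ratio)  # symmetric in the two positions
  flat <- matrix(100, 60, 60)
  same <- centrosome_intensity_ratio(flat, p1, p2, px, 0.35)
  expect_equal(same$ratio, 1)
  expect_lte(r$ratio, 1)
  expect_warning(centrosome_intensity_ratio(img, p1, p1 + c(0.3, 0), px,
                                            0.35),
                 "overlap")
  expect_error(
    suppressWarnings(
      centrosome_intensity_ratio(img, c(30, 10) * px, c(52, 8) * px, px,
                                 0.35)),
    "<= 0")
})

test_that("discretized ROI area converges to pi r^2 as pixels shrink", {
  r <- 0.35
  for (px in c(0.05, 0.01, 0.002)) {
    n <- ceiling(2 * r / px) + 4
    m <- roi_mask(n, n, c((n - 1) / 2 * px, (n - 1) / 2 * px), r, px)
    area <- sum(m) * px^2
    expect_equal(area, pi * r^2, tolerance = 4 * px / r)
  }
})

test_that("FRAP normalization matches its defining arithmetic", {
  cur <- frap_normalize(bleached = c(110, 110, 110, 60, 85),
                        reference = rep(110, 5),
                        background = 10, pre_frames = 3, frame_interval = 1)
  expect_equal(mean(cur$value[cur$time < 0]), 1, tolerance = 1e-12)
  expect_equal(cur$value[4], 0.5)
  expect_equal(cur$time[4], 0)  # first post-bleach frame
  expect_error(frap_normalize(1:5, rep(5, 5), background = 10), "<= 0")
  # gain invariance: scaling both channels cancels; offset handled by background
  g <- frap_normalize(bleached = 3 * c(110, 110, 110, 60, 85) - 2 * 10,
                      reference = 3 * rep(110, 5) - 2 * 10,
                      background = 10, pre_frames = 3)
  expect_equal(g$value, cur$value, tolerance = 1e-12)
})

test_that("exponential fit recovers scripted FRAP parameters", {
  fr <- make_frap_series(mobile_fraction = 0.66, halftime = 20,
                         noise_sd = 0, seed = 1)
  cur <- frap_normalize(fr$bleached, fr$reference, fr$truth$background,
                        pre_frames = 5, frame_interval = 1)
  fit <- frap_halftime(cur)
  expect_equal(fit$halftime, 20, tolerance = 0.5 / 20)
  expect_equal(fit$mobile_fraction, 0.66, tolerance = 0.01)
  # plateau of the normalized curve approaches depth + mf (1 - depth)
  plateau <- utils::tail(cur$value, 1)
  expect_equal(plateau, 0.3 + 0.66 * 0.7, tolerance = 0.01)

  flat <- make_frap_series(mobile_fraction = 0, seed = 1)
  fit0 <- frap_halftime(frap_normalize(flat$bleached, flat$reference,
                                       10, 5, 1))
  expect_equal(fit0$mobile_fraction, 0)

  dec <- frap_normalize(bleached = c(rep(110, 5), seq(60, 30, by = -2)),
                        reference = rep(110, 21), background = 10,
                        pre_frames = 5)
  expect_error(frap_halftime(dec), "decreases")
})

test_that("ROI mean series tracks the scripted recovery through the movie", {
  fr <- make_frap_series(mobile_fraction = 0.5, n_post = 20, seed = 2)
  series <- roi_series(fr$movie, "frap", fr$rois$bleach$center,
                       fr$rois$bleach$radius)
  expect_equal(series, fr$bleached, tolerance = 1e-9)
})
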