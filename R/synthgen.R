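#' @title Synthetic movie generators with known ground truth
#' @description Every generator is a pure function of its parameters and a
#'   seed: the global RNG state is saved and restored, and identical calls
#'   produce identical pixel data. The ground truth returned alongside each
#'   movie is sufficient to score the corresponding analysis stage without
#'   looking at the pixels.
#' @name synthgen
NULL

# Evaluate expr under a private RNG stream seeded with `seed`.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Render isotropic 2D Gaussian puncta onto a h x w frame.
# positions: matrix with columns x, y in micrometers; peak: counts at center.
render_gaussians <- function(h, w, pixel_size, positions, sigma, peak) {
  img <- matrix(0, h, w)
  if (is.null(positions) || nrow(positions) == 0L) return(img)
  xs <- (seq_len(w) - 1) * pixel_size
  ys <- (seq_len(h) - 1) * pixel_size
  for (i in seq_len(nrow(positions))) {
    gx <- exp(-(xs - positions[i, 1])^2 / (2 * sigma^2))
    gy <- exp(-(ys - positions[i, 2])^2 / (2 * sigma^2))
    img <- img + peak * outer(gy, gx)
  }
  img
}

# Poisson shot noise plus Gaussian read noise; SNR = peak / read-noise sigma.
# snr = Inf means fully noiseless. Result is nonnegative integer counts.
add_noise <- function(signal, background, peak, snr) {
  clean <- signal + background
  if (!is.finite(snr)) return(round(clean))
  if (snr <= 0) stop("'snr' must be positive")
  shot <- matrix(stats::rpois(length(clean), lambda = as.vector(clean)),
                 nrow(clean), ncol(clean))
  read <- matrix(stats::rnorm(length(clean), sd = peak / snr),
                 nrow(clean), ncol(clean))
  pmax(round(shot + read), 0)
}

#' Synthetic centriole-pair movie with scripted fracture kinetics
#'
#' Renders two Gaussian puncta per frame whose separation is constant at
#' `cohesive_distance` before fracture onset, grows linearly at the scripted
#' rate (micrometers per minute) after onset, and shrinks back at the same
#' rate after an optional repair frame — a piecewise-linear distance script
#' matching the locally linear separations seen in fracture events. Frame-rate
#' calibration, a diffraction-scale Gaussian point-spread function and a
#' Poisson + Gaussian noise model make the movies realistic inputs for the
#' detector and linker.
#'
#' @param n_frames number of frames.
#' @param width,height frame size in pixels.
#' @param pixel_size micrometers per pixel (default the confocal calibration
#'   0.1426 um used throughout).
#' @param frame_interval seconds per frame.
#' @param cohesive_distance micrometers; inter-centriole distance of the
#'   cohesive pair (typical range 0.5-1 um).
#' @param fracture `NULL` for a cohesive cell, otherwise a list with `onset`
#'   (1-based frame), `rate` (um/min, > 0) and optional `repair` frame.
#' @param psf_sigma micrometers; Gaussian PSF sigma (default 0.2 um,
#'   diffraction scale at this pixel size).
#' @param snr peak signal over read-noise sigma; `Inf` for a noiseless movie.
#' @param peak,background punctum peak and background, in counts.
#' @param jitter micrometers; isotropic Gaussian jitter applied to each
#'   punctum position per frame (0 = scripted positions exactly).
#' @param midpoint micrometers `c(x, y)`; pair midpoint (default: field
#'   center).
#' @param orientation radians; pair axis angle, drawn from the seed if `NULL`.
#' @param seed RNG seed.
#' @return a list with `movie` (a [calibrated_movie()] with channel
#'   `"centriole"`) and `truth` (per-frame true positions `a`, `b`, the true
#'   distance series, and the fracture script).
#' @export
make_centriole_movie <- function(n_frames = 40, width = 64, height = 64,
                                 pixel_size = 0.1426, frame_interval = 6,
                                 cohesive_distance = 0.8, fracture = NULL,
                                 psf_sigma = 0.2, snr = 10,
                                 peak = 1000, background = 100,
                                 jitter = 0, midpoint = NULL,
                                 orientation = NULL, seed = 1) {
  if (cohesive_distance < 0) stop("'cohesive_distance' must be >= 0")
  if (!is.null(fracture)) {
    if (is.null(fracture$onset) || is.null(fracture$rate) ||
        fracture$rate <= 0) {
      stop("'fracture' needs an onset frame and a positive rate (um/min)")
    }
  }
  with_seed(seed, {
    if (is.null(midpoint)) {
      midpoint <- c((width - 1) / 2, (height - 1) / 2) * pixel_size
    }
    if (is.null(orientation)) orientation <- stats::runif(1, 0, pi)
    dt_min <- frame_interval / 60
    f <- seq_len(n_frames)
    d <- rep(cohesive_distance, n_frames)
    if (!is.null(fracture)) {
      on <- fracture$onset
      d <- cohesive_distance + fracture$rate * pmax(0, f - on) * dt_min
      if (!is.null(fracture$repair)) {
        rp <- fracture$repair
        d_rp <- cohesive_distance + fracture$rate * max(0, rp - on) * dt_min
        past <- f > rp
        d[past] <- pmax(cohesive_distance,
                        d_rp - fracture$rate * (f[past] - rp) * dt_min)
      }
    }
    u <- c(cos(orientation), sin(orientation))
    a <- cbind(midpoint[1] + u[1] * d / 2, midpoint[2] + u[2] * d / 2)
    b <- cbind(midpoint[1] - u[1] * d / 2, midpoint[2] - u[2] * d / 2)
    if (jitter > 0) {
      a <- a + matrix(stats::rnorm(2 * n_frames, sd = jitter), ncol = 2)
      b <- b + matrix(stats::rnorm(2 * n_frames, sd = jitter), ncol = 2)
    }
    lim_x <- (width - 1) * pixel_size
    lim_y <- (height - 1) * pixel_size
    all_pos <- rbind(a, b)
    if (any(all_pos[, 1] < 0 | all_pos[, 1] > lim_x |
            all_pos[, 2] < 0 | all_pos[, 2] > lim_y)) {
      stop("puncta leave the field of view; enlarge the frame or shorten the script")
    }
    arr <- array(0, dim = c(n_frames, height, width))
    for (ti in f) {
      sig <- render_gaussians(height, width, pixel_size,
                              rbind(a[ti, ], b[ti, ]), psf_sigma, peak)
      arr[ti, , ] <- add_noise(sig, background, peak, snr)
    }
    truth <- structure(list(
      a = a, b = b,
      distance = sqrt(rowSums((a - b)^2)),
      scripted_distance = d,
      fracture = fracture,
      cohesive_distance = cohesive_distance,
      seed = seed
    ), class = "ground_truth")
    list(
      movie = calibrated_movie(list(centriole = arr), pixel_size,
                               frame_interval),
      truth = truth
    )
  })
}

# Exact per-bin reporter/reference ratios for a linear back-to-front ramp on a
# rectangular cell of length L and width W with a disk of radius R excluded
# around each centriole (positions in normalized coordinate s along the axis).
# Uniform reference; per-channel normalization over included pixels. Evaluated
# by 1D quadrature of the included-width profile — independent of any pixel
# grid.
polarity_bin_oracle <- function(ratio, n_bins, length_um, width_um,
                                exclusion_radius = 0, centriole_s = numeric(0)) {
  ramp <- function(s) 1 + (ratio - 1) * s
  incl_w <- function(s) {
    w <- rep(width_um, length(s))
    for (sc in centriole_s) {
      dy <- abs(s - sc) * length_um
      cut <- dy < exclusion_radius
      w[cut] <- pmax(0, w[cut] - 2 * sqrt(exclusion_radius^2 - dy[cut]^2))
    }
    w
  }
  qgrid <- seq(0, 1, length.out = 20001)
  wq <- incl_w(qgrid)
  iq <- ramp(qgrid)
  total_mean <- sum(iq * wq) / sum(wq)
  edges <- seq(0, 1, length.out = n_bins + 1)
  vapply(seq_len(n_bins), function(i) {
    sel <- qgrid >= edges[i] & qgrid <= edges[i + 1]
    (sum(iq[sel] * wq[sel]) / sum(wq[sel])) / total_mean
  }, 0)
}

#' Synthetic polarity-gradient movie
#'
#' A rectangular cell translating along the migration axis (+y) carries a
#' polarity-reporter channel whose intensity ramps linearly from the cell rear
#' to the front, achieving the requested front/back ratio, and a reference
#' channel that is uniform inside the cell. The ground truth records exact
#' per-bin reporter/reference ratios (continuous-geometry quadrature,
#' accounting for the centriole exclusion disks) for scoring the profiler.
#'
#' @param n_frames frames (default 8, within the 6-20 usable time points per
#'   cell typical of 5-min-interval polarity recordings).
#' @param gradient_ratio front-to-back reporter intensity ratio (> 0).
#' @param cell_length,cell_width cell size in micrometers.
#' @param step_um cell displacement per frame along +y, micrometers.
#' @param pixel_size micrometers per pixel.
#' @param frame_interval seconds (default 300 = 5 min).
#' @param centriole_s centriole positions along the normalized cell axis
#'   (0 = rear, 1 = front); both centrioles at the cell center by default.
#' @param exclusion_radius micrometers, used only to precompute oracle bin
#'   ratios.
#' @param n_bins bin count for the precomputed oracle ratios.
#' @param base reporter intensity at the cell rear, counts.
#' @param noise_sd additive Gaussian noise sigma (0 = noiseless).
#' @param seed RNG seed.
#' @return list with `movie` (channels `"polarity"` and `"reference"`),
#'   `masks` (logical `time x height x width` array), `centrioles` (list of
#'   per-frame position matrices, micrometers) and `truth` (per-bin oracle
#'   ratios and the generating parameters).
#' @export
make_polarity_movie <- function(n_frames = 8, gradient_ratio = 2,
                                cell_length = 30, cell_width = 12,
                                step_um = 1, pixel_size = 0.2,
                                frame_interval = 300,
                                centriole_s = c(0.5, 0.5),
                                exclusion_radius = 1.5,
                                n_bins = 2, base = 500,
                                noise_sd = 0, seed = 1) {
  if (gradient_ratio <= 0) stop("'gradient_ratio' must be positive")
  with_seed(seed, {
    margin <- 4
    w_px <- ceiling(cell_width / pixel_size) + 2 * margin
    h_px <- ceiling((cell_length + step_um * n_frames) / pixel_size) +
      2 * margin
    len_px <- round(cell_length / pixel_size)
    wid_px <- round(cell_width / pixel_size)
    pol <- array(0, dim = c(n_frames, h_px, w_px))
    ref <- array(0, dim = c(n_frames, h_px, w_px))
    masks <- array(FALSE, dim = c(n_frames, h_px, w_px))
    centrioles <- vector("list", n_frames)
    x0 <- margin + 1
    for (ti in seq_len(n_frames)) {
      y0 <- margin + 1 + round((ti - 1) * step_um / pixel_size)
      rows <- y0:(y0 + len_px - 1)
      cols <- x0:(x0 + wid_px - 1)
      if (max(rows) > h_px) stop("cell trajectory leaves the frame")
      s <- (rows - min(rows)) / (max(rows) - min(rows))
      ramp <- base * (1 + (gradient_ratio - 1) * s)
      pol[ti, rows, cols] <- matrix(ramp, length(rows), length(cols))
      ref[ti, rows, cols] <- base
      masks[ti, rows, cols] <- TRUE
      cy <- (min(rows) - 1 + centriole_s * (len_px - 1)) * pixel_size
      cx <- rep((mean(range(cols)) - 1) * pixel_size, length(centriole_s))
      centrioles[[ti]] <- cbind(x = cx, y = cy)
      if (noise_sd > 0) {
        pol[ti, , ] <- pmax(pol[ti, , ] +
          matrix(stats::rnorm(h_px * w_px, sd = noise_sd), h_px, w_px), 0)
        ref[ti, , ] <- pmax(ref[ti, , ] +
          matrix(stats::rnorm(h_px * w_px, sd = noise_sd), h_px, w_px), 0)
      }
    }
    truth <- structure(list(
      gradient_ratio = gradient_ratio,
      bin_ratios = polarity_bin_oracle(gradient_ratio, n_bins, cell_length,
                                       cell_width, exclusion_radius,
                                       centriole_s),
      n_bins = n_bins,
      exclusion_radius = exclusion_radius,
      seed = seed
    ), class = "ground_truth")
    list(
      movie = calibrated_movie(list(polarity = pol, reference = ref),
                               pixel_size, frame_interval),
      masks = masks,
      centrioles = centrioles,
      truth = truth
    )
  })
}

#' Synthetic FRAP sequence
#'
#' The bleached-ROI mean follows a single-exponential recovery
#' `depth + mf * (1 - depth) * (1 - 2^(-t / halftime))` in pre-bleach-
#' normalized units, on top of a constant background; the reference ROI is
#' constant. Five pre-bleach frames at a 1-s frame rate by default.
#'
#' @param pre_frames pre-bleach frames (default 5).
#' @param n_post post-bleach frames.
#' @param frame_interval seconds between frames (default 1).
#' @param background detector background level, counts.
#' @param reference_level reference-ROI raw level, counts.
#' @param prebleach_level bleached-ROI raw pre-bleach level, counts.
#' @param bleach_depth normalized signal immediately after bleaching, in
#'   (0, 1).
#' @param mobile_fraction fraction of signal that recovers, in [0, 1].
#' @param halftime recovery half-time, seconds.
#' @param noise_sd per-pixel Gaussian noise sigma (0 = noiseless).
#' @param seed RNG seed.
#' @return list with `movie` (channel `"frap"`, 32 x 64 px), `rois`
#'   (bleach/reference centers and radius, micrometers), the raw `bleached`
#'   and `reference` ROI mean series, and `truth`.
#' @export
make_frap_series <- function(pre_frames = 5, n_post = 120, frame_interval = 1,
                             background = 10, reference_level = 110,
                             prebleach_level = 110, bleach_depth = 0.3,
                             mobile_fraction = 0.66, halftime = 20,
                             noise_sd = 0, seed = 1) {
  if (mobile_fraction < 0 || mobile_fraction > 1) {
    stop("'mobile_fraction' must lie in [0, 1]")
  }
  if (bleach_depth <= 0 || bleach_depth >= 1) {
    stop("'bleach_depth' must lie in (0, 1)")
  }
  with_seed(seed, {
    n <- pre_frames + n_post
    t_post <- (seq_len(n_post) - 1) * frame_interval
    norm <- c(rep(1, pre_frames),
              bleach_depth + mobile_fraction * (1 - bleach_depth) *
                (1 - 2^(-t_post / halftime)))
    bleached <- background + (prebleach_level - background) * norm
    reference <- rep(reference_level, n)
    px <- 0.1426
    h <- 32; w <- 64
    arr <- array(background, dim = c(n, h, w))
    bl_cols <- 9:24; rf_cols <- 41:56; rows <- 9:24
    for (ti in seq_len(n)) {
      arr[ti, rows, bl_cols] <- bleached[ti]
      arr[ti, rows, rf_cols] <- reference[ti]
      if (noise_sd > 0) {
        arr[ti, , ] <- pmax(arr[ti, , ] +
          matrix(stats::rnorm(h * w, sd = noise_sd), h, w), 0)
      }
    }
    rois <- list(
      bleach = list(center = c(mean(bl_cols) - 1, mean(rows) - 1) * px,
                    radius = 6 * px),
      reference = list(center = c(mean(rf_cols) - 1, mean(rows) - 1) * px,
                       radius = 6 * px)
    )
    truth <- structure(list(
      mobile_fraction = mobile_fraction, halftime = halftime,
      background = background, bleach_depth = bleach_depth,
      bleach_frame = pre_frames + 1L, seed = seed
    ), class = "ground_truth")
    list(
      movie = calibrated_movie(list(frap = arr), px, frame_interval),
      rois = rois,
      bleached = bleached, reference = reference,
      truth = truth
    )
  })
}

# Periodic bilinear translation of a matrix by (dx, dy) pixels
# (x = columns, y = rows); positive dx moves content toward larger x.
shift_periodic <- function(mat, dx, dy) {
  h <- nrow(mat); w <- ncol(mat)
  r0 <- (seq_len(h) - 1) - dy
  c0 <- (seq_len(w) - 1) - dx
  rf <- floor(r0); cf <- floor(c0)
  wr <- r0 - rf; wc <- c0 - cf
  idx <- function(i, n) (i %% n) + 1L
  m00 <- mat[idx(rf, h), idx(cf, w), drop = FALSE]
  m01 <- mat[idx(rf, h), idx(cf + 1, w), drop = FALSE]
  m10 <- mat[idx(rf + 1, h), idx(cf, w), drop = FALSE]
  m11 <- mat[idx(rf + 1, h), idx(cf + 1, w), drop = FALSE]
  (1 - wr) %o% (1 - wc) * m00 + (1 - wr) %o% wc * m01 +
    wr %o% (1 - wc) * m10 + wr %o% wc * m11
}

#' Synthetic drifting-texture sequence
#'
#' Frame `t` is frame `t - 1` translated by the scripted shift (periodic
#' boundary, bilinear interpolation for subpixel shifts) plus optional noise;
#' the shifts are recorded exactly in the ground truth. Used to validate the
#' overlap-optimizing displacement estimator.
#'
#' @param n_frames frames.
#' @param shifts `(n_frames - 1) x 2` matrix of per-frame-pair `(dx, dy)` in
#'   pixels; recycled from a length-2 vector.
#' @param width,height frame size, pixels.
#' @param texture_density blobs per pixel of the random texture.
#' @param pixel_size micrometers per pixel.
#' @param frame_interval seconds per frame.
#' @param noise_sd additive Gaussian noise sigma (0 = noiseless).
#' @param search_radius pixels; shifts beyond this declared search radius are
#'   rejected.
#' @param seed RNG seed.
#' @return list with `movie` (channel `"cells"`) and `truth` (the scripted
#'   per-pair shift matrix, px and um).
#' @export
make_drift_sequence <- function(n_frames = 6, shifts = c(0, 3),
                                width = 64, height = 64,
                                texture_density = 0.01,
                                pixel_size = 1, frame_interval = 30,
                                noise_sd = 0, search_radius = 25, seed = 1) {
  if (is.null(dim(shifts))) {
    shifts <- matrix(shifts, nrow = n_frames - 1, ncol = 2, byrow = TRUE)
  }
  if (nrow(shifts) != n_frames - 1) {
    stop("'shifts' must have n_frames - 1 rows")
  }
  if (any(abs(shifts) > search_radius)) {
    stop("scripted shift exceeds the declared search radius")
  }
  with_seed(seed, {
    n_blobs <- max(3, round(texture_density * width * height))
    pos <- cbind(stats::runif(n_blobs, 0, (width - 1) * pixel_size),
                 stats::runif(n_blobs, 0, (height - 1) * pixel_size))
    peaks <- stats::runif(n_blobs, 200, 1000)
    base <- matrix(0, height, width)
    for (i in seq_len(n_blobs)) {
      base <- base + render_gaussians(height, width, pixel_size,
                                      pos[i, , drop = FALSE],
                                      sigma = 2 * pixel_size, peaks[i])
    }
    arr <- array(0, dim = c(n_frames, height, width))
    cur <- base
    arr[1, , ] <- cur
    for (ti in 2:n_frames) {
      cur <- shift_periodic(cur, shifts[ti - 1, 1], shifts[ti - 1, 2])
      arr[ti, , ] <- cur
    }
    if (noise_sd > 0) {
      arr <- arr + array(stats::rnorm(length(arr), sd = noise_sd), dim(arr))
    }
    arr <- pmax(arr, 0)
    truth <- structure(list(
      shifts_px = shifts,
      shifts_um = shifts * pixel_size,
      seed = seed
    ), class = "ground_truth")
    list(
      movie = calibrated_movie(list(cells = arr), pixel_size, frame_interval),
      truth = truth
    )
  })
}

#' Synthetic vessel mask and cell positions
#'
#' Rasterizes thick random line segments into a binary vessel mask, scatters
#' cells (some scripted onto the vessel), and records each cell's true
#' Euclidean distance to the nearest vessel pixel — computed by brute-force
#' search over all vessel pixels, independently of the distance-transform
#' implementation under test.
#'
#' @param width,height mask size, pixels.
#' @param pixel_size micrometers per pixel.
#' @param n_vessels number of vessel segments (>= 1).
#' @param vessel_halfwidth vessel half-thickness, pixels.
#' @param n_cells number of cells scattered uniformly.
#' @param cells optional explicit cell positions (micrometers, columns x, y);
#'   overrides `n_cells`.
#' @param seed RNG seed.
#' @return list with `mask` (logical matrix), `cell_channel` (rendered cell
#'   image), `cells` (positions, micrometers) and `truth` (per-cell true
#'   nearest-vessel distance in micrometers and inside/outside label).
#' @export
make_vessel_image <- function(width = 96, height = 96, pixel_size = 1,
                              n_vessels = 2, vessel_halfwidth = 2,
                              n_cells = 20, cells = NULL, seed = 1) {
  if (n_vessels < 1) stop("need at least one vessel segment")
  with_seed(seed, {
    mask <- matrix(FALSE, height, width)
    cc <- matrix(rep(seq_len(width) - 1, each = height), height, width)
    rr <- matrix(rep(seq_len(height) - 1, times = width), height, width)
    for (v in seq_len(n_vessels)) {
      p1 <- c(stats::runif(1, 0, width - 1), stats::runif(1, 0, height - 1))
      p2 <- c(stats::runif(1, 0, width - 1), stats::runif(1, 0, height - 1))
      d <- p2 - p1
      len2 <- sum(d^2)
      if (len2 == 0) next
      tt <- pmin(pmax(((cc - p1[1]) * d[1] + (rr - p1[2]) * d[2]) / len2, 0), 1)
      dist2 <- (cc - (p1[1] + tt * d[1]))^2 + (rr - (p1[2] + tt * d[2]))^2
      mask <- mask | (dist2 <= vessel_halfwidth^2)
    }
    if (!any(mask)) stop("vessel geometry produced an empty mask")
    if (is.null(cells)) {
      cells <- cbind(stats::runif(n_cells, 0, (width - 1) * pixel_size),
                     stats::runif(n_cells, 0, (height - 1) * pixel_size))
      # put a few cells exactly on the vessel
      vp <- which(mask, arr.ind = TRUE)
      n_on <- min(3L, nrow(cells))
      pick <- vp[sample.int(nrow(vp), n_on), , drop = FALSE]
      cells[seq_len(n_on), ] <- cbind((pick[, 2] - 1) * pixel_size,
                                      (pick[, 1] - 1) * pixel_size)
    }
    colnames(cells) <- c("x", "y")
    vp <- which(mask, arr.ind = TRUE)  # (row, col)
    vx <- (vp[, 2] - 1) * pixel_size
    vy <- (vp[, 1] - 1) * pixel_size
    true_dist <- vapply(seq_len(nrow(cells)), function(i) {
      # nearest vessel pixel from the cell's containing pixel center
      px <- round(cells[i, 1] / pixel_size) * pixel_size
      py <- round(cells[i, 2] / pixel_size) * pixel_size
      sqrt(min((vx - px)^2 + (vy - py)^2))
    }, 0)
    inside <- mask[cbind(round(cells[, 2] / pixel_size) + 1,
                         round(cells[, 1] / pixel_size) + 1)]
    cell_channel <- render_gaussians(height, width, pixel_size, cells,
                                     sigma = 2 * pixel_size, peak = 500)
    truth <- structure(list(
      distance = true_dist, inside = inside, seed = seed
    ), class = "ground_truth")
    list(mask = mask, cell_channel = cell_channel, cells = cells,
         truth = truth)
  })
}
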