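#' Sample an intensity profile along a line
#'
#' Bilinear interpolation at uniform steps from endpoint A to endpoint B,
#' the usual plot-profile behaviour. Used for the 5-um profile along the
#' centriolar axis.
#'
#' @param image 2D intensity matrix.
#' @param a,b endpoints `c(x, y)` in micrometers.
#' @param pixel_size micrometers per pixel.
#' @param step sampling step, micrometers (default 0.1).
#' @return a `line_profile`: data.frame with `position` (micrometers from A)
#'   and `raw` intensity.
#' @export
line_profile <- function(image, a, b, pixel_size, step = 0.1) {
  len <- sqrt(sum((b - a)^2))
  if (len <= 0) stop("degenerate line (zero length)")
  pos <- seq(0, len, by = step)
  u <- (b - a) / len
  xs <- a[1] + pos * u[1]
  ys <- a[2] + pos * u[2]
  cs <- xs / pixel_size + 1  # fractional column index
  rs <- ys / pixel_size + 1
  h <- nrow(image); w <- ncol(image)
  if (any(cs < 1 | cs > w | rs < 1 | rs > h)) {
    stop("line exits the image bounds")
  }
  c0 <- pmin(floor(cs), w - 1); r0 <- pmin(floor(rs), h - 1)
  fc <- cs - c0; fr <- rs - r0
  v <- (1 - fr) * (1 - fc) * image[cbind(r0, c0)] +
       (1 - fr) * fc       * image[cbind(r0, c0 + 1)] +
       fr       * (1 - fc) * image[cbind(r0 + 1, c0)] +
       fr       * fc       * image[cbind(r0 + 1, c0 + 1)]
  structure(data.frame(position = pos, raw = v),
            class = c("line_profile", "data.frame"))
}

#' Normalize a line profile to its end segments
#'
#' Divides every sample by the mean of the first `tail_count` and last
#' `tail_count` raw values. By default the two end segments are pooled into a
#' single mean of `2 * tail_count` samples; `per_end = TRUE` instead
#' normalizes each half of the profile to its own end mean.
#'
#' @param profile a `line_profile`.
#' @param tail_count samples per end (default 4).
#' @param per_end normalize each half to its own end segment.
#' @return the profile with a `normalized` column added.
#' @export
normalize_profile <- function(profile, tail_count = 4L, per_end = FALSE) {
  n <- nrow(profile)
  if (n < 2L * tail_count) {
    stop("profile has fewer than 2 * tail_count samples")
  }
  head_idx <- seq_len(tail_count)
  tail_idx <- seq(n - tail_count + 1L, n)
  if (per_end) {
    m_head <- mean(profile$raw[head_idx])
    m_tail <- mean(profile$raw[tail_idx])
    if (m_head <= 0 || m_tail <= 0) stop("end-segment mean is <= 0")
    half <- seq_len(n) <= n / 2
    profile$normalized <- ifelse(half, profile$raw / m_head,
                                 profile$raw / m_tail)
  } else {
    m <- mean(profile$raw[c(head_idx, tail_idx)])
    if (m <= 0) stop("pooled end-segment mean is <= 0")
    profile$normalized <- profile$raw / m
  }
  profile
}

# mean intensity in a circular ROI; membership by pixel-center test
roi_mean <- function(image, center, radius, pixel_size) {
  h <- nrow(image); w <- ncol(image)
  xs <- (seq_len(w) - 1) * pixel_size
  ys <- (seq_len(h) - 1) * pixel_size
  cx <- abs(xs - center[1]) <= radius
  cy <- abs(ys - center[2]) <= radius
  if (!any(cx) || !any(cy)) stop("ROI contains no pixel centers")
  sub <- image[cy, cx, drop = FALSE]
  dx2 <- (xs[cx] - center[1])^2
  dy2 <- (ys[cy] - center[2])^2
  inside <- outer(dy2, dx2, "+") <= radius^2
  if (!any(inside)) stop("ROI contains no pixel centers")
  mean(sub[inside])
}

#' Intensity ratio between the two centrioles of an intact centrosome
#'
#' Mean fluorescence in two circular ROIs (default radius 0.35 um), each
#' centered on one centriole of a summed z-projection; the ratio takes the
#' higher mean as divisor, so it lies in (0, 1] and is symmetric in the two
#' positions.
#'
#' @param image summed z-projection, 2D matrix.
#' @param p1,p2 centriole positions `c(x, y)`, micrometers.
#' @param pixel_size micrometers per pixel.
#' @param roi_radius micrometers (default 0.35).
#' @return list with `ratio`, `mean1`, `mean2`.
#' @export
centrosome_intensity_ratio <- function(image, p1, p2, pixel_size,
                                       roi_radius = 0.35) {
  if (roi_radius <= 0) stop("'roi_radius' must be positive")
  lim_x <- (ncol(image) - 1) * pixel_size
  lim_y <- (nrow(image) - 1) * pixel_size
  for (p in list(p1, p2)) {
    if (p[1] - roi_radius < 0 || p[1] + roi_radius > lim_x ||
        p[2] - roi_radius < 0 || p[2] + roi_radius > lim_y) {
      stop("ROI extends beyond the image")
    }
  }
  if (sqrt(sum((p1 - p2)^2)) < 2 * roi_radius) {
    warning("the two ROIs overlap")
  }
  m1 <- roi_mean(image, p1, roi_radius, pixel_size)
  m2 <- roi_mean(image, p2, roi_radius, pixel_size)
  if (max(m1, m2) <= 0 || min(m1, m2) <= 0) {
    stop("ROI mean is <= 0; no signal under at least one ROI")
  }
  list(ratio = min(m1, m2) / max(m1, m2), mean1 = m1, mean2 = m2)
}

#' Mean-intensity series of a circular ROI through a movie
#'
#' @param movie a [calibrated_movie()].
#' @param channel channel role.
#' @param center ROI center `c(x, y)`, micrometers.
#' @param radius ROI radius, micrometers.
#' @return numeric vector, one mean per frame.
#' @export
roi_series <- function(movie, channel, center, radius) {
  vapply(seq_len(movie$frames), function(ti) {
    roi_mean(get_frame(movie, channel, ti), center, radius, movie$pixel_size)
  }, 0)
}

#' Normalize a FRAP recovery curve
#'
#' Background detector noise is subtracted from both series, the bleached-ROI
#' mean is divided by the non-bleached reference-ROI mean frame by frame, and
#' the result is rescaled so the pre-bleach mean equals 1.
#'
#' @param bleached bleached-ROI mean series.
#' @param reference reference-ROI mean series, same length.
#' @param background background detector level.
#' @param pre_frames number of pre-bleach frames (>= 1).
#' @param frame_interval seconds per frame.
#' @return a `frap_curve`: data.frame with `time` (seconds, 0 at the first
#'   post-bleach frame), `value` (normalized recovery) and attributes
#'   `pre_frames`, `bleach_frame`.
#' @export
frap_normalize <- function(bleached, reference, background, pre_frames = 5L,
                           frame_interval = 1) {
  if (length(bleached) != length(reference)) {
    stop("bleached and reference series differ in length")
  }
  if (pre_frames < 1L) stop("'pre_frames' must be >= 1")
  ref0 <- reference - background
  if (any(ref0 <= 0)) stop("reference minus background is <= 0 at some frame")
  v <- (bleached - background) / ref0
  pre_mean <- mean(v[seq_len(pre_frames)])
  if (pre_mean <= 0) stop("pre-bleach mean is <= 0")
  v <- v / pre_mean
  n <- length(v)
  tt <- (seq_len(n) - pre_frames - 1) * frame_interval
  out <- data.frame(time = tt, value = v)
  attr(out, "pre_frames") <- as.integer(pre_frames)
  attr(out, "bleach_frame") <- as.integer(pre_frames + 1L)
  class(out) <- c("frap_curve", "data.frame")
  out
}

#' Fit a single-exponential recovery to a normalized FRAP curve
#'
#' Least-squares fit of `value(t) = plateau - (plateau - depth) * exp(-k t)`
#' to the post-bleach samples. Returns the recovery half-time
#' `log(2) / k` and the plateau-derived mobile fraction
#' `(plateau - depth) / (1 - depth)` (pre-bleach level is 1 by construction).
#'
#' @param curve a `frap_curve` from [frap_normalize()].
#' @return list with `halftime` (seconds), `mobile_fraction`, `plateau`,
#'   `depth`, `rate` and the `fit` object.
#' @export
frap_halftime <- function(curve) {
  post <- curve[curve$time >= 0, , drop = FALSE]
  if (nrow(post) < 10L) stop("need at least 10 post-bleach frames")
  depth0 <- post$value[1]
  plateau0 <- mean(post$value[post$time >= stats::quantile(post$time, 0.8)])
  rise <- plateau0 - depth0
  if (rise < -1e-8) stop("post-bleach curve decreases; recovery fit cannot converge")
  if (rise <= 1e-8) {
    # flat curve: nothing recovers
    return(list(halftime = NA_real_, mobile_fraction = 0,
                plateau = depth0, depth = depth0, rate = 0, fit = NULL))
  }
  k0 <- log(2) / max(diff(range(post$time)) / 4, 1e-6)
  fit <- try(minpack.lm::nlsLM(
    value ~ plateau - (plateau - depth) * exp(-k * time),
    data = post,
    start = list(plateau = plateau0, depth = depth0, k = k0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) stop("exponential recovery fit failed")
  cf <- stats::coef(fit)
  if (cf[["k"]] <= 0) stop("fit converged to a non-recovering curve")
  list(
    halftime = log(2) / cf[["k"]],
    mobile_fraction = (cf[["plateau"]] - cf[["depth"]]) / (1 - cf[["depth"]]),
    plateau = cf[["plateau"]],
    depth = cf[["depth"]],
    rate = cf[["k"]],
    fit = fit
  )
}

#' @export
plot.frap_curve <- function(x, ...) {
  graphics::plot(x$time, x$value, xlab = "time after bleach (s)",
                 ylab = "normalized intensity", pch = 16, cex = 0.6, ...)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::abline(h = 1, lty = 3, col = "grey70")
  invisible(x)
}
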