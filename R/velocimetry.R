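#' Background-correct an image sequence
#'
#' Subtracts the pixelwise temporal mean of the whole sequence from every
#' frame and clips negative residuals at zero, removing static structure so
#' that only moving objects contribute to the displacement estimate.
#'
#' @param sequence 3D array (`time x height x width`) or
#'   [calibrated_movie()] channel.
#' @return array of the same shape.
#' @export
background_correct <- function(sequence) {
  if (length(dim(sequence)) != 3L) stop("'sequence' must be a 3D array")
  n <- dim(sequence)[1]
  if (n < 2L) stop("need at least two frames")
  avg <- apply(sequence, c(2, 3), mean)
  out <- sequence
  for (ti in seq_len(n)) out[ti, , ] <- pmax(sequence[ti, , ] - avg, 0)
  out
}

#' Remove connected components outside a size band
#'
#' 8-connectivity labeling; components with area outside
#' `[min_area, max_area]` (inclusive) are removed — the particle filter that
#' discards objects smaller or larger than cells.
#'
#' @param mask logical or 0/1 matrix.
#' @param min_area,max_area area bounds in square micrometers.
#' @param pixel_size micrometers per pixel.
#' @return logical matrix of surviving components.
#' @export
size_filter <- function(mask, min_area, max_area, pixel_size = 1) {
  if (min_area >= max_area) stop("'min_area' must be below 'max_area'")
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- EBImage::imageData(lab)
  if (max(lab) == 0) return(matrix(FALSE, nrow(mask), ncol(mask)))
  # bwlabel is 4-connected; merge labels touching diagonally (union-find)
  parent <- seq_len(max(lab))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  h <- nrow(lab); w <- ncol(lab)
  for (off in list(c(1, 1), c(1, -1))) {
    a <- lab[1:(h - 1), if (off[2] > 0) 1:(w - 1) else 2:w]
    b <- lab[2:h, if (off[2] > 0) 2:w else 1:(w - 1)]
    touch <- which(a > 0 & b > 0 & a != b)
    for (k in touch) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_along(parent), find, 1L)
  lab[lab > 0] <- roots[lab[lab > 0]]
  areas <- tabulate(lab[lab > 0]) * pixel_size^2
  keep <- which(areas >= min_area & areas <= max_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Estimate the lateral displacement between two frames
#'
#' Finds the integer shift within `search_radius` that maximizes the
#' zero-mean normalized cross-correlation of the overlapping region — the
#' shift that optimizes the overlap of the current frame with the previous
#' one. Exact score ties are broken toward the smaller shift magnitude.
#' Optional parabolic interpolation of the correlation peak refines the shift
#' to sub-pixel precision.
#'
#' @param current,previous 2D matrices of identical shape.
#' @param search_radius pixels (default 25).
#' @param subpixel apply 3-point parabolic refinement along each axis.
#' @param method `"ncc"` (normalized cross-correlation, default) or
#'   `"phase"` (phase correlation).
#' @return list with `dx`, `dy` (pixels; the translation mapping `previous`
#'   onto `current`) and `score` (peak correlation).
#' @export
estimate_displacement <- function(current, previous, search_radius = 25,
                                  subpixel = FALSE,
                                  method = c("ncc", "phase")) {
  method <- match.arg(method)
  if (!all(dim(current) == dim(previous))) stop("frames differ in shape")
  if (stats::sd(current) == 0 || stats::sd(previous) == 0) {
    stop("flat (zero-variance) frame; displacement undefined")
  }
  h <- nrow(current); w <- ncol(current)
  r <- search_radius
  if (method == "phase") {
    fa <- stats::fft(current); fb <- stats::fft(previous)
    cross <- fa * Conj(fb)
    cross <- cross / pmax(Mod(cross), 1e-12)
    cc <- Re(stats::fft(cross, inverse = TRUE)) / length(cross)
    # wrap to signed shifts and mask to the search radius
    score_at <- function(dy, dx) cc[(dy %% h) + 1, (dx %% w) + 1]
  } else {
    score_at <- function(dy, dx) {
      # overlap of current vs previous shifted by (dx, dy)
      r1 <- max(1, 1 + dy):min(h, h + dy)
      c1 <- max(1, 1 + dx):min(w, w + dx)
      a <- current[r1, c1]
      b <- previous[r1 - dy, c1 - dx]
      sa <- stats::sd(a); sb <- stats::sd(b)
      if (sa == 0 || sb == 0) return(-Inf)
      mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
    }
  }
  cand <- expand.grid(dy = -r:r, dx = -r:r)
  ord <- order(cand$dx^2 + cand$dy^2)  # ties resolve toward smaller |shift|
  cand <- cand[ord, ]
  best <- c(0, 0); best_score <- -Inf
  scores <- matrix(NA_real_, 2 * r + 1, 2 * r + 1)  # [dy + r + 1, dx + r + 1]
  for (i in seq_len(nrow(cand))) {
    s <- score_at(cand$dy[i], cand$dx[i])
    scores[cand$dy[i] + r + 1, cand$dx[i] + r + 1] <- s
    if (s > best_score + 1e-12) {
      best_score <- s
      best <- c(cand$dx[i], cand$dy[i])
    }
  }
  dx <- best[1]; dy <- best[2]
  if (subpixel) {
    para <- function(sm, s0, sp) {
      den <- sm - 2 * s0 + sp
      if (!is.finite(den) || den >= 0) return(0)
      delta <- 0.5 * (sm - sp) / den
      max(min(delta, 0.5), -0.5)
    }
    iy <- dy + r + 1; ix <- dx + r + 1
    if (iy > 1 && iy < 2 * r + 1) {
      dy <- dy + para(scores[iy - 1, ix], scores[iy, ix], scores[iy + 1, ix])
    }
    if (ix > 1 && ix < 2 * r + 1) {
      dx <- dx + para(scores[iy, ix - 1], scores[iy, ix], scores[iy, ix + 1])
    }
  }
  list(dx = dx, dy = dy, score = best_score)
}

#' Per-frame drift series of a movie channel
#'
#' Runs [estimate_displacement()] on every consecutive frame pair of a
#' (typically background-corrected) sequence.
#'
#' @param sequence 3D array (`time x height x width`).
#' @param search_radius,subpixel,method passed to [estimate_displacement()].
#' @param pixel_size micrometers per pixel.
#' @return a `drift_series`: data.frame with `pair`, `dx_px`, `dy_px`,
#'   `dx_um`, `dy_um`, `score`, one row per consecutive frame pair.
#' @export
estimate_drift_series <- function(sequence, search_radius = 25,
                                  subpixel = FALSE, method = "ncc",
                                  pixel_size = 1) {
  n <- dim(sequence)[1]
  if (n < 2L) stop("need at least two frames")
  rows <- lapply(2:n, function(ti) {
    est <- estimate_displacement(sequence[ti, , ], sequence[ti - 1, , ],
                                 search_radius, subpixel, method)
    data.frame(pair = ti - 1L, dx_px = est$dx, dy_px = est$dy,
               dx_um = est$dx * pixel_size, dy_um = est$dy * pixel_size,
               score = est$score)
  })
  structure(do.call(rbind, rows),
            class = c("drift_series", "data.frame"))
}

#' Chemotactic velocity from a drift series
#'
#' Per frame pair, the displacement component toward the chemokine source,
#' converted to micrometers per minute.
#'
#' @param drift a `drift_series` (or data.frame with `dy_px`).
#' @param frame_interval seconds between frames.
#' @param pixel_size micrometers per pixel.
#' @param source_direction `"+y"` (source toward increasing y, default) or
#'   `"-y"`.
#' @return list with `per_pair` (um/min, positive toward the source) and
#'   `mean` velocity.
#' @export
chemotactic_velocity <- function(drift, frame_interval, pixel_size,
                                 source_direction = "+y") {
  if (frame_interval <= 0 || pixel_size <= 0) {
    stop("calibration must be positive")
  }
  sgn <- if (source_direction == "-y") -1 else 1
  v <- sgn * drift$dy_px * pixel_size / (frame_interval / 60)
  list(per_pair = v, mean = mean(v))
}
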