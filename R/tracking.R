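#' Detect fluorescent puncta in a single frame
#'
#' Laplacian-of-Gaussian blob detection at the scale implied by the expected
#' object diameter, followed by 8-neighbour local-maximum selection and
#' sub-pixel refinement by intensity-weighted centroid of the positive
#' band-passed response in a window of about one object diameter. Spots are
#' returned in decreasing quality order, quality being the scale-normalized
#' LoG response at the peak.
#'
#' @param image 2D intensity matrix.
#' @param pixel_size micrometers per pixel.
#' @param expected_diameter micrometers; must be resolved by at least 2 pixels.
#' @param quality_threshold spots with quality below this are discarded. With
#'   `relative = TRUE` (default) the threshold is a fraction of the strongest
#'   response in the frame, mirroring a manually adjusted quality cut-off.
#' @param relative interpret `quality_threshold` relative to the frame maximum.
#' @return data.frame with columns `x`, `y` (micrometers) and `quality`.
#' @export
detect_spots <- function(image, pixel_size, expected_diameter = 0.65,
                         quality_threshold = 0.5, relative = TRUE) {
  if (expected_diameter < 2 * pixel_size) {
    stop("expected_diameter is under-resolved at this pixel size (< 2 px)")
  }
  empty <- data.frame(x = numeric(0), y = numeric(0), quality = numeric(0))
  rng <- range(image)
  if (diff(rng) == 0) return(empty)
  sigma <- expected_diameter / (2 * sqrt(2)) / pixel_size  # px; LoG blob scale
  hw <- max(2L, ceiling(3 * sigma))
  xs <- -hw:hw
  g <- exp(-outer(xs^2, xs^2, "+") / (2 * sigma^2))
  r2 <- outer(xs^2, xs^2, "+")
  log_k <- (r2 - 2 * sigma^2) / sigma^2 * g   # scale-normalized Laplacian
  log_k <- -(log_k - mean(log_k))             # zero-sum, positive at blobs
  resp <- EBImage::imageData(EBImage::filter2(EBImage::Image(image), log_k))
  h <- nrow(image); w <- ncol(image)
  thr <- if (relative) quality_threshold * max(resp) else quality_threshold
  thr <- max(thr, 1e-6 * diff(rng))
  # 8-neighbour local maxima strictly above every neighbour
  pk <- matrix(FALSE, h, w)
  core_r <- 2:(h - 1); core_c <- 2:(w - 1)
  ctr <- resp[core_r, core_c]
  is_max <- ctr >= thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (ctr > resp[core_r + dr, core_c + dc])
  }
  pk[core_r, core_c] <- is_max
  if (!any(pk)) return(empty)
  peaks <- which(pk, arr.ind = TRUE)
  # centroid window half-width ~ object radius: tight enough that a
  # neighbouring punctum at cohesive distance does not bias the centroid
  win <- max(2L, round(expected_diameter / 2 / pixel_size))
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    r <- peaks[i, 1]; c <- peaks[i, 2]
    rs <- max(1, r - win):min(h, r + win)
    cs <- max(1, c - win):min(w, c + win)
    # centroid on the positive band-passed response: the LoG negative lobe
    # cancels the shoulder of any nearby punctum
    patch <- pmax(resp[rs, cs, drop = FALSE], 0)
    tot <- sum(patch)
    if (tot <= 0) return(NULL)
    rc <- sum(rowSums(patch) * rs) / tot
    cc <- sum(colSums(patch) * cs) / tot
    data.frame(x = (cc - 1) * pixel_size, y = (rc - 1) * pixel_size,
               quality = resp[r, c])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) return(empty)
  out[order(out$quality, decreasing = TRUE), , drop = FALSE]
}

#' Link centriole spot detections into a two-identity pair track
#'
#' Greedy frame-to-frame nearest-neighbour assignment of the two centriole
#' identities A and B, minimizing summed displacement; exact cost ties are
#' broken by spot quality rank. A missed detection is bridged for up to
#' `gap_size` frames by carrying the last known position as assignment memory
#' (the frame itself is recorded missing); longer gaps terminate the track.
#' Frames offering more than four candidate spots for three consecutive
#' frames abort linking — the cell is ambiguous.
#'
#' @param spots_per_frame list (one element per frame) of data.frames as
#'   returned by [detect_spots()].
#' @param max_distance micrometers; maximum accepted frame-to-frame
#'   displacement per identity.
#' @param gap_size frames; maximum bridged detection gap.
#' @return a `centriole_pair_track`: data.frame with columns `frame`, `ax`,
#'   `ay`, `bx`, `by` (micrometers, `NA` when missing) and `distance`
#'   (micrometers, `NA` if either position is missing).
#' @export
link_pair <- function(spots_per_frame, max_distance = 25, gap_size = 3) {
  n <- length(spots_per_frame)
  res <- data.frame(frame = seq_len(n), ax = NA_real_, ay = NA_real_,
                    bx = NA_real_, by = NA_real_, distance = NA_real_)
  # initialize on the first frame holding at least two spots
  start <- which(vapply(spots_per_frame,
                        function(s) !is.null(s) && nrow(s) >= 2, TRUE))[1]
  if (is.na(start)) {
    return(structure(res, class = c("centriole_pair_track", "data.frame")))
  }
  s0 <- spots_per_frame[[start]]
  mem_a <- c(s0$x[1], s0$y[1]); mem_b <- c(s0$x[2], s0$y[2])
  gap_a <- 0L; gap_b <- 0L; crowded <- 0L
  res[start, c("ax", "ay")] <- mem_a
  res[start, c("bx", "by")] <- mem_b
  for (ti in seq_len(n)[-seq_len(start)]) {
    sp <- spots_per_frame[[ti]]
    k <- if (is.null(sp)) 0L else nrow(sp)
    if (k > 4L) {
      crowded <- crowded + 1L
      if (crowded >= 3L) stop("more than 4 candidate spots persisting; ambiguous cell")
      sp <- sp[1:4, , drop = FALSE]; k <- 4L
    } else crowded <- 0L
    best <- NULL; best_cost <- Inf; best_rank <- Inf
    big <- 1e6
    for (ia in 0:k) for (ib in 0:k) {
      if (ia != 0 && ia == ib) next
      cost <- 0; rank <- 0
      if (ia > 0) {
        da <- sqrt(sum((c(sp$x[ia], sp$y[ia]) - mem_a)^2))
        if (da > max_distance) next
        cost <- cost + da; rank <- rank + ia
      } else cost <- cost + big
      if (ib > 0) {
        db <- sqrt(sum((c(sp$x[ib], sp$y[ib]) - mem_b)^2))
        if (db > max_distance) next
        cost <- cost + db; rank <- rank + ib
      } else cost <- cost + big
      if (cost < best_cost - 1e-12 ||
          (abs(cost - best_cost) <= 1e-12 && rank < best_rank)) {
        best <- c(ia, ib); best_cost <- cost; best_rank <- rank
      }
    }
    if (is.null(best)) best <- c(0L, 0L)
    if (best[1] > 0) {
      mem_a <- c(sp$x[best[1]], sp$y[best[1]]); gap_a <- 0L
      res[ti, c("ax", "ay")] <- mem_a
    } else gap_a <- gap_a + 1L
    if (best[2] > 0) {
      mem_b <- c(sp$x[best[2]], sp$y[best[2]]); gap_b <- 0L
      res[ti, c("bx", "by")] <- mem_b
    } else gap_b <- gap_b + 1L
    if (gap_a > gap_size || gap_b > gap_size) break  # track ends
  }
  ok <- !is.na(res$ax) & !is.na(res$bx)
  res$distance[ok] <- sqrt((res$ax[ok] - res$bx[ok])^2 +
                           (res$ay[ok] - res$by[ok])^2)
  structure(res, class = c("centriole_pair_track", "data.frame"))
}

#' @export
print.centriole_pair_track <- function(x, ...) {
  ok <- sum(!is.na(x$distance))
  cat(sprintf("centriole_pair_track: %d frame(s), %d with both centrioles\n",
              nrow(x), ok))
  if (ok) {
    cat(sprintf("  distance range %.3f - %.3f um\n",
                min(x$distance, na.rm = TRUE), max(x$distance, na.rm = TRUE)))
  }
  invisible(x)
}

#' Track a centriole pair through a calibrated movie
#'
#' Convenience wrapper: runs [detect_spots()] on every frame of the centriole
#' channel and links the detections with [link_pair()].
#'
#' @param movie a [calibrated_movie()] with a `"centriole"` channel.
#' @param expected_diameter,quality_threshold passed to [detect_spots()].
#' @param max_distance,gap_size passed to [link_pair()].
#' @param channel channel role holding the centriole marker.
#' @return a `centriole_pair_track`.
#' @export
track_centriole_pair <- function(movie, expected_diameter = 0.65,
                                 quality_threshold = 0.5,
                                 max_distance = 25, gap_size = 3,
                                 channel = "centriole") {
  stopifnot(inherits(movie, "calibrated_movie"))
  spots <- lapply(seq_len(movie$frames), function(ti) {
    detect_spots(get_frame(movie, channel, ti), movie$pixel_size,
                 expected_diameter, quality_threshold)
  })
  link_pair(spots, max_distance, gap_size)
}

#' Inter-centriole distance series of a pair track
#'
#' @param track a `centriole_pair_track`.
#' @param frame_interval seconds per frame.
#' @return data.frame with `time` (seconds, `(frame - 1) * frame_interval`)
#'   and `distance` (micrometers); frames with a missing centriole are
#'   omitted, never interpolated.
#' @export
distance_series <- function(track, frame_interval) {
  if (nrow(track) == 0L) stop("empty track")
  ok <- !is.na(track$distance)
  data.frame(time = (track$frame[ok] - 1) * frame_interval,
             distance = track$distance[ok])
}

#' Migration statistics of a cell track
#'
#' @param positions matrix or data.frame with columns `x`, `y` (micrometers),
#'   one row per frame, temporally ordered.
#' @param frame_interval seconds per frame.
#' @return list with `speed` (accumulated path length over elapsed time,
#'   um/min), `accumulated_distance` (um), `net_displacement` (um) and
#'   `directionality` (net over accumulated, in [0, 1]).
#' @export
track_migration_stats <- function(positions, frame_interval) {
  positions <- as.matrix(positions[, c("x", "y")])
  n <- nrow(positions)
  if (n < 2L) stop("need at least two track points")
  elapsed_min <- (n - 1) * frame_interval / 60
  if (elapsed_min <= 0) stop("zero elapsed time")
  steps <- sqrt(rowSums(diff(positions)^2))
  acc <- sum(steps)
  net <- sqrt(sum((positions[n, ] - positions[1, ])^2))
  list(speed = acc / elapsed_min,
       accumulated_distance = acc,
       net_displacement = net,
       directionality = if (acc > 0) net / acc else 0)
}

#' Comet-track statistics around microtubule-organizing centers
#'
#' Attributes each comet track to the nearest anchor if its origin (position
#' at the track's first frame) lies within `origin_radius`, then reports
#' nucleation rates and mean comet speed.
#'
#' @param tracks data.frame with columns `track`, `frame`, `x`, `y`
#'   (micrometers) — the generic tracker-export layout.
#' @param anchors matrix of anchor positions (columns x, y, micrometers).
#' @param origin_radius micrometers.
#' @param frame_interval seconds per frame.
#' @return list with `attributed` (tracks per anchor), `rate_per_anchor` and
#'   `rate_per_cell` (track starts per minute, per anchor and total),
#'   `mean_speed` (um/s) and `origin_counts` (anchors with at least one
#'   attributed track).
#' @export
comet_stats <- function(tracks, anchors, origin_radius, frame_interval) {
  anchors <- as.matrix(anchors)
  if (nrow(anchors) == 0L) stop("'anchors' must be nonempty")
  if (origin_radius <= 0) stop("'origin_radius' must be positive")
  ids <- unique(tracks$track)
  obs_min <- (diff(range(tracks$frame)) + 1) * frame_interval / 60
  assigned <- integer(nrow(anchors))
  speeds <- numeric(0)
  n_attr <- 0L
  for (id in ids) {
    tr <- tracks[tracks$track == id, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    origin <- c(tr$x[1], tr$y[1])
    d2 <- (anchors[, 1] - origin[1])^2 + (anchors[, 2] - origin[2])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) <= origin_radius) {
      assigned[j] <- assigned[j] + 1L
      n_attr <- n_attr + 1L
    }
    if (nrow(tr) >= 2) {
      step <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
      speeds <- c(speeds, mean(step) / frame_interval)
    }
  }
  list(attributed = assigned,
       rate_per_anchor = n_attr / obs_min / nrow(anchors),
       rate_per_cell = n_attr / obs_min,
       mean_speed = if (length(speeds)) mean(speeds) else NA_real_,
       origin_counts = sum(assigned > 0))
}
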