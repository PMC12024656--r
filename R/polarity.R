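#' Back-to-front polarity reporter profile of one cell
#'
#' Quantifies the front-rear gradient of a polarity reporter relative to a
#' reference channel. Per frame: pixels within `exclusion_radius` of any
#' centriole are excluded for the entire analysis; each channel is normalized
#' to that cell's intensity averaged over all time points (included pixels
#' only); pixel positions are projected onto the migration direction and
#' rescaled to [0, 1] by that frame's cell extent (rear = 0); pixels are
#' grouped into `n_bins` equally long segments and the ratio of normalized
#' reporter to normalized reference is averaged per segment — first within
#' each time point, then over all time points of the cell.
#'
#' @param movie a [calibrated_movie()] carrying the reporter and reference
#'   channels.
#' @param masks logical `time x height x width` array of per-frame cell masks.
#' @param centrioles list (per frame) of centriole position matrices
#'   (columns x, y, micrometers); an empty matrix means no exclusion.
#' @param directions per-frame unit direction of migration as a 2-column
#'   matrix (x, y), or `NULL` to estimate it from the mask-centroid
#'   displacement smoothed over 3 frames.
#' @param n_bins number of segments (50 fine, 2 front/back).
#' @param exclusion_radius micrometers; disk radius excluded around each
#'   centriole (default 1.5).
#' @param reporter,reference channel role labels.
#' @param min_timepoints minimum usable frames (default 6, matching cells
#'   followed for at least 30 min at 5-min intervals).
#' @return a `polarity_profile`: list with `profile` (per-bin time-averaged
#'   ratio, `NA` where a bin was empty in every frame), `per_frame` (frames x
#'   bins matrix), `n_bins`, `fractured` (filled by callers), and bookkeeping
#'   counts.
#' @export
compute_polarity_profile <- function(movie, masks, centrioles,
                                     directions = NULL, n_bins = 50,
                                     exclusion_radius = 1.5,
                                     reporter = "polarity",
                                     reference = "reference",
                                     min_timepoints = 6L) {
  stopifnot(inherits(movie, "calibrated_movie"))
  n <- movie$frames
  if (n < min_timepoints) {
    stop("cell observed for fewer than ", min_timepoints, " time points")
  }
  px <- movie$pixel_size
  h <- movie$height; w <- movie$width
  xs <- (seq_len(w) - 1) * px
  ys <- (seq_len(h) - 1) * px
  xmat <- matrix(rep(xs, each = h), h, w)
  ymat <- matrix(rep(ys, times = w), h, w)
  for (ti in seq_len(n)) {
    if (!any(masks[ti, , ])) stop("empty cell mask at frame ", ti)
  }
  if (is.null(directions)) directions <- estimate_directions(masks, px)
  # per-frame inclusion masks (cell minus centriole exclusion disks)
  incl <- vector("list", n)
  for (ti in seq_len(n)) {
    m <- masks[ti, , ]
    if (!any(m)) stop("empty cell mask at frame ", ti)
    cen <- centrioles[[ti]]
    if (!is.null(cen) && nrow(cen) > 0) {
      for (i in seq_len(nrow(cen))) {
        d2 <- (xmat - cen[i, 1])^2 + (ymat - cen[i, 2])^2
        m <- m & (d2 > exclusion_radius^2)
      }
    }
    incl[[ti]] <- m
  }
  # all-time-point per-channel means over included pixels
  rep_vals <- lapply(seq_len(n), function(ti) {
    get_frame(movie, reporter, ti)[incl[[ti]]]
  })
  ref_vals <- lapply(seq_len(n), function(ti) {
    get_frame(movie, reference, ti)[incl[[ti]]]
  })
  rep_mean <- mean(unlist(rep_vals))
  ref_mean <- mean(unlist(ref_vals))
  if (rep_mean <= 0 || ref_mean <= 0) stop("channel mean is <= 0")
  per_frame <- matrix(NA_real_, n, n_bins)
  excluded_px <- integer(n); binned_px <- integer(n)
  for (ti in seq_len(n)) {
    m <- incl[[ti]]
    u <- directions[ti, ] / sqrt(sum(directions[ti, ]^2))
    proj <- xmat[m] * u[1] + ymat[m] * u[2]
    extent <- range(proj)
    if (diff(extent) <= 0) stop("degenerate (zero-length) cell extent at frame ", ti)
    s <- (proj - extent[1]) / diff(extent)
    bin <- pmin(floor(s * n_bins) + 1L, n_bins)
    rv <- rep_vals[[ti]] / rep_mean
    fv <- ref_vals[[ti]] / ref_mean
    for (bi in unique(bin)) {
      sel <- bin == bi
      denom <- mean(fv[sel])
      if (denom > 0) per_frame[ti, bi] <- mean(rv[sel]) / denom
    }
    excluded_px[ti] <- sum(masks[ti, , ]) - sum(m)
    binned_px[ti] <- sum(m)
  }
  profile <- colMeans(per_frame, na.rm = TRUE)
  profile[!is.finite(profile)] <- NA_real_
  structure(list(
    profile = profile,
    per_frame = per_frame,
    n_bins = as.integer(n_bins),
    n_timepoints = n,
    excluded_px = excluded_px,
    binned_px = binned_px,
    fractured = NA
  ), class = "polarity_profile")
}

# migration direction from mask-centroid displacement, smoothed over 3 frames
estimate_directions <- function(masks, pixel_size) {
  n <- dim(masks)[1]
  cent <- t(vapply(seq_len(n), function(ti) {
    idx <- which(masks[ti, , ], arr.ind = TRUE)
    c(mean(idx[, 2] - 1), mean(idx[, 1] - 1)) * pixel_size
  }, c(0, 0)))
  steps <- diff(cent)
  if (nrow(steps) == 0) stop("cannot estimate direction from a single frame")
  dirs <- matrix(0, n, 2)
  for (ti in seq_len(n)) {
    lo <- max(1, ti - 2); hi <- min(nrow(steps), ti)
    v <- colSums(steps[lo:hi, , drop = FALSE])
    if (sum(v^2) == 0) v <- colSums(steps)  # stationary: fall back to net
    if (sum(v^2) == 0) stop("cell never moves; migration direction undefined")
    dirs[ti, ] <- v
  }
  dirs
}

#' @export
print.polarity_profile <- function(x, ...) {
  cat(sprintf("polarity_profile: %d bins over %d time point(s)\n",
              x$n_bins, x$n_timepoints))
  if (x$n_bins <= 4) {
    cat("  back-to-front ratios:",
        paste(sprintf("%.3f", x$profile), collapse = ", "), "\n")
  } else {
    cat(sprintf("  back %.3f ... front %.3f\n",
                x$profile[1], x$profile[x$n_bins]))
  }
  invisible(x)
}

#' @export
plot.polarity_profile <- function(x, ...) {
  mid <- (seq_len(x$n_bins) - 0.5) / x$n_bins
  graphics::plot(mid, x$profile, type = "b", pch = 16, cex = 0.6,
                 xlab = "normalized position (0 = back, 1 = front)",
                 ylab = "reporter / reference ratio", ...)
  graphics::abline(h = 1, lty = 3, col = "grey60")
  invisible(x)
}

#' Stratify polarity profiles by centrosome integrity
#'
#' Splits a set of per-cell profiles into intact and fractured groups using
#' the cell-level fracture call on each cell's inter-centriole distance
#' series.
#'
#' @param profiles named list of `polarity_profile` objects (names = cell
#'   ids).
#' @param series named list of distance series (numeric vectors or data.frames
#'   with a `distance` column), same cell ids.
#' @param threshold micrometers (default 1.5).
#' @param min_timepoints fractured frames required for the cell-level call.
#' @return list with `intact` and `fractured` sublists of profiles (each
#'   profile's `fractured` flag filled in).
#' @export
stratify_by_fracture <- function(profiles, series, threshold = 1.5,
                                 min_timepoints = 2L) {
  ids <- names(profiles)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("profiles must be uniquely named by cell id")
  }
  if (anyDuplicated(names(series))) stop("duplicate cell id in distance series")
  if (!setequal(ids, names(series))) stop("unmatched cell ids between profiles and series")
  out <- list(intact = list(), fractured = list())
  for (id in ids) {
    s <- series[[id]]
    d <- if (is.data.frame(s)) s$distance else s
    fr <- cell_fractured(d, threshold, min_timepoints)
    p <- profiles[[id]]
    p$fractured <- fr
    out[[if (fr) "fractured" else "intact"]][[id]] <- p
  }
  out
}
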