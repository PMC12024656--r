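#' Classify an inter-centriole distance into a category scheme
#'
#' Two category schemes are in use: the dendritic-cell (`"dc"`) scheme with
#' classes close `[0, 1.5)`, near `[1.5, 3.5)`, short-distance separated
#' `[3.5, 5)` and long-distance separated `[5, Inf)`; and the fibroblast
#' scheme with close `[0, 1.5)`, near `[1.5, 3)` and far `[3, Inf)`. All
#' intervals are half-open with inclusive lower bounds; printed bounds such as
#' "1.49" are display rounding of the same half-open intervals.
#'
#' @param distance inter-centriole distance(s), micrometers, >= 0.
#' @param scheme `"dc"` or `"fibroblast"`.
#' @param bounds optional override of the scheme boundaries (strictly
#'   increasing, micrometers).
#' @return an ordered factor over the scheme's categories.
#' @export
classify_frame <- function(distance, scheme = c("dc", "fibroblast"),
                           bounds = NULL) {
  scheme <- match.arg(scheme)
  if (any(distance < 0, na.rm = TRUE)) stop("distance must be >= 0")
  if (is.null(bounds)) {
    bounds <- if (scheme == "dc") c(1.5, 3.5, 5.0) else c(1.5, 3.0)
  }
  labels <- if (length(bounds) == 3L) {
    c("close", "near", "short-distance separated", "long-distance separated")
  } else if (length(bounds) == 2L) {
    c("close", "near", "far")
  } else {
    paste0("cat", seq_len(length(bounds) + 1L))
  }
  cut(distance, breaks = c(0, bounds, Inf), labels = labels,
      right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
}

#' Is a single frame fractured?
#'
#' A frame counts as fractured when the inter-centriole distance reaches the
#' threshold (inclusive: 1.5 um itself is fractured, consistent with the
#' category boundary placing 1.5 um in "near").
#'
#' @param distance micrometers, >= 0.
#' @param threshold micrometers (default 1.5).
#' @return logical, vectorized over `distance`.
#' @export
is_fractured_frame <- function(distance, threshold = 1.5) {
  if (any(distance < 0, na.rm = TRUE)) stop("distance must be >= 0")
  distance >= threshold
}

#' Cell-level fracture call
#'
#' A cell has a fractured centrosome when its centrioles are at least
#' `threshold` apart for at least `min_timepoints` time points — any frames,
#' not necessarily consecutive.
#'
#' @param distance distance series, micrometers (may be empty; `NA` frames
#'   are ignored).
#' @param threshold micrometers.
#' @param min_timepoints required fractured frames (default 2).
#' @return logical scalar.
#' @export
cell_fractured <- function(distance, threshold = 1.5, min_timepoints = 2L) {
  distance <- distance[!is.na(distance)]
  if (length(distance) == 0L) return(FALSE)
  sum(is_fractured_frame(distance, threshold)) >= min_timepoints
}

#' Breakage frequency of a cohort
#'
#' @param reports list of `fracture_report` objects (or of logical fracture
#'   flags).
#' @return fraction of fractured cells, in [0, 1].
#' @export
breakage_frequency <- function(reports) {
  if (length(reports) == 0L) stop("empty cohort")
  flags <- vapply(reports, function(r) {
    if (inherits(r, "fracture_report")) r$fractured else as.logical(r)
  }, TRUE)
  mean(flags)
}

#' Maximal observed separation
#'
#' @param distance nonempty distance series, micrometers.
#' @return maximum distance, micrometers.
#' @export
max_separation <- function(distance) {
  distance <- distance[!is.na(distance)]
  if (length(distance) == 0L) stop("empty distance series")
  max(distance)
}

#' Separation velocity after fracture onset
#'
#' Onset is the first frame at or above the fracture threshold; the velocity
#' is the maximum, over sliding windows of `window` consecutive observations
#' starting at or after onset, of the distance change divided by the elapsed
#' time, reported in micrometers per minute.
#'
#' @param series data.frame with `time` (seconds) and `distance` (um), as
#'   from [distance_series()].
#' @param threshold micrometers.
#' @param window observations per sliding window (default 3).
#' @return list with `velocity` (um/min) and `onset_index`/`onset_time`.
#' @export
separation_velocity <- function(series, threshold = 1.5, window = 3L) {
  d <- series$distance; t_s <- series$time
  on <- which(is_fractured_frame(d, threshold))[1]
  if (is.na(on)) stop("series never reaches the fracture threshold")
  i0 <- max(1L, on - 1L)  # include the crossing step itself
  idx <- i0:length(d)
  if (length(idx) < 2L) stop("too few observations after onset")
  w <- min(window, length(idx))
  v <- -Inf
  for (s in seq_len(length(idx) - w + 1L)) {
    i <- idx[s]; j <- idx[s + w - 1L]
    dt_min <- (t_s[j] - t_s[i]) / 60
    if (dt_min > 0) v <- max(v, (d[j] - d[i]) / dt_min)
  }
  list(velocity = v, onset_index = on, onset_time = t_s[on])
}

#' Repair outcome of a fractured cell
#'
#' `"repaired"` when the distance falls back below the threshold after onset
#' and stays below for at least `rejoin_frames` observations before the series
#' ends; `"non-repaired"` when it remains at or above the threshold through
#' the end; `"censored"` when the series ends within `rejoin_frames` of a
#' re-crossing, so sustained re-cohesion cannot be judged.
#'
#' @param series data.frame with `time` and `distance`.
#' @param threshold micrometers.
#' @param rejoin_frames observations of sustained re-cohesion required
#'   (default 3).
#' @return `"repaired"`, `"non-repaired"` or `"censored"`.
#' @export
repair_outcome <- function(series, threshold = 1.5, rejoin_frames = 3L) {
  d <- series$distance
  on <- which(is_fractured_frame(d, threshold))[1]
  if (is.na(on)) stop("series never reaches the fracture threshold")
  after <- d[on:length(d)]
  below <- after < threshold
  if (!any(below)) return("non-repaired")
  # runs of consecutive below-threshold observations after onset
  r <- rle(below)
  ends <- cumsum(r$lengths)
  for (k in seq_along(r$lengths)) {
    if (r$values[k] && r$lengths[k] >= rejoin_frames) return("repaired")
  }
  # some re-crossing happened but no sustained run: if the last run is a short
  # below-threshold run ending the series, the outcome is censored
  last <- length(r$values)
  if (r$values[last] && r$lengths[last] < rejoin_frames) return("censored")
  "non-repaired"
}

#' Full fracture report for one cell
#'
#' Combines the per-frame categories, cell-level call, onset, separation
#' velocity, maximal separation and repair outcome into one container.
#'
#' @param series data.frame with `time` (s) and `distance` (um).
#' @param config an [analysis_config()].
#' @param scheme category scheme, `"dc"` or `"fibroblast"`.
#' @param cell_id optional identifier carried into exports.
#' @return an object of class `fracture_report`.
#' @export
fracture_report <- function(series, config = analysis_config(),
                            scheme = "dc", cell_id = NA) {
  thr <- config$fracture_threshold
  bounds <- if (scheme == "dc") config$dc_category_bounds
            else config$fibroblast_category_bounds
  frac <- cell_fractured(series$distance, thr, config$min_fractured_timepoints)
  onset <- velocity <- NA_real_
  outcome <- NA_character_
  if (frac) {
    sv <- separation_velocity(series, thr, config$velocity_window)
    onset <- sv$onset_time
    velocity <- sv$velocity
    outcome <- repair_outcome(series, thr, config$rejoin_frames)
  }
  structure(list(
    cell_id = cell_id,
    series = series,
    categories = classify_frame(series$distance, scheme, bounds),
    fractured = frac,
    onset_time = onset,
    separation_velocity = velocity,
    max_separation = if (nrow(series)) max_separation(series$distance)
                     else NA_real_,
    repair = outcome,
    scheme = scheme
  ), class = "fracture_report")
}

#' @export
print.fracture_report <- function(x, ...) {
  cat(sprintf("fracture_report (cell %s, %s scheme): %s\n",
              format(x$cell_id), x$scheme,
              if (isTRUE(x$fractured)) "FRACTURED" else "intact"))
  cat(sprintf("  max separation %.2f um", x$max_separation))
  if (isTRUE(x$fractured)) {
    cat(sprintf("; onset %.0f s; separation velocity %.2f um/min; %s",
                x$onset_time, x$separation_velocity, x$repair))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.fracture_report <- function(object, ...) {
  data.frame(
    cell_id = object$cell_id,
    fractured = object$fractured,
    onset_time = object$onset_time,
    separation_velocity = object$separation_velocity,
    max_separation = object$max_separation,
    repair = ifelse(is.na(object$repair), NA, object$repair),
    stringsAsFactors = FALSE
  )
}

# even-odd ray-casting point-in-polygon test
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Junction decision time of a cell track
#'
#' The decision clock starts when the cell reference point (nucleus centroid
#' when available, else the centriole-pair midpoint) first enters the junction
#' polygon and stops at the first frame after which the point has permanently
#' left it; a track that exits and re-enters keeps the clock running until the
#' final exit. Frames are labeled `before`/`during`/`after` accordingly.
#'
#' @param track data.frame with `time` (seconds) and reference-point `x`, `y`
#'   (micrometers).
#' @param junction polygon vertex matrix (columns x, y, micrometers).
#' @return list with `decision_time` (minutes), `phase` (factor per frame)
#'   and the entry/exit times in seconds.
#' @export
decision_time <- function(track, junction) {
  junction <- as.matrix(junction)
  inside <- point_in_polygon(track$x, track$y, junction)
  if (!any(inside)) stop("track never enters the junction")
  first_in <- which(inside)[1]
  last_in <- which(inside)[length(which(inside))]
  phase <- rep("after", nrow(track))
  phase[seq_len(nrow(track)) < first_in] <- "before"
  phase[seq(first_in, last_in)] <- "during"
  exit_idx <- last_in + 1L
  if (exit_idx > nrow(track)) {
    # still inside at the end of the recording
    return(list(decision_time = NA_real_,
                phase = factor(phase, c("before", "during", "after")),
                entry_time = track$time[first_in], exit_time = NA_real_))
  }
  list(
    decision_time = (track$time[exit_idx] - track$time[first_in]) / 60,
    phase = factor(phase, c("before", "during", "after")),
    entry_time = track$time[first_in],
    exit_time = track$time[exit_idx]
  )
}
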