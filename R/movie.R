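#' Calibrated multi-channel time-lapse movie
#'
#' The universal input container of the pipeline: one or more channels of
#' identical shape, each a `time x height x width` array of nonnegative
#' intensities in arbitrary detector units, plus the physical calibration
#' needed to convert pixels to micrometers and frames to seconds.
#'
#' Coordinates follow the package-wide convention: pixel `(row, col)` (1-based
#' array indices) maps to physical position `x = (col - 1) * pixel_size`,
#' `y = (row - 1) * pixel_size`, both in micrometers. All distances reported by
#' the pipeline are in micrometers.
#'
#' @param channels named list of numeric 3D arrays (`time x height x width`),
#'   one per channel role (e.g. `"centriole"`, `"nucleus"`, `"polarity"`).
#'   Channel roles are explicit labels, never inferred from page order.
#' @param pixel_size micrometers per pixel (> 0).
#' @param frame_interval seconds between consecutive frames (> 0).
#' @param source_direction direction of the chemokine source along the image
#'   y axis: `"+y"` (increasing row index, the default) or `"-y"`.
#' @return an object of class `calibrated_movie`.
#' @export
calibrated_movie <- function(channels, pixel_size, frame_interval,
                             source_direction = "+y") {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("'channels' must be a non-empty named list of 3D arrays")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) {
    stop("every channel must be a 3D array (time x height x width)")
  }
  if (length(unique(lapply(dims, identity))) != 1L) {
    stop("all channel arrays must share an identical shape")
  }
  for (ch in names(channels)) {
    if (any(channels[[ch]] < 0, na.rm = TRUE)) {
      stop("channel '", ch, "' contains negative intensities")
    }
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("'pixel_size' must be a single positive number (micrometers/pixel)")
  }
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      frame_interval <= 0) {
    stop("'frame_interval' must be a single positive number (seconds)")
  }
  source_direction <- match.arg(source_direction, c("+y", "-y"))
  structure(
    list(
      frames = dims[[1L]][1L],
      height = dims[[1L]][2L],
      width = dims[[1L]][3L],
      channels = channels,
      pixel_size = pixel_size,
      frame_interval = frame_interval,
      source_direction = source_direction
    ),
    class = "calibrated_movie"
  )
}

#' @export
print.calibrated_movie <- function(x, ...) {
  cat(sprintf(
    "calibrated_movie: %d frame(s), %d x %d px, %d channel(s) [%s]\n",
    x$frames, x$height, x$width, length(x$channels),
    paste(names(x$channels), collapse = ", ")
  ))
  cat(sprintf(
    "  pixel size %.4f um/px, frame interval %g s, source along %s\n",
    x$pixel_size, x$frame_interval, x$source_direction
  ))
  invisible(x)
}

#' Extract one frame of one channel
#'
#' @param movie a `calibrated_movie`.
#' @param channel channel role label.
#' @param frame 1-based frame index.
#' @return a `height x width` numeric matrix.
#' @export
get_frame <- function(movie, channel, frame) {
  stopifnot(inherits(movie, "calibrated_movie"))
  if (!channel %in% names(movie$channels)) {
    stop("movie has no channel with role '", channel, "'")
  }
  if (frame < 1L || frame > movie$frames) stop("frame index out of range")
  movie$channels[[channel]][frame, , , drop = TRUE]
}

#' Load a multi-page TIFF as a calibrated movie
#'
#' Pages are de-interleaved by the stated channel order: page `k` belongs to
#' channel `((k - 1) mod n_channels) + 1` of frame `floor((k - 1)/n_channels) + 1`,
#' i.e. channels cycle fastest, the usual export layout of time-lapse stacks.
#' Intensities are read as stored (`as.is`), never rescaled.
#'
#' @param path a readable multi-page TIFF file.
#' @param pixel_size micrometers per pixel.
#' @param frame_interval seconds per frame.
#' @param channel_roles character vector of channel role labels, in page order.
#' @param source_direction `"+y"` or `"-y"`, see [calibrated_movie()].
#' @return a `calibrated_movie`.
#' @export
load_movie <- function(path, pixel_size, frame_interval, channel_roles,
                       source_direction = "+y") {
  if (!file.exists(path)) stop("cannot read movie file: ", path)
  if (length(channel_roles) < 1L) stop("need at least one channel role")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) == 0L) stop("TIFF contains no pages: ", path)
  nch <- length(channel_roles)
  if (length(pages) %% nch != 0L) {
    stop(sprintf("page count (%d) is not divisible by channel count (%d)",
                 length(pages), nch))
  }
  nfr <- length(pages) %/% nch
  h <- nrow(pages[[1L]]); w <- ncol(pages[[1L]])
  channels <- stats::setNames(vector("list", nch), channel_roles)
  for (ci in seq_len(nch)) {
    arr <- array(0, dim = c(nfr, h, w))
    for (ti in seq_len(nfr)) {
      pg <- pages[[(ti - 1L) * nch + ci]]
      if (length(dim(pg)) == 3L) pg <- pg[, , 1L]  # collapse spurious samples
      arr[ti, , ] <- pg
    }
    channels[[ci]] <- arr
  }
  calibrated_movie(channels, pixel_size, frame_interval, source_direction)
}

#' Write a calibrated movie as a channel-interleaved 16-bit TIFF
#'
#' Intensities are rounded to integers and must fit in 16 bits; this is the
#' lossless counterpart of [load_movie()] for the integer-valued movies the
#' synthetic generator produces.
#'
#' @param movie a `calibrated_movie`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "calibrated_movie"))
  mx <- max(vapply(movie$channels, max, 0))
  if (mx > 65535) stop("intensities exceed 16-bit range; rescale before writing")
  pages <- vector("list", movie$frames * length(movie$channels))
  k <- 1L
  for (ti in seq_len(movie$frames)) {
    for (ch in names(movie$channels)) {
      pages[[k]] <- round(movie$channels[[ch]][ti, , ]) / 65535
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}
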