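#' Euclidean distance map to the nearest vessel pixel
#'
#' Exact Euclidean distance transform of the complement of the vessel mask,
#' scaled to micrometers: every pixel's distance to the nearest vessel pixel,
#' zero exactly on the vessel.
#'
#' @param mask logical or 0/1 matrix marking vessel pixels.
#' @param pixel_size micrometers per pixel.
#' @return numeric matrix of distances in micrometers.
#' @export
vessel_distance_map <- function(mask, pixel_size = 1) {
  mask <- mask != 0
  if (!any(mask)) stop("vessel mask is empty")
  inv <- matrix(as.numeric(!mask), nrow(mask), ncol(mask))
  dm <- EBImage::imageData(EBImage::distmap(inv, metric = "euclidean"))
  dm * pixel_size
}

#' Cell-to-vessel proximity statistics
#'
#' Looks up the nearest-vessel distance at each cell centroid's pixel and
#' labels the cell inside or outside the vessel. With `per_pixel = TRUE` a
#' cell mask is analyzed instead: the distance distribution over all marked
#' pixels is reported, matching a per-pixel supra-threshold analysis.
#'
#' @param cells matrix of cell centroid positions (columns x, y, micrometers),
#'   or — with `per_pixel = TRUE` — a logical matrix of supra-threshold cell
#'   pixels.
#' @param vessel_mask logical or 0/1 vessel mask.
#' @param pixel_size micrometers per pixel.
#' @param per_pixel treat `cells` as a pixel mask.
#' @return a `vessel_distance_result`: list with `distance` (per cell or per
#'   pixel, micrometers), `inside` (logical), `n_inside`, `n_outside` and the
#'   `distance_map`.
#' @export
cell_vessel_stats <- function(cells, vessel_mask, pixel_size = 1,
                              per_pixel = FALSE) {
  dm <- vessel_distance_map(vessel_mask, pixel_size)
  vm <- vessel_mask != 0
  h <- nrow(dm); w <- ncol(dm)
  if (per_pixel) {
    if (!any(cells != 0)) stop("no cell detections")
    sel <- which(cells != 0)
    dist <- dm[sel]
    inside <- vm[sel]
  } else {
    cells <- matrix(as.numeric(cells), ncol = 2,
                    dimnames = list(NULL, c("x", "y")))
    if (nrow(cells) == 0L) stop("no cell detections")
    rows <- round(cells[, 2] / pixel_size) + 1
    cols <- round(cells[, 1] / pixel_size) + 1
    if (any(rows < 1 | rows > h | cols < 1 | cols > w)) {
      stop("cell detection outside the image bounds")
    }
    dist <- dm[cbind(rows, cols)]
    inside <- vm[cbind(rows, cols)]
  }
  structure(list(
    distance = dist,
    inside = inside,
    n_inside = sum(inside),
    n_outside = sum(!inside),
    distance_map = dm
  ), class = "vessel_distance_result")
}

#' @export
print.vessel_distance_result <- function(x, ...) {
  cat(sprintf(
    "vessel_distance_result: %d cell(s)/pixel(s); %d inside, %d outside\n",
    length(x$distance), x$n_inside, x$n_outside))
  out <- x$distance[!x$inside]
  if (length(out)) {
    cat(sprintf("  outside distances: median %.2f um (range %.2f - %.2f)\n",
                stats::median(out), min(out), max(out)))
  }
  invisible(x)
}

#' Otsu threshold helper for mask construction
#'
#' Convenience wrapper returning a binary mask at Otsu's threshold; mask
#' construction itself is an input to the analyses, not part of their
#' contract.
#'
#' @param image 2D intensity matrix.
#' @return logical matrix.
#' @export
otsu_mask <- function(image) {
  rng <- range(image)
  if (diff(rng) == 0) stop("constant image has no threshold")
  scaled <- (image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(scaled))
  image > rng[1] + thr * diff(rng)
}
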