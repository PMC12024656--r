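# brute-force nearest-vessel-pixel distance, micrometers
brute_force_distance_map <- function(mask, pixel_size = 1) {
  vp <- which(mask != 0, arr.ind = TRUE)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      out[r, c] <- sqrt(min((vp[, 1] - r)^2 + (vp[, 2] - c)^2))
    }
  }
  out * pixel_size
}

# brute-force 8-connected component labeling by flood fill
brute_force_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# translate + rotate spot coordinates about a pivot (for invariance checks)
transform_spots <- function(spots, angle = 0, shift = c(0, 0),
                            pivot = c(0, 0)) {
  co <- cos(angle); si <- sin(angle)
  x <- spots$x - pivot[1]; y <- spots$y - pivot[2]
  spots$x <- pivot[1] + co * x - si * y + shift[1]
  spots$y <- pivot[2] + si * x + co * y + shift[2]
  spots
}
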