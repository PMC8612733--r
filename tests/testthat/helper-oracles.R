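# Independent oracles used across the suite. Deliberately written as slow,
# explicit loops so they share no code with the implementation.

# 8-connected component labeling by breadth-first search.
bfs_label <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (bin[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(i, j))
      lab[i, j] <- nxt
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          r <- p[1] + dr; c <- p[2] + dc
          if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
              bin[r, c] && lab[r, c] == 0L) {
            lab[r, c] <- nxt
            queue <- c(queue, list(c(r, c)))
          }
        }
      }
    }
  }
  lab
}

# Pixels of a disk of given radius around a (row, col) center, by brute force.
disk_pixels <- function(shape, center, radius) {
  out <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) {
    if ((i - center[1])^2 + (j - center[2])^2 <= radius^2) out[i, j] <- TRUE
  }
  out
}

# A frame with k hard-edged puncta of the given radius laid out on a grid,
# used where a deterministic punctum count is needed.
frame_with_puncta <- function(k, shape = c(96L, 96L), radius = 2,
                              I_dense = 100, I_dilute = 10) {
  px <- matrix(I_dilute, shape[1], shape[2])
  per_row <- floor((shape[2] - 8) / 12)
  for (i in seq_len(k)) {
    r0 <- 8 + 12 * ((i - 1) %/% per_row)
    c0 <- 8 + 12 * ((i - 1) %% per_row)
    stopifnot(r0 + radius < shape[1])
    px[disk_pixels(shape, c(r0, c0), radius)] <- I_dense
  }
  image2d(px)
}
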