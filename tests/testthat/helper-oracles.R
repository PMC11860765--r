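# Brute-force oracles, deliberately implemented with different algorithms
# than the package internals they cross-check.

# Depth-first flood fill with an explicit stack, one pixel at a time.
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- if (connectivity == 8) {
    expand.grid(dr = -1:1, dc = -1:1)
  } else {
    data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) { # column-major scan
    if (mask[r0, c0] > 0 && lab[r0, c0] == 0L) {
      cur <- cur + 1L
      stack <- list(c(r0, c0))
      lab[r0, c0] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (k in seq_len(nrow(offs))) {
          r <- p[1] + offs$dr[k]; c <- p[2] + offs$dc[k]
          if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
              mask[r, c] > 0 && lab[r, c] == 0L) {
            lab[r, c] <- cur
            stack[[length(stack) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  lab
}

# Per-pixel sort-and-average median of a list of patches.
oracle_median_patch <- function(patches) {
  d <- dim(patches[[1]])
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v <- sort(vapply(patches, function(p) p[i, j], numeric(1)))
    n <- length(v)
    out[i, j] <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  out
}

# Sorted-middle median of a vector (explicit order statistics).
oracle_median <- function(v) {
  v <- sort(v); n <- length(v)
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

# Minimal stand-in nucleus records for QC/selection tests.
stub_record <- function(id, area_px = 100, edge = FALSE) {
  list(nucleus_id = id, projected_area_px = area_px, touches_edge = edge,
       channels = list(), voxel_size = c(0.1, 0.1, 0.71))
}
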