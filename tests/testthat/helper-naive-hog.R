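# Independent brute-force HOG reference.  Works directly on a grayscale
# matrix with explicit per-pixel loops: [-1, 0, 1] gradients with edge
# replication, unsigned orientations in [0, 180) with linear interpolation
# between bin centers at (b + 0.5) * 180/bins, magnitude-weighted votes,
# floor-division cell tiling, overlapping blocks (row-major scan, cells
# row-major within a block) normalized by v / sqrt(sum(v^2) + eps^2).
naive_hog <- function(g, config) {
  cs <- config$cell_size
  bins <- config$orientation_bins
  bc <- config$block_cells
  stride <- config$block_stride
  nc <- nrow_cells <- config$resize_to %/% cs
  region <- nc * cs
  H <- region; W <- region

  hist <- array(0, dim = c(bins, nc, nc))  # bins x cell_y x cell_x
  bw <- 180 / bins
  for (r in seq_len(H)) {
    for (cc in seq_len(W)) {
      rp <- min(r + 1, H); rm <- max(r - 1, 1)
      cp <- min(cc + 1, W); cm <- max(cc - 1, 1)
      gx <- g[r, cp] - g[r, cm]
      gy <- g[rp, cc] - g[rm, cc]
      m <- sqrt(gx^2 + gy^2)
      a <- (atan2(gy, gx) * 180 / pi) %% 180
      pos <- a / bw - 0.5
      lo <- floor(pos)
      whi <- pos - lo
      b_lo <- (lo %% bins) + 1
      b_hi <- (b_lo %% bins) + 1
      cy <- (r - 1) %/% cs + 1
      cx <- (cc - 1) %/% cs + 1
      hist[b_lo, cy, cx] <- hist[b_lo, cy, cx] + m * (1 - whi)
      hist[b_hi, cy, cx] <- hist[b_hi, cy, cx] + m * whi
    }
  }

  nb <- (nc - bc) %/% stride + 1
  out <- c()
  for (by in seq_len(nb)) {
    for (bx in seq_len(nb)) {
      v <- c()
      for (dy in seq_len(bc)) {
        for (dx in seq_len(bc)) {
          v <- c(v, hist[, (by - 1) * stride + dy, (bx - 1) * stride + dx])
        }
      }
      out <- c(out, v / sqrt(sum(v^2) + config$block_norm_eps^2))
    }
  }
  out
}
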