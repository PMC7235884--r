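#' HOG descriptor configuration
#'
#' Geometry of the histogram-of-oriented-gradients descriptor used by the
#' classical baselines: images are resized to `resize_to` pixels per side,
#' tiled into `cell_size` cells (floor division; trailing pixels beyond
#' the last whole cell are excluded), and described by unsigned (0-180
#' degree) orientation histograms normalized over overlapping blocks of
#' `block_cells x block_cells` cells at a stride of `block_stride` cells.
#' With the defaults (200 px, 32 px cells, 2x2 blocks, stride 1, 9 bins)
#' there are 6x6 cells, 5x5 block positions and the descriptor length is
#' `5 * 5 * 4 * 9 = 900`.
#'
#' @param resize_to resized side length in pixels (default 200).
#' @param cell_size cell side in pixels (default 32).
#' @param block_cells cells per block side (default 2).
#' @param block_stride block stride in cells (default 1).
#' @param orientation_bins unsigned orientation bins over 0-180 degrees
#'   (default 9).
#' @param block_norm_eps epsilon of the L2 block normalization
#'   `v / sqrt(sum(v^2) + eps^2)` (default 1e-6).
#' @return An object of class `hog_config`.
#' @export
hog_config <- function(resize_to = 200L, cell_size = 32L, block_cells = 2L,
                       block_stride = 1L, orientation_bins = 9L,
                       block_norm_eps = 1e-6) {
  check_scalar_num(resize_to, "resize_to", lower = 2, integer = TRUE)
  check_scalar_num(cell_size, "cell_size", lower = 1, integer = TRUE)
  check_scalar_num(block_cells, "block_cells", lower = 1, integer = TRUE)
  check_scalar_num(block_stride, "block_stride", lower = 1, integer = TRUE)
  check_scalar_num(orientation_bins, "orientation_bins", lower = 1,
                   integer = TRUE)
  check_scalar_num(block_norm_eps, "block_norm_eps", lower = 0)
  cfg <- structure(list(resize_to = as.integer(resize_to),
                        cell_size = as.integer(cell_size),
                        block_cells = as.integer(block_cells),
                        block_stride = as.integer(block_stride),
                        orientation_bins = as.integer(orientation_bins),
                        block_norm_eps = block_norm_eps),
                   class = "hog_config")
  if (hog_cells_per_axis(cfg) < cfg$block_cells)
    stop_config("cell_size",
                "leaves fewer whole cells than one block requires")
  cfg
}

hog_cells_per_axis <- function(config) config$resize_to %/% config$cell_size

hog_blocks_per_axis <- function(config) {
  nc <- hog_cells_per_axis(config)
  (nc - config$block_cells) %/% config$block_stride + 1L
}

#' Descriptor length implied by a HOG configuration
#'
#' @param config a [hog_config()].
#' @return `blocks^2 * cells_per_block * orientation_bins`.
#' @export
hog_length <- function(config = hog_config()) {
  nb <- hog_blocks_per_axis(config)
  nb * nb * config$block_cells^2 * config$orientation_bins
}

#' Convert an 8-bit color image to 8-bit grayscale
#'
#' ITU-R BT.601 luma, `0.299 R + 0.587 G + 0.114 B`, rounded half up so
#' the operation is bit-exact across platforms.
#'
#' @param image `H x W x 3` 8-bit array.
#' @return `H x W` integer-valued matrix in `[0, 255]`.
#' @export
to_grayscale <- function(image) {
  check_rgb_array(image)
  check_uint8(image)
  y <- luma(image)
  floor(y + 0.5)  # round half up
}

# Cell orientation histograms of a grayscale matrix (already resized).
# [-1, 0, 1] central-difference gradients with edge replication; unsigned
# orientation in [0, 180) split into `bins` with linear interpolation
# between the two nearest bin centers (centers at (b + 0.5) * 180/bins,
# circular wrap); votes weighted by gradient magnitude.
# Returns an array (bins, cells_y, cells_x).
cell_histograms <- function(g, config) {
  nc <- hog_cells_per_axis(config)
  cs <- config$cell_size
  bins <- config$orientation_bins
  region <- nc * cs
  g <- g[seq_len(region), seq_len(region), drop = FALSE]
  H <- nrow(g); W <- ncol(g)

  gx <- g[, c(2:W, W)] - g[, c(1, 1:(W - 1))]
  gy <- g[c(2:H, H), ] - g[c(1, 1:(H - 1)), ]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180

  bw <- 180 / bins
  pos <- ang / bw - 0.5             # distance in bins from first center
  lo <- floor(pos)
  w_hi <- pos - lo
  bin_lo <- (as.integer(lo) %% bins)
  bin_hi <- (bin_lo + 1L) %% bins

  rows <- row(g); cols <- col(g)
  cell_y <- (rows - 1L) %/% cs
  cell_x <- (cols - 1L) %/% cs
  cell_id <- cell_y + nc * cell_x    # 0-based, column-major cells

  idx_lo <- bin_lo + bins * cell_id
  idx_hi <- bin_hi + bins * cell_id
  nbin <- bins * nc * nc
  hist <- numeric(nbin)
  acc_lo <- rowsum(c(mag * (1 - w_hi)), group = c(idx_lo))
  acc_hi <- rowsum(c(mag * w_hi), group = c(idx_hi))
  hist[as.integer(rownames(acc_lo)) + 1L] <-
    hist[as.integer(rownames(acc_lo)) + 1L] + acc_lo[, 1]
  hist[as.integer(rownames(acc_hi)) + 1L] <-
    hist[as.integer(rownames(acc_hi)) + 1L] + acc_hi[, 1]
  array(hist, dim = c(bins, nc, nc))
}

#' Histogram-of-oriented-gradients descriptor
#'
#' Resizes the image to `resize_to` pixels per side (bilinear), converts
#' to grayscale, computes central-difference gradients, accumulates
#' magnitude-weighted unsigned orientation histograms per cell with linear
#' bin interpolation, and concatenates L2-normalized overlapping blocks.
#' Block positions are scanned row-major (y fastest within the
#' concatenation: blocks by row, then within each block cells by row, then
#' bins); the layout is fixed so descriptors are comparable across calls.
#'
#' @param image `H x W x 3` 8-bit color image of any size.
#' @param config a [hog_config()].
#' @return Numeric vector of length [hog_length()] (900 under defaults).
#' @examples
#' img <- array(sample(0:255, 64 * 64 * 3, replace = TRUE),
#'              dim = c(64, 64, 3))
#' length(hog_descriptor(img))
#' @export
hog_descriptor <- function(image, config = hog_config()) {
  check_rgb_array(image)
  s <- config$resize_to
  d <- dim(image)
  img <- if (d[1] == s && d[2] == s) image else
    array(pmin(255, pmax(0, round(as.array(
      EBImage::resize(image, w = s, h = s))))), dim = c(s, s, 3L))
  g <- to_grayscale(img)
  ch <- cell_histograms(g, config)
  bins <- config$orientation_bins
  bc <- config$block_cells
  nb <- hog_blocks_per_axis(config)
  stride <- config$block_stride
  eps2 <- config$block_norm_eps^2

  out <- numeric(hog_length(config))
  k <- 0L
  blocklen <- bc * bc * bins
  for (by in seq_len(nb)) {            # block rows (y) outer
    for (bx in seq_len(nb)) {
      cy <- (by - 1L) * stride
      cx <- (bx - 1L) * stride
      v <- numeric(blocklen)
      j <- 0L
      for (dy in seq_len(bc)) {        # cells within block, row-major
        for (dx in seq_len(bc)) {
          v[j + seq_len(bins)] <- ch[, cy + dy, cx + dx]
          j <- j + bins
        }
      }
      out[k + seq_len(blocklen)] <- v / sqrt(sum(v^2) + eps2)
      k <- k + blocklen
    }
  }
  out
}

#' HOG feature matrix of an image set
#'
#' By default descriptors are computed on the original images (the
#' classical pipeline is independent of the network's equalization/Lab
#' chain); set `preprocessed = TRUE` to equalize first.
#'
#' @param dataset an [image_set].
#' @param config a [hog_config()].
#' @param preprocessed run histogram equalization before the descriptor.
#' @param plan a [preprocess_plan()] (used only when `preprocessed`).
#' @return `n x hog_length(config)` matrix, rows in dataset order, columns
#'   named `h0 ... h899` under defaults.
#' @export
hog_features <- function(dataset, config = hog_config(),
                         preprocessed = FALSE,
                         plan = preprocess_plan()) {
  stopifnot(inherits(dataset, "image_set"))
  n <- length(dataset)
  m <- matrix(0, nrow = n, ncol = hog_length(config))
  for (i in seq_len(n)) {
    img <- dataset$images[[i]]
    if (preprocessed) img <- equalize_histogram(img,
                                                plan$equalization_mode)
    m[i, ] <- hog_descriptor(img, config)
  }
  if (any(!is.finite(m)))
    stop("non-finite HOG feature encountered", call. = FALSE)
  rownames(m) <- dataset$ids
  colnames(m) <- paste0("h", seq_len(ncol(m)) - 1L)
  m
}
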