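#' Preprocessing plan
#'
#' Collects the switches of the image preprocessing chain applied before
#' network training: minority-class augmentation, histogram equalization,
#' sRGB to CIELAB conversion, and standardization to the network's
#' `64 x 64 x 3` input on the unit interval.  The chain order is fixed:
#' augment, then equalize, then convert color space, then resize/rescale.
#'
#' @param augment_minority_only if `TRUE` (default) only the class with the
#'   strictly smaller sample count is augmented; on balanced data nothing
#'   is augmented.  If `FALSE`, every sample is augmented.
#' @param include_originals keep the source image alongside its three
#'   derivatives (default `TRUE`, giving exactly 4 samples per source).
#' @param equalization_mode `"per_channel_rgb"` (default) equalizes each
#'   RGB channel independently; `"luminance_only"` equalizes the luma
#'   channel and rescales chroma proportionally.
#' @param target_size side length of the standardized input (default 64).
#' @param input_space `"lab"` (default) feeds the network CIELAB planes
#'   affinely mapped to `[0, 1]`; `"rgb"` feeds `value / 255`.  Both paths
#'   exist because training uses Lab while deployment-style scoring of raw
#'   RGB frames is also supported.
#' @return An object of class `preprocess_plan`.
#' @export
preprocess_plan <- function(augment_minority_only = TRUE,
                            include_originals = TRUE,
                            equalization_mode = c("per_channel_rgb",
                                                  "luminance_only"),
                            target_size = 64L,
                            input_space = c("lab", "rgb")) {
  equalization_mode <- match.arg(equalization_mode)
  input_space <- match.arg(input_space)
  check_scalar_num(target_size, "target_size", lower = 8, integer = TRUE)
  structure(list(augment_minority_only = isTRUE(augment_minority_only),
                 include_originals = isTRUE(include_originals),
                 equalization_mode = equalization_mode,
                 target_size = as.integer(target_size),
                 value_scale = "unit_interval",
                 input_space = input_space),
            class = "preprocess_plan")
}

#' Load a labeled image set from a HAM10000-dialect manifest
#'
#' Reads a CSV manifest with columns `image_id` and `dx`, keeps only the
#' keratosis rows (`dx == "akiec"`, mapped to label 1, and `dx == "bkl"`,
#' mapped to label 0), drops every other diagnosis code, and loads the
#' corresponding image files from `image_dir` (extensions `.png`, `.jpg`,
#' `.jpeg`, `.tif`, `.tiff` are searched in that order).  Sample order
#' follows manifest row order.
#'
#' @param manifest path to the metadata CSV.
#' @param image_dir directory holding the image files.
#' @return An [image_set].
#' @seealso [write_manifest()] for the inverse operation.
#' @export
load_manifest <- function(manifest, image_dir) {
  if (!file.exists(manifest))
    stop(sprintf("manifest '%s' does not exist", manifest), call. = FALSE)
  meta <- read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("image_id", "dx") %in% names(meta)))
    stop("manifest format error: columns 'image_id' and 'dx' are required",
         call. = FALSE)
  keep <- meta$dx %in% c("akiec", "bkl")
  meta <- meta[keep, , drop = FALSE]
  if (nrow(meta) == 0L)
    stop("no rows with dx in {akiec, bkl}: empty dataset", call. = FALSE)
  if (anyDuplicated(meta$image_id))
    stop("manifest contains duplicate image_id values", call. = FALSE)
  exts <- c(".png", ".jpg", ".jpeg", ".tif", ".tiff")
  images <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    paths <- file.path(image_dir, paste0(meta$image_id[i], exts))
    hit <- paths[file.exists(paths)]
    if (length(hit) == 0L)
      stop(sprintf("image file for image_id '%s' not found in '%s'",
                   meta$image_id[i], image_dir), call. = FALSE)
    images[[i]] <- read_image_file(hit[1])
  }
  image_set(images, as.integer(meta$dx == "akiec"), meta$image_id)
}

# --- geometric transforms (exact, index-permutation only) -----------------

rotate90 <- function(a)  # clockwise: out[i, j] = in[H + 1 - j, i]
  aperm(a[dim(a)[1]:1, , , drop = FALSE], c(2L, 1L, 3L))

hflip <- function(a) a[, dim(a)[2]:1, , drop = FALSE]

vflip <- function(a) a[dim(a)[1]:1, , , drop = FALSE]

#' Expand an image set by rotation and flips
#'
#' For every image selected for augmentation the output contains the
#' original plus its 90-degree rotation, horizontal flip and vertical flip
#' — four samples per source, so 327 minority images become 1308.  Labels
#' are inherited and derivative identifiers are suffixed `_rot90`,
#' `_hflip`, `_vflip`; `source_ids` records provenance so cross-validation
#' can keep derivatives of test images out of training folds.  Sources
#' appear in input order, each immediately followed by its derivatives.
#'
#' @param dataset a non-empty [image_set].
#' @param plan a [preprocess_plan()]; `augment_minority_only` chooses
#'   between expanding only the strictly smaller class (default; ties leave
#'   the set untouched) and expanding every sample, and
#'   `include_originals` controls whether sources are kept.
#' @return An [image_set].
#' @export
augment_set <- function(dataset, plan = preprocess_plan()) {
  if (!inherits(dataset, "image_set") || length(dataset) == 0L)
    stop("'dataset' must be a non-empty image_set", call. = FALSE)
  n_pos <- sum(dataset$labels == 1L)
  n_neg <- length(dataset) - n_pos
  selected <- if (!plan$augment_minority_only) {
    rep(TRUE, length(dataset))
  } else if (n_pos < n_neg) {
    dataset$labels == 1L
  } else if (n_neg < n_pos) {
    dataset$labels == 0L
  } else {
    rep(FALSE, length(dataset))  # balanced: no strict minority
  }

  images <- list(); labels <- integer(); ids <- character()
  src <- character()
  for (i in seq_along(dataset$ids)) {
    im <- dataset$images[[i]]
    id <- dataset$ids[i]
    if (!selected[i]) {
      images <- c(images, list(im)); labels <- c(labels, dataset$labels[i])
      ids <- c(ids, id); src <- c(src, dataset$source_ids[i])
      next
    }
    derived <- list(rot90 = rotate90(im), hflip = hflip(im),
                    vflip = vflip(im))
    if (plan$include_originals) {
      images <- c(images, list(im)); labels <- c(labels, dataset$labels[i])
      ids <- c(ids, id); src <- c(src, dataset$source_ids[i])
    }
    images <- c(images, unname(derived))
    labels <- c(labels, rep(dataset$labels[i], 3L))
    ids <- c(ids, paste0(id, "_", names(derived)))
    src <- c(src, rep(dataset$source_ids[i], 3L))
  }
  image_set(images, labels, ids, src)
}

# --- histogram equalization ----------------------------------------------

# Classic min-shifted CDF remapping of one 8-bit channel:
#   y = round(255 * (CDF(v) - CDF_min) / (N - CDF_min)),
# where CDF_min is the CDF mass of the lowest occupied bin.  Maps a linear
# ramp (uniform histogram) to itself; a constant channel is left unchanged.
equalize_channel <- function(v) {
  h <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(h)
  n <- length(v)
  cdf_min <- cdf[which(h > 0L)[1]]
  if (n == cdf_min) return(v)  # constant channel
  map <- round(255 * (cdf - cdf_min) / (n - cdf_min))
  map[map < 0] <- 0
  map[v + 1L]
}

luma <- function(img) 0.299 * img[, , 1] + 0.587 * img[, , 2] +
  0.114 * img[, , 3]

#' Histogram equalization of an 8-bit color image
#'
#' Standard cumulative-distribution equalization, used to emphasize the
#' texture of keratosis lesions before training.  In `per_channel_rgb`
#' mode each channel is remapped independently through its own CDF; in
#' `luminance_only` mode the luma channel is equalized and the RGB values
#' rescaled proportionally so chroma ratios are preserved.
#'
#' @param image `H x W x 3` array with integer values in `[0, 255]`.
#' @param mode `"per_channel_rgb"` or `"luminance_only"`.
#' @return An 8-bit image of the same shape.
#' @export
equalize_histogram <- function(image, mode = c("per_channel_rgb",
                                               "luminance_only")) {
  mode <- match.arg(mode)
  check_rgb_array(image)
  check_uint8(image)
  out <- image
  if (mode == "per_channel_rgb") {
    for (ch in 1:3)
      out[, , ch] <- equalize_channel(as.integer(image[, , ch]))
    dim(out) <- dim(image)
  } else {
    y <- luma(image)
    yr <- as.integer(round(y))
    yeq <- equalize_channel(yr)
    scale <- ifelse(y > 0, yeq / y, 0)
    for (ch in 1:3)
      out[, , ch] <- pmin(255, pmax(0, round(image[, , ch] * scale)))
  }
  out
}

# --- color space conversion ----------------------------------------------

#' Convert an 8-bit sRGB image to CIELAB
#'
#' D65 white point; `L` lies in `[0, 100]`, `a` and `b` in the
#' conventional CIELAB ranges (roughly `[-128, 127]`).  Values are real.
#'
#' @param image `H x W x 3` 8-bit sRGB array.
#' @return `H x W x 3` numeric array of L, a, b planes.
#' @seealso [lab_to_srgb()] for the inverse.
#' @export
rgb_to_lab <- function(image) {
  check_rgb_array(image)
  check_uint8(image)
  d <- dim(image)
  m <- matrix(as.vector(image) / 255, ncol = 3L)
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  array(lab, dim = d)
}

#' Convert a CIELAB image back to 8-bit sRGB
#'
#' @param image `H x W x 3` numeric CIELAB array (D65).
#' @return `H x W x 3` 8-bit sRGB array; out-of-gamut values are clipped.
#' @export
lab_to_srgb <- function(image) {
  check_rgb_array(image)
  d <- dim(image)
  m <- matrix(as.vector(image), ncol = 3L)
  srgb <- grDevices::convertColor(m, from = "Lab", to = "sRGB")
  array(pmin(255, pmax(0, round(srgb * 255))), dim = d)
}

# --- standardization ------------------------------------------------------

#' Standardize an image to the network input tensor
#'
#' Resizes to `target_size x target_size` with bilinear interpolation and
#' rescales each channel to `[0, 1]` by a fixed affine map: `v / 255` for
#' RGB input, and `L / 100`, `(a + 128) / 255`, `(b + 128) / 255` for
#' CIELAB input.
#'
#' @param image `H x W x 3` array (8-bit RGB or real-valued Lab).
#' @param plan a [preprocess_plan()] supplying `target_size`.
#' @param space `"rgb"` or `"lab"`, naming the color space of `image`.
#' @return Numeric `target_size x target_size x 3` array in `[0, 1]`.
#' @export
standardize_to_input <- function(image, plan = preprocess_plan(),
                                 space = c("rgb", "lab")) {
  space <- match.arg(space)
  check_rgb_array(image)
  s <- plan$target_size
  d <- dim(image)
  out <- if (d[1] == s && d[2] == s) image else
    as.array(EBImage::resize(image, w = s, h = s))
  if (space == "rgb") {
    out <- out / 255
  } else {
    out[, , 1] <- out[, , 1] / 100
    out[, , 2] <- (out[, , 2] + 128) / 255
    out[, , 3] <- (out[, , 3] + 128) / 255
  }
  array(pmin(1, pmax(0, out)), dim = c(s, s, 3L))
}

#' Run the full preprocessing chain over an image set
#'
#' Applies, in order: optional augmentation, histogram equalization,
#' optional CIELAB conversion, and standardization, returning the stacked
#' input tensor the network trains on.
#'
#' @param dataset an [image_set].
#' @param plan a [preprocess_plan()].
#' @param augment apply [augment_set()] first (training data only;
#'   default `FALSE`).
#' @return A list with elements `x` (`target x target x 3 x n` tensor in
#'   `[0, 1]`), `y` (integer labels) and `ids`.
#' @export
preprocess_set <- function(dataset, plan = preprocess_plan(),
                           augment = FALSE) {
  if (augment) dataset <- augment_set(dataset, plan)
  n <- length(dataset)
  s <- plan$target_size
  x <- array(0, dim = c(s, s, 3L, n))
  for (i in seq_len(n)) {
    im <- equalize_histogram(dataset$images[[i]], plan$equalization_mode)
    if (plan$input_space == "lab") {
      im <- rgb_to_lab(im)
      x[, , , i] <- standardize_to_input(im, plan, space = "lab")
    } else {
      x[, , , i] <- standardize_to_input(im, plan, space = "rgb")
    }
  }
  list(x = x, y = dataset$labels, ids = dataset$ids)
}
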