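#' Labeled dermoscopy image collections
#'
#' An `image_set` is the package's container for a labeled two-class image
#' dataset: an ordered collection of 8-bit RGB images with per-sample
#' identifiers and binary labels (1 = actinic keratosis, the positive class;
#' 0 = benign keratosis).  Every pipeline stage (augmentation, equalization,
#' color conversion, feature extraction, training) consumes and preserves
#' this structure.
#'
#' @param images list of `H x W x 3` numeric arrays with integer values in
#'   `[0, 255]`.
#' @param labels integer vector of 0/1 labels, one per image.
#' @param ids character vector of unique sample identifiers.
#' @param source_ids character vector tracking provenance: for original
#'   images this equals `ids`; for augmented derivatives it is the
#'   identifier of the source image.  Used to prevent train/test leakage of
#'   augmented copies in cross-validation.
#'
#' @return An object of class `image_set`: a list with elements `ids`,
#'   `images`, `labels`, `source_ids`.
#' @examples
#' img <- array(rep(128, 8 * 8 * 3), dim = c(8, 8, 3))
#' ds <- image_set(list(img), labels = 1L, ids = "sample_001")
#' length(ds)
#' @export
image_set <- function(images, labels, ids, source_ids = ids) {
  if (!is.list(images))
    stop("'images' must be a list of H x W x 3 arrays", call. = FALSE)
  n <- length(images)
  labels <- as.integer(labels)
  ids <- as.character(ids)
  source_ids <- as.character(source_ids)
  if (length(labels) != n || length(ids) != n || length(source_ids) != n)
    stop("images, labels and ids must have equal length", call. = FALSE)
  if (n > 0 && !all(labels %in% c(0L, 1L)))
    stop("labels must be 0 (benign) or 1 (actinic keratosis)", call. = FALSE)
  if (anyDuplicated(ids))
    stop("image ids must be unique", call. = FALSE)
  for (im in images) check_rgb_array(im)
  structure(list(ids = ids, images = images, labels = labels,
                 source_ids = source_ids),
            class = "image_set")
}

#' @export
length.image_set <- function(x) length(x$ids)

#' Subset an image set
#'
#' @param x an [image_set].
#' @param i index vector (integer or logical).
#' @param ... ignored.
#' @return An [image_set] with the selected samples, in index order.
#' @export
`[.image_set` <- function(x, i, ...) {
  idx <- seq_along(x$ids)[i]
  image_set(x$images[idx], x$labels[idx], x$ids[idx], x$source_ids[idx])
}

#' @export
print.image_set <- function(x, ...) {
  n <- length(x)
  dims <- if (n > 0) paste(dim(x$images[[1]])[1:2], collapse = "x") else "-"
  cat(sprintf(
    "<image_set> %d samples (%d AK, %d BK), first image %s px\n",
    n, sum(x$labels == 1L), sum(x$labels == 0L), dims))
  invisible(x)
}

# rbind-like concatenation preserving order.
c_image_sets <- function(...) {
  sets <- list(...)
  image_set(
    images = do.call(c, lapply(sets, `[[`, "images")),
    labels = do.call(c, lapply(sets, `[[`, "labels")),
    ids = do.call(c, lapply(sets, `[[`, "ids")),
    source_ids = do.call(c, lapply(sets, `[[`, "source_ids")))
}
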