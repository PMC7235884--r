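#' Configuration for the synthetic dermoscopy image generator
#'
#' Defines a seeded two-class image distribution that emulates the salient
#' structure of a keratosis dermoscopy dataset: a skin-toned background, an
#' elliptical lesion patch, band-limited texture, and pixel noise.  The two
#' classes differ in dominant texture frequency and in the hue of the
#' central patch, with the magnitude of both differences controlled by a
#' single `separation` parameter: at `separation = 0` the class-conditional
#' distributions are identical (no classifier can beat chance), at
#' `separation = 1` the classes are easily separable.
#'
#' @param n_per_class number of images generated per class (>= 1).
#' @param image_size side length in pixels of the square images (>= 16).
#'   Default 64, the network's native input size.
#' @param separation real in `[0, 1]`; scales the between-class difference
#'   in texture frequency and patch hue.
#' @param noise_sd standard deviation of additive Gaussian pixel noise, in
#'   8-bit intensity units (default 8).
#' @param seed integer seed.  Each image draws its parameters from a
#'   substream derived from `(seed, class, image counter)`, so enlarging
#'   `n_per_class` re-generates the existing images identically and only
#'   appends new ones.
#' @return An object of class `synth_config` (a validated list).
#' @seealso [generate_dataset()]
#' @export
synth_config <- function(n_per_class, image_size = 64L, separation = 0.5,
                         noise_sd = 8, seed = 1L) {
  check_scalar_num(n_per_class, "n_per_class", lower = 1, integer = TRUE)
  check_scalar_num(image_size, "image_size", lower = 16, integer = TRUE)
  check_scalar_num(separation, "separation", lower = 0, upper = 1)
  check_scalar_num(noise_sd, "noise_sd", lower = 0)
  check_scalar_num(seed, "seed", integer = TRUE)
  structure(list(n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size),
                 separation = separation, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Render one lesion-like image.  All randomness comes from the caller's
# RNG state (one substream per image).
render_lesion <- function(size, positive, separation, noise_sd) {
  s <- size
  # draws in fixed order so the image is a pure function of the substream
  base_shift <- runif(3, -12, 12)
  freq <- 2 + 8 * separation * positive + runif(1, -0.5, 0.5)
  theta <- runif(1, 0, pi)
  phase <- runif(1, 0, 2 * pi)
  amp <- runif(1, 15, 25)
  centre <- (0.5 + runif(2, -0.08, 0.08)) * s
  semi <- runif(2, 0.22, 0.38) * s
  rot <- runif(1, 0, pi)
  noise <- rnorm(s * s * 3, 0, noise_sd)

  xs <- (seq_len(s) - 0.5) / s   # columns
  ys <- (seq_len(s) - 0.5) / s   # rows
  # oriented sinusoidal texture; gradient energy scales with freq
  grating <- amp * sin(2 * pi * freq *
                         outer(ys * sin(theta), xs * cos(theta), "+") +
                       phase)

  # soft-edged rotated ellipse mask
  colg <- outer(rep(1, s), seq_len(s) - 0.5) - centre[1]
  rowg <- outer(seq_len(s) - 0.5, rep(1, s)) - centre[2]
  xr <- colg * cos(rot) + rowg * sin(rot)
  yr <- -colg * sin(rot) + rowg * cos(rot)
  d <- sqrt((xr / semi[1])^2 + (yr / semi[2])^2)
  mask <- pmin(1, pmax(0, (1.05 - d) * 8))

  skin <- c(195, 161, 145) + base_shift
  patch <- c(15, -5, -12) + positive * separation * c(35, -28, -18)

  img <- array(0, dim = c(s, s, 3))
  for (ch in 1:3)
    img[, , ch] <- skin[ch] + grating + patch[ch] * mask
  img <- img + array(noise, dim = c(s, s, 3))
  array(pmin(255, pmax(0, round(img))), dim = c(s, s, 3))
}

#' Generate a seeded synthetic two-class image dataset
#'
#' Draws `2 * n_per_class` lesion-like images (class 1 = AK-like, class 0 =
#' BK-like) from the distribution described in [synth_config()].  The
#' positive class carries higher-frequency texture and a redder central
#' patch, both in proportion to `separation`.  The function is a pure
#' function of its configuration: identical configurations yield
#' bit-identical pixel arrays.
#'
#' @param config a [synth_config()].
#' @return An [image_set] with `2 * n_per_class` samples ordered as all
#'   positives (`ak_00001`, ...) followed by all negatives (`bk_00001`,
#'   ...).
#' @examples
#' ds <- generate_dataset(synth_config(n_per_class = 5, seed = 7))
#' table(ds$labels)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synth_config"))
    config <- do.call(synth_config, as.list(config))
  n <- config$n_per_class
  images <- vector("list", 2L * n)
  labels <- integer(2L * n)
  ids <- character(2L * n)
  k <- 0L
  for (cls in c(1L, 0L)) {
    for (j in seq_len(n)) {
      k <- k + 1L
      images[[k]] <- with_seed(
        derive_seed(config$seed, cls * 1000000L + j),
        render_lesion(config$image_size, cls, config$separation,
                      config$noise_sd))
      labels[k] <- cls
      ids[k] <- sprintf("%s_%05d", if (cls == 1L) "ak" else "bk", j)
    }
  }
  image_set(images, labels, ids)
}

#' Write an image set to disk in the HAM10000 metadata dialect
#'
#' Writes one PNG per sample plus a `metadata.csv` manifest with header
#' `image_id,dx` (LF line endings, UTF-8), where `dx` is `akiec` for
#' positive samples and `bkl` for negatives — the layout produced by the
#' public HAM10000 archive and consumed by [load_manifest()].
#'
#' @param dataset a non-empty [image_set].
#' @param directory output directory; created (recursively) if absent.
#' @return The manifest path, invisibly usable with [load_manifest()].
#' @export
write_manifest <- function(dataset, directory) {
  if (!inherits(dataset, "image_set"))
    stop("'dataset' must be an image_set", call. = FALSE)
  if (length(dataset) == 0L)
    stop("refusing to write a manifest for an empty image set",
         call. = FALSE)
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", directory), call. = FALSE)
  if (file.access(directory, mode = 2L) != 0L)
    stop(sprintf("directory '%s' is not writable", directory),
         call. = FALSE)
  for (i in seq_along(dataset$ids))
    write_image_file(dataset$images[[i]],
                     file.path(directory,
                               paste0(dataset$ids[i], ".png")))
  manifest <- file.path(directory, "metadata.csv")
  dx <- ifelse(dataset$labels == 1L, "akiec", "bkl")
  con <- file(manifest, open = "wb")
  on.exit(close(con))
  writeLines(c("image_id,dx", paste(dataset$ids, dx, sep = ",")),
             con = con, sep = "\n", useBytes = TRUE)
  manifest
}

# --- raster I/O (EBImage stores arrays as width x height x channel) -------

write_image_file <- function(img, path) {
  check_rgb_array(img)
  ebi <- EBImage::Image(aperm(img, c(2L, 1L, 3L)) / 255,
                        colormode = "Color")
  EBImage::writeImage(ebi, path)
  invisible(path)
}

read_image_file <- function(path) {
  arr <- as.array(EBImage::readImage(path))
  d <- dim(arr)
  if (length(d) == 2L)
    stop(sprintf("'%s' is single-channel; 3-channel RGB input required",
                 path), call. = FALSE)
  if (d[3] == 4L) arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(arr)[3] != 3L)
    stop(sprintf("'%s' does not have 3 color channels", path),
         call. = FALSE)
  aperm(array(round(arr * 255), dim = dim(arr)), c(2L, 1L, 3L))
}
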