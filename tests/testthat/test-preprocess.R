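# --- manifest loading -----------------------------------------------------

write_tiny_manifest <- function(dir, rows) {
  writeLines(c("image_id,dx", rows), file.path(dir, "metadata.csv"))
  file.path(dir, "metadata.csv")
}

test_that("loader keeps only keratosis rows and maps dx to labels", {
  dir <- withr::local_tempdir()
  for (id in c("a1", "b1", "n1"))
    akdl:::write_image_file(rand_image(16, seed = match(id, c("a1", "b1", "n1"))),
                            file.path(dir, paste0(id, ".png")))
  mf <- write_tiny_manifest(dir, c("a1,akiec", "b1,bkl", "n1,nv"))
  ds <- load_manifest(mf, dir)
  expect_length(ds, 2)
  expect_identical(ds$ids, c("a1", "b1"))
  expect_identical(ds$labels, c(1L, 0L))
})

test_that("loader rejects malformed manifests", {
  dir <- withr::local_tempdir()
  akdl:::write_image_file(rand_image(16), file.path(dir, "a1.png"))
  expect_error(load_manifest(file.path(dir, "nope.csv"), dir),
               "does not exist")
  bad <- file.path(dir, "bad.csv")
  writeLines(c("image,diagnosis", "a1,akiec"), bad)
  expect_error(load_manifest(bad, dir), "image_id")
  dup <- write_tiny_manifest(dir, c("a1,akiec", "a1,bkl"))
  expect_error(load_manifest(dup, dir), "duplicate")
  none <- file.path(dir, "none.csv")
  writeLines(c("image_id,dx", "a1,nv"), none)
  expect_error(load_manifest(none, dir), "empty")
  missing <- file.path(dir, "missing.csv")
  writeLines(c("image_id,dx", "ghost,akiec"), missing)
  expect_error(load_manifest(missing, dir), "ghost")
})

# --- augmentation ---------------------------------------------------------

test_that("one source image yields identity, rotation and both flips", {
  # asymmetric 2 x 3 image so every transform is distinguishable
  im <- array(as.numeric(1:18), dim = c(2, 3, 3))
  ds <- image_set(list(im), labels = 1L, ids = "src")
  out <- augment_set(ds, preprocess_plan(augment_minority_only = FALSE))
  expect_length(out, 4)
  expect_identical(out$ids, c("src", "src_rot90", "src_hflip",
                              "src_vflip"))
  expect_identical(out$labels, rep(1L, 4))
  expect_identical(out$source_ids, rep("src", 4))
  expect_identical(out$images[[1]], im)

  # independent index-arithmetic references
  H <- 2; W <- 3
  rot <- array(0, dim = c(W, H, 3))
  for (i in 1:W) for (j in 1:H) rot[i, j, ] <- im[H + 1 - j, i, ]
  hfl <- im[, W:1, , drop = FALSE]
  vfl <- im[H:1, , , drop = FALSE]
  expect_identical(out$images[[2]], rot)
  expect_identical(out$images[[3]], hfl)
  expect_identical(out$images[[4]], vfl)
})

test_that("flip and rotation transforms satisfy their group laws", {
  im <- rand_image(8, 6, seed = 9)
  expect_identical(akdl:::hflip(akdl:::hflip(im)), im)
  expect_identical(akdl:::vflip(akdl:::vflip(im)), im)
  r4 <- akdl:::rotate90(akdl:::rotate90(akdl:::rotate90(akdl:::rotate90(im))))
  expect_identical(r4, im)
})

test_that("minority-only augmentation expands exactly the smaller class by 4x", {
  ds <- tiny_set(n = 7, n_pos = 2)
  out <- augment_set(ds, preprocess_plan())
  expect_equal(sum(out$labels == 1L), 8)    # 2 x 4
  expect_equal(sum(out$labels == 0L), 5)    # untouched
  # balanced data has no strict minority: nothing is augmented
  bal <- tiny_set(n = 4, n_pos = 2)
  expect_length(augment_set(bal, preprocess_plan()), 4)
  # augment-everything plan
  all4 <- augment_set(bal, preprocess_plan(augment_minority_only = FALSE))
  expect_length(all4, 16)
  # derivatives only
  no_orig <- augment_set(bal, preprocess_plan(augment_minority_only = FALSE,
                                              include_originals = FALSE))
  expect_length(no_orig, 12)
})

# --- histogram equalization ----------------------------------------------

test_that("a uniform-histogram ramp is a fixed point of equalization", {
  ramp <- matrix(rep(0:255, each = 16), nrow = 64)   # 64 x 64, each value 16x
  img <- array(rep(ramp, 3), dim = c(64, 64, 3))
  expect_equal(equalize_histogram(img), img)
})

test_that("a 4x4 block matches the direct CDF-mapping enumeration", {
  v <- c(52, 55, 61, 59, 79, 61, 76, 61, 109, 129, 63, 52, 195, 160, 62,
         120)
  img <- array(rep(v, 3), dim = c(4, 4, 3))
  out <- equalize_histogram(img)
  # independent enumeration of the min-shifted CDF remapping
  n <- 16
  cnt <- table(factor(v, levels = 0:255))
  cdf <- cumsum(cnt)
  cdf_min <- min(cdf[cdf > 0])
  expected <- round(255 * (cdf[v + 1] - cdf_min) / (n - cdf_min))
  expect_equal(as.vector(out[, , 1]), as.numeric(expected))
  expect_equal(out[, , 2], out[, , 1])
})

test_that("equalized output is near-uniform up to the largest histogram bin", {
  for (seed in 1:5) {
    img <- rand_image(32, seed = seed)
    ch <- as.vector(img[, , 1])
    # concentrate mass to make the input clearly non-uniform
    ch[ch < 128] <- ch[ch < 128] %/% 4
    img[, , 1] <- ch
    out <- equalize_histogram(img)[, , 1]
    emp_cdf <- stats::ecdf(out)
    max_bin <- max(tabulate(as.integer(ch) + 1L, 256)) / length(ch)
    dev <- max(abs(emp_cdf(0:255) - (0:255 + 1) / 256))
    expect_lt(dev, max_bin + 1e-9)
  }
})

test_that("degenerate and invalid equalization inputs are handled", {
  cimg <- const_image(8)
  expect_equal(equalize_histogram(cimg), cimg)  # constant image unchanged
  bad <- const_image(8) + 0.5
  expect_error(equalize_histogram(bad), "8-bit")
  lum <- equalize_histogram(rand_image(16, seed = 3),
                            mode = "luminance_only")
  expect_equal(dim(lum), c(16, 16, 3))
  expect_true(all(lum == round(lum)) && min(lum) >= 0 && max(lum) <= 255)
})

# --- color space ----------------------------------------------------------

test_that("sRGB white and black map to the CIELAB reference points", {
  white <- rgb_to_lab(const_image(2, value = c(255, 255, 255)))
  expect_equal(white[1, 1, 1], 100, tolerance = 1e-6)
  expect_equal(abs(white[1, 1, 2]), 0, tolerance = 1e-4)
  expect_equal(abs(white[1, 1, 3]), 0, tolerance = 1e-4)
  black <- rgb_to_lab(const_image(2, value = c(0, 0, 0)))
  expect_equal(black[1, 1, 1], 0, tolerance = 1e-8)
})

test_that("Lab round trip recovers in-gamut colors within one 8-bit unit", {
  grid <- expand.grid(r = seq(0, 255, by = 51), g = seq(0, 255, by = 51),
                      b = seq(0, 255, by = 51))
  img <- array(c(grid$r, grid$g, grid$b), dim = c(36, 6, 3))
  back <- lab_to_srgb(rgb_to_lab(img))
  expect_lte(max(abs(back - img)), 1)
})

test_that("Lab channel ranges are conventional", {
  img <- rand_image(16, seed = 4)
  lab <- rgb_to_lab(img)
  expect_gte(min(lab[, , 1]), 0)
  expect_lte(max(lab[, , 1]), 100)
  expect_true(all(abs(lab[, , 2:3]) <= 128))
})

# --- standardization ------------------------------------------------------

test_that("standardization resizes to 64x64x3 on the unit interval", {
  img <- rand_image(450, 600, seed = 6)
  out <- standardize_to_input(img, space = "rgb")
  expect_equal(dim(out), c(64, 64, 3))
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
  # native-size input only gets the affine map
  small <- const_image(64, value = c(51, 102, 255))
  out2 <- standardize_to_input(small, space = "rgb")
  expect_equal(unique(as.vector(out2[, , 1])), 51 / 255)
  expect_equal(unique(as.vector(out2[, , 3])), 1)
})

test_that("Lab standardization applies the fixed per-channel affine maps", {
  lab <- array(0, dim = c(64, 64, 3))
  lab[, , 1] <- 50; lab[, , 2] <- 0; lab[, , 3] <- -128
  out <- standardize_to_input(lab, space = "lab")
  expect_equal(unique(as.vector(out[, , 1])), 0.5)
  expect_equal(unique(as.vector(out[, , 2])), 128 / 255)
  expect_equal(unique(as.vector(out[, , 3])), 0)
})

test_that("non-3-channel inputs are rejected across the chain", {
  gray <- matrix(0, 8, 8)
  expect_error(standardize_to_input(gray), "3")
  expect_error(rgb_to_lab(array(0, dim = c(4, 4, 4))), "3")
  expect_error(equalize_histogram(array(0L, dim = c(4, 4))), "3")
})

test_that("the full preprocessing chain emits the training tensor", {
  ds <- tiny_set(n = 4, n_pos = 2, size = 32)
  pp <- preprocess_set(ds, preprocess_plan())
  expect_equal(dim(pp$x), c(64, 64, 3, 4))
  expect_gte(min(pp$x), 0)
  expect_lte(max(pp$x), 1)
  expect_identical(pp$y, ds$labels)
  # deterministic
  expect_identical(pp$x, preprocess_set(ds, preprocess_plan())$x)
})
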