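test_that("the architecture reproduces the expected shape chain", {
  shp <- model_shapes(akdl_config())
  expect_equal(shp$conv1, c(64, 64, 6))
  expect_equal(shp$pool, c(32, 32, 6))
  expect_equal(shp$conv2, c(32, 32, 16))
  expect_equal(shp$flatten, 16384)
})

test_that("parameter counts match an independent per-layer tally", {
  m <- akdl_build(akdl_config(fc_width = 120))
  # independent tally from the layer dimensions actually present
  tally <- vapply(m$weights, length, integer(1))
  expect_equal(unname(tally[["W1"]] + tally[["b1"]]), (5 * 5 * 3 + 1) * 6)
  expect_equal(unname(tally[["W2"]] + tally[["b2"]]), (5 * 5 * 6 + 1) * 16)
  expect_equal(unname(tally[["W3"]] + tally[["b3"]]), 16384 * 120 + 120)
  expect_equal(unname(tally[["W4"]] + tally[["b4"]]), 120 * 2 + 2)
  expect_equal(count_parameters(m), sum(tally))
  expect_equal(count_parameters(m),
               456 + 2416 + (16384 * 120 + 120) + (120 * 2 + 2))
})

test_that("weight initialization is deterministic in the seed", {
  a <- akdl_build(akdl_config(init_seed = 42))
  b <- akdl_build(akdl_config(init_seed = 42))
  c <- akdl_build(akdl_config(init_seed = 43))
  expect_identical(a$weights, b$weights)
  expect_false(identical(a$weights, c$weights))
})

test_that("invalid architecture configurations are rejected", {
  expect_error(akdl_config(dropout_p = 1), "dropout_p")
  expect_error(akdl_config(leaky_slope = 0), "leaky_slope")
  expect_error(akdl_config(fc_width = 0), "fc_width")
  expect_error(akdl_config(conv_stride = 2), "conv_stride")
})

test_that("predictions are normalized, deterministic and batch-shaped", {
  m <- akdl_build(akdl_config(input_size = 16, fc_width = 8))
  x <- array(runif(16 * 16 * 3 * 5, 0, 1), dim = c(16, 16, 3, 5))
  p <- predict(m, x)
  expect_equal(dim(p), c(5, 2))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_identical(p, predict(m, x))
  expect_equal(predict(m, x, type = "class"),
               as.integer(p[, "ak"] >= 0.5))
})

test_that("dropout is inactive at inference", {
  cfg_drop <- akdl_config(input_size = 16, fc_width = 8, dropout_p = 0.5,
                          init_seed = 2)
  cfg_nodrop <- akdl_config(input_size = 16, fc_width = 8, dropout_p = 0,
                            init_seed = 2)
  x <- array(runif(16 * 16 * 3 * 4), dim = c(16, 16, 3, 4))
  m1 <- akdl_build(cfg_drop)
  m2 <- akdl_build(cfg_nodrop)
  expect_identical(m1$weights, m2$weights)
  expect_identical(predict(m1, x), predict(m2, x))
})

test_that("zero learning rate leaves the initial weights untouched", {
  cfg <- akdl_config(input_size = 16, fc_width = 8, init_seed = 7)
  x <- array(runif(16 * 16 * 3 * 8), dim = c(16, 16, 3, 8))
  y <- rep(c(0L, 1L), 4)
  m <- akdl(x, y, config = cfg,
            control = train_config(initial_learn_rate = 0, epochs = 3))
  expect_identical(m$weights, akdl_build(cfg)$weights)
})

test_that("training is deterministic end to end and records its history", {
  cfg <- akdl_config(input_size = 16, fc_width = 8, init_seed = 1)
  tc <- train_config(epochs = 4, shuffle_seed = 9)
  set.seed(31)
  x <- array(runif(16 * 16 * 3 * 12), dim = c(16, 16, 3, 12))
  y <- rep(c(0L, 1L), 6)
  m1 <- akdl(x, y, config = cfg, control = tc)
  m2 <- akdl(x, y, config = cfg, control = tc)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 4)
  expect_true(all(m1$history$loss >= 0))
  # a different shuffle seed changes the trajectory
  m3 <- akdl(x, y, config = cfg,
             control = train_config(epochs = 4, shuffle_seed = 10))
  expect_false(identical(m1$weights, m3$weights))
})

test_that("first-epoch loss on balanced data starts near ln 2", {
  set.seed(17)
  x <- array(runif(64 * 64 * 3 * 20), dim = c(64, 64, 3, 20))
  y <- rep(c(0L, 1L), 10)
  # untrained default network on balanced data
  m0 <- akdl_build(akdl_config())
  p <- predict(m0, x)
  expect_lt(abs(-mean(log(p[cbind(1:20, y + 1)])) - log(2)), 0.2)
  # and the first recorded training epoch starts there too
  m <- akdl(x, y, control = train_config(epochs = 1))
  expect_lt(abs(m$history$loss[1] - log(2)), 0.2)
  expect_true(all(is.finite(m$history$loss)))
})

test_that("degenerate training inputs are rejected", {
  cfg <- akdl_config(input_size = 16, fc_width = 8)
  x <- array(runif(16 * 16 * 3 * 4), dim = c(16, 16, 3, 4))
  expect_error(akdl(x, rep(1L, 4), config = cfg), "single class")
  expect_error(akdl(x, c(0L, 1L), config = cfg), "match")
  bad <- array(runif(8 * 8 * 3 * 4), dim = c(8, 8, 3, 4))
  expect_error(akdl(bad, rep(c(0L, 1L), 2), config = cfg), "16 x 16")
  expect_error(akdl(x * 2, rep(c(0L, 1L), 2), config = cfg), "\\[0, 1\\]")
})

test_that("the float trainer agrees with the double-precision reference step", {
  cfg <- akdl_config(input_size = 16, fc_width = 9, dropout_p = 0,
                     init_seed = 5)
  tc <- train_config(epochs = 1, mini_batch_size = 4, shuffle_seed = 2)
  set.seed(99)
  x <- array(runif(16 * 16 * 3 * 4), dim = c(16, 16, 3, 4))
  y <- c(0L, 1L, 0L, 1L)
  m <- akdl(x, y, config = cfg, control = tc)

  # independent step: R double-precision forward/backward + momentum rule
  w <- akdl:::init_weights(cfg)
  ord <- akdl:::with_seed(tc$shuffle_seed, sample.int(4))
  fw <- akdl:::forward_akdl(w, x[, , , ord, drop = FALSE], cfg,
                            training = TRUE, keep_cache = TRUE)
  gr <- akdl:::backward_akdl(w, fw$cache, fw$probs, y[ord], cfg)
  for (nm in names(w)) {
    l2 <- if (nm %in% c("W1", "W2", "W3", "W4"))
      tc$l2_regularization else 0
    w[[nm]] <- w[[nm]] - tc$initial_learn_rate * (gr[[nm]] + l2 * w[[nm]])
  }
  diffs <- mapply(function(a, b) max(abs(a - b)), m$weights, w)
  expect_lt(max(diffs), 1e-6)
})

test_that("model checkpoints round-trip with a JSON sidecar", {
  cfg <- akdl_config(input_size = 16, fc_width = 8)
  m <- akdl_build(cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_akdl(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$config$fc_width, 8)
  m2 <- load_akdl(path)
  expect_identical(m2$weights, m$weights)
})

test_that("augmented training makes classification flip-insensitive", {
  ds <- generate_dataset(synth_config(n_per_class = 40, separation = 1,
                                      seed = 3))
  plan <- preprocess_plan(augment_minority_only = FALSE)
  m <- akdl(ds, plan = plan, augment = TRUE,
            control = train_config(epochs = 10, shuffle_seed = 3))
  flipped <- image_set(lapply(ds$images, akdl:::hflip), ds$labels, ds$ids)
  agree <- mean(predict(m, ds, type = "class") ==
                  predict(m, flipped, type = "class"))
  expect_gte(agree, 0.9)
})
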