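test_that("confusion counts enumerate the four cells with AK positive", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(cc$TP, 1); expect_equal(cc$FN, 1)
  expect_equal(cc$TN, 1); expect_equal(cc$FP, 1)
  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$FP + perfect$FN, 0)
  expect_error(confusion_counts(integer(), integer()), "empty")
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "length")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "binary")
})

test_that("metrics evaluate the five closed forms on canonical tables", {
  m <- binary_metrics(list(TP = 1, FP = 1, TN = 1, FN = 1))
  expect_equal(m$Acc, 0.5); expect_equal(m$Sens, 0.5)
  expect_equal(m$Spec, 0.5); expect_equal(m$Prec, 0.5)
  expect_equal(m$MCC, 0)
  p <- binary_metrics(list(TP = 10, FP = 0, TN = 10, FN = 0))
  expect_equal(unlist(p[c("Acc", "Sens", "Spec", "Prec", "MCC")]),
               c(Acc = 1, Sens = 1, Spec = 1, Prec = 1, MCC = 1))
  expect_warning(u <- binary_metrics(list(TP = 0, FP = 0, TN = 5, FN = 5)),
                 "Prec")
  expect_true(is.nan(u$Prec))
  expect_true("Prec" %in% u$undefined)
  expect_error(binary_metrics(list(TP = 0, FP = 0, TN = 0, FN = 0)),
               "no samples")
})

test_that("metrics agree with direct formula evaluation on random tables", {
  set.seed(202)
  for (i in 1:200) {
    tp <- sample(0:40, 1); fp <- sample(0:40, 1)
    tn <- sample(0:40, 1); fn <- sample(0:40, 1)
    if (tp + fp + tn + fn == 0) next
    m <- suppressWarnings(binary_metrics(list(TP = tp, FP = fp, TN = tn,
                                              FN = fn)))
    expect_equal(m$Acc, (tn + tp) / (tp + fp + tn + fn))
    if (tp + fn > 0) expect_equal(m$Sens, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m$Spec, tn / (tn + fp))
    if (tp + fp > 0) expect_equal(m$Prec, tp / (tp + fp))
    den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    if (den > 0) {
      expect_equal(m$MCC, (tp * tn - fp * fn) / den)
      expect_gte(m$MCC, -1); expect_lte(m$MCC, 1)
    }
  }
})

test_that("MCC is symmetric under class swap and negates under inversion", {
  set.seed(77)
  for (i in 1:50) {
    y <- sample(0:1, 30, replace = TRUE)
    p <- sample(0:1, 30, replace = TRUE)
    if (length(unique(y)) < 2 || length(unique(p)) < 2) next
    m <- suppressWarnings(binary_metrics(confusion_counts(y, p)))
    swap <- suppressWarnings(binary_metrics(confusion_counts(1 - y,
                                                             1 - p)))
    inv <- suppressWarnings(binary_metrics(confusion_counts(y, 1 - p)))
    expect_equal(swap$MCC, m$MCC)
    expect_equal(inv$MCC, -m$MCC)
  }
})

test_that("the trivial all-positive classifier has Sens 1 and Spec 0", {
  y <- c(rep(1, 7), rep(0, 13))
  m <- suppressWarnings(binary_metrics(confusion_counts(y, rep(1, 20))))
  expect_equal(m$Sens, 1)
  expect_equal(m$Spec, 0)
})

test_that("ROC handles perfect, inverted and tied rankings", {
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1))$auc, 0)
  # all-tied scores collapse to the chance diagonal
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("trapezoidal AUC equals the tie-corrected rank statistic", {
  set.seed(55)
  for (i in 1:20) {
    n <- 200
    y <- sample(0:1, n, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), 1)          # rounding forces ties
    auc <- roc_auc(s, y)$auc
    rk <- rank(s)                    # average ranks = tie correction
    np <- sum(y == 1); nn <- sum(y == 0)
    mw <- (sum(rk[y == 1]) - np * (np + 1) / 2) / (np * nn)
    expect_equal(auc, mw, tolerance = 1e-10)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(4)
  s <- rnorm(100)
  y <- rep(c(0, 1), 50)
  a <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a)
  expect_equal(roc_auc(2 * s + 7, y)$auc, a)
})

test_that("fold plans are disjoint, exhaustive, balanced and seeded", {
  y <- rep(c(1, 0), c(60, 40))
  fp <- make_folds(y, k = 10, seed = 3)
  expect_equal(sort(unique(fp$assignments)), 1:10)
  expect_equal(length(fp$assignments), 100)
  sizes <- tabulate(fp$assignments, 10)
  expect_true(max(sizes) - min(sizes) <= 1)
  # stratified: per-class fold sizes differ by at most one
  for (cls in 0:1) {
    cs <- tabulate(fp$assignments[y == cls], 10)
    expect_true(max(cs) - min(cs) <= 1)
  }
  expect_identical(make_folds(y, k = 10, seed = 3)$assignments,
                   fp$assignments)
  expect_false(identical(make_folds(y, k = 10, seed = 4)$assignments,
                         fp$assignments))
  expect_error(make_folds(rep(1, 5), k = 10), "at least")
  expect_error(make_folds(rep(c(1, 0), c(5, 95)), k = 10, stratified = TRUE),
               "fewer than k")
})

test_that("cross-validation reports k folds whose mean ties out exactly", {
  ds <- generate_dataset(synth_config(n_per_class = 12, image_size = 32,
                                      separation = 1, seed = 6))
  fp <- make_folds(ds$labels, k = 3, seed = 1)
  cfg <- hog_config(resize_to = 64, cell_size = 16)
  cv <- cross_validate(baseline_recipe(baseline_spec("knn"), cfg), ds, fp)
  expect_equal(nrow(cv$folds), 3)
  expect_equal(length(cv$roc), 3)
  for (col in c("Acc", "Sens", "Spec", "Prec", "MCC", "AUC"))
    expect_equal(unname(cv$mean[[col]]), mean(cv$folds[[col]]),
                 tolerance = 1e-12)
})

test_that("augmented derivatives of test images never reach the training set", {
  ds <- generate_dataset(synth_config(n_per_class = 10, image_size = 32,
                                      separation = 1, seed = 8))
  # imbalance so minority augmentation actually fires
  ds <- ds[c(1:4, 11:20)]
  fp <- make_folds(ds$labels, k = 2, seed = 1)
  seen <- new.env(parent = emptyenv())
  probe <- structure(list(
    name = "probe",
    fit = function(train_set, fold_seed = 0L) {
      assign(sprintf("fold%d", fold_seed), train_set, envir = seen)
      list(score = function(test_set) test_set$labels + 0.1,
           predict = function(test_set) test_set$labels,
           probabilistic = TRUE)
    }), class = "model_recipe")
  cv <- cross_validate(probe, ds, fp, augment = TRUE)
  for (f in 1:2) {
    train_set <- get(sprintf("fold%d", f), envir = seen)
    test_ids <- ds$ids[fp$assignments == f]
    expect_length(intersect(train_set$source_ids, test_ids), 0)
    # minority class was expanded fourfold inside the fold
    n_min_src <- sum(ds$labels[fp$assignments != f] == 1L)
    expect_equal(sum(train_set$labels == 1L), 4 * n_min_src)
  }
  expect_equal(nrow(cv$folds), 2)
})

test_that("trapezoidal AUC agrees with the pROC reference implementation", {
  set.seed(12)
  for (i in 1:5) {
    y <- sample(0:1, 80, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(80), 1)
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(s, y)$auc, ref, tolerance = 1e-12)
  }
})
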