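#' Confusion counts for binary predictions
#'
#' Tabulates true/false positives and negatives with AK (label 1) as the
#' positive class.
#'
#' @param labels integer 0/1 truth vector.
#' @param predicted integer 0/1 prediction vector of the same length.
#' @return An object of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion_counts <- function(labels, predicted) {
  if (length(labels) == 0L)
    stop("empty inputs: no samples to tabulate", call. = FALSE)
  if (length(labels) != length(predicted))
    stop("labels and predictions differ in length", call. = FALSE)
  if (!all(labels %in% c(0, 1)) || !all(predicted %in% c(0, 1)))
    stop("labels and predictions must be binary 0/1", call. = FALSE)
  structure(list(TP = sum(labels == 1 & predicted == 1),
                 FP = sum(labels == 0 & predicted == 1),
                 TN = sum(labels == 0 & predicted == 0),
                 FN = sum(labels == 1 & predicted == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Accuracy, sensitivity, specificity, precision and MCC from counts
#'
#' Computes the five standard confusion-matrix metrics:
#' `Acc = (TN + TP) / total`, `Sens = TP / (TP + FN)`,
#' `Spec = TN / (TN + FP)`, `Prec = TP / (TP + FP)` and the Matthews
#' correlation coefficient
#' `MCC = (TP * TN - FP * FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as `NaN` and flagged in
#' the `undefined` attribute-style field.
#'
#' @param counts a [confusion_counts()] (or a list with TP/FP/TN/FN).
#' @return A list with `Acc`, `Sens`, `Spec`, `Prec`, `MCC` and
#'   `undefined`, a character vector naming any metric with a zero
#'   denominator.
#' @export
binary_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  total <- tp + fp + tn + fn
  if (total == 0) stop("no samples: metrics undefined", call. = FALSE)
  safe_div <- function(num, den) if (den == 0) NaN else num / den
  mcc_den <- sqrt(as.double(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  out <- list(Acc = (tn + tp) / total,
              Sens = safe_div(tp, tp + fn),
              Spec = safe_div(tn, tn + fp),
              Prec = safe_div(tp, tp + fp),
              MCC = if (mcc_den == 0) NaN else
                (as.double(tp) * tn - as.double(fp) * fn) / mcc_den)
  out$undefined <- names(out)[vapply(out, function(v)
    is.numeric(v) && is.nan(v), logical(1))]
  if (length(out$undefined) > 0)
    warning(sprintf("undefined metric(s) (zero denominator): %s",
                    paste(out$undefined, collapse = ", ")), call. = FALSE)
  out
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps a decision threshold over the unique score values (equal scores
#' collapse into one threshold step), producing `(FPR, TPR)` points from
#' `(0, 0)` to `(1, 1)`, and integrates by the trapezoidal rule.  Larger
#' scores must mean more AK-like.
#'
#' @param scores numeric vector.
#' @param labels integer 0/1 vector; both classes must be present.
#' @return A list with `curve` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1", call. = FALSE)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    stop("both classes must be present to compute a ROC curve",
         call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores into single steps
  grp <- cumsum(!duplicated(s))
  tp_steps <- tapply(y == 1, grp, sum)
  fp_steps <- tapply(y == 0, grp, sum)
  tpr <- c(0, cumsum(tp_steps) / np)
  fpr <- c(0, cumsum(fp_steps) / nn)
  thr <- c(Inf, unique(s))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr, threshold = thr),
       auc = auc)
}

#' Plan a (stratified) k-fold partition
#'
#' Assigns every sample to one of `k` folds.  With `stratified = TRUE`
#' (default) shuffled indices of each class are dealt round-robin so the
#' per-class fold sizes differ by at most one; otherwise all indices are
#' dealt together.  Reproducible from `seed`.
#'
#' @param labels integer 0/1 vector (only its length is used when
#'   `stratified = FALSE`).
#' @param k fold count (default 10).
#' @param seed integer seed.
#' @param stratified preserve class proportions across folds.
#' @return An object of class `fold_plan`: `k`, `assignments` (fold index
#'   per sample), `seed`, `stratified`.
#' @export
make_folds <- function(labels, k = 10L, seed = 1L, stratified = TRUE) {
  labels <- as.integer(labels)
  n <- length(labels)
  check_scalar_num(k, "k", lower = 2, integer = TRUE)
  if (n < k) stop("need at least k samples", call. = FALSE)
  assignments <- integer(n)
  with_seed(derive_seed(seed, 0L), {
    if (stratified) {
      for (cls in unique(labels)) {
        idx <- which(labels == cls)
        if (length(idx) < k)
          stop(sprintf(
            "class %d has %d samples, fewer than k = %d (stratified)",
            cls, length(idx), k), call. = FALSE)
        shuffled <- idx[sample.int(length(idx))]
        assignments[shuffled] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      shuffled <- sample.int(n)
      assignments[shuffled] <- rep_len(seq_len(k), n)
    }
  })
  structure(list(k = as.integer(k), assignments = assignments,
                 seed = as.integer(seed), stratified = stratified),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> k=%d, %s, seed=%d; fold sizes: %s\n", x$k,
              if (x$stratified) "stratified" else "unstratified",
              x$seed, paste(tabulate(x$assignments, x$k), collapse = " ")))
  invisible(x)
}

#' Model recipes for cross-validation
#'
#' A recipe is a factory producing a fresh trainable scorer per fold, the
#' unit [cross_validate()] operates on.  `akdl_recipe` wraps the shallow
#' network (preprocessing according to `plan`); `baseline_recipe` wraps a
#' HOG + classical-classifier pipeline.  Both return an object with a
#' `fit(train_set, fold_seed)` function whose result exposes
#' `score(test_set)` (AK score; a probability for the network and random
#' forest / knn, a signed decision value for the SVM), `predict(test_set)`
#' (0/1 labels by the model's native rule) and `probabilistic` (whether
#' scores live on the probability scale).
#'
#' @param config an [akdl_config()].
#' @param control a [train_config()].
#' @param plan a [preprocess_plan()].
#' @param spec a [baseline_spec()].
#' @param hog a [hog_config()].
#' @return An object of class `model_recipe`.
#' @rdname recipes
#' @export
akdl_recipe <- function(config = akdl_config(), control = train_config(),
                        plan = preprocess_plan()) {
  structure(list(
    name = "akdl",
    fit = function(train_set, fold_seed = 0L) {
      cfg <- config; ctl <- control
      cfg$init_seed <- derive_seed(config$init_seed, fold_seed)
      ctl$shuffle_seed <- derive_seed(control$shuffle_seed,
                                      fold_seed + 1L)
      model <- akdl(train_set, config = cfg, control = ctl, plan = plan)
      list(score = function(test_set)
             predict(model, test_set, type = "prob")[, "ak"],
           predict = function(test_set)
             predict(model, test_set, type = "class"),
           probabilistic = TRUE,
           model = model)
    }), class = "model_recipe")
}

#' @rdname recipes
#' @export
baseline_recipe <- function(spec = baseline_spec("svm"),
                            hog = hog_config()) {
  # descriptors are deterministic per image id, so across folds each image
  # is described once and the vector reused
  memo <- new.env(parent = emptyenv())
  features_of <- function(set) {
    miss <- !vapply(set$ids, exists, logical(1), envir = memo)
    if (any(miss)) {
      fresh <- hog_features(set[miss], hog)
      for (i in seq_len(nrow(fresh)))
        assign(rownames(fresh)[i], fresh[i, ], envir = memo)
    }
    m <- do.call(rbind, mget(set$ids, envir = memo))
    rownames(m) <- set$ids
    m
  }
  structure(list(
    name = spec$kind,
    fit = function(train_set, fold_seed = 0L) {
      sp <- spec
      sp$seed <- derive_seed(spec$seed, fold_seed)
      fit <- fit_baseline(features_of(train_set), train_set$labels, sp)
      list(score = function(test_set)
             score_samples(fit, features_of(test_set)),
           predict = function(test_set)
             predict(fit, features_of(test_set)),
           probabilistic = spec$kind != "svm",
           model = fit)
    }), class = "model_recipe")
}

#' k-fold cross-validation of a model recipe
#'
#' For every fold: fit a fresh model on the training indices (optionally
#' augmenting the training data first — augmentation never touches the
#' test fold, and derivative provenance is asserted so no augmented copy
#' of a test image can leak into training), score and label the test
#' indices, and compute the confusion metrics plus trapezoidal AUC.  The
#' summary row holds the arithmetic means of the per-fold metrics.
#'
#' @param recipe a [akdl_recipe()] or [baseline_recipe()] (or any object
#'   with the same `fit` contract).
#' @param dataset an [image_set].
#' @param plan a [fold_plan()] from [make_folds()].
#' @param augment augment each fold's training data with
#'   [augment_set()] under `preprocess` (default `FALSE`).
#' @param preprocess a [preprocess_plan()] governing augmentation.
#' @return An object of class `cv_report`: `folds` (data.frame of per-fold
#'   metrics), `mean` (named numeric vector of their means), `roc` (list
#'   of per-fold ROC curves), `model_name`, `train_seconds`.
#' @export
cross_validate <- function(recipe, dataset, plan, augment = FALSE,
                           preprocess = preprocess_plan()) {
  stopifnot(inherits(dataset, "image_set"), inherits(plan, "fold_plan"))
  if (length(dataset) != length(plan$assignments))
    stop("fold plan does not match dataset size", call. = FALSE)
  k <- plan$k
  rows <- vector("list", k)
  rocs <- vector("list", k)
  t0 <- proc.time()[["elapsed"]]
  for (f in seq_len(k)) {
    test_idx <- which(plan$assignments == f)
    train_idx <- which(plan$assignments != f)
    if (length(test_idx) == 0L)
      stop(sprintf("fold %d is empty", f), call. = FALSE)
    train_set <- dataset[train_idx]
    test_set <- dataset[test_idx]
    if (augment) {
      train_set <- augment_set(train_set, preprocess)
      leaked <- train_set$source_ids %in% test_set$ids
      if (any(leaked))
        stop("internal error: augmented derivative of a test image found in the training set",
             call. = FALSE)
    }
    fitted <- recipe$fit(train_set, fold_seed = f)
    scores <- fitted$score(test_set)
    predicted <- fitted$predict(test_set)
    cc <- confusion_counts(test_set$labels, predicted)
    met <- suppressWarnings(binary_metrics(cc))
    roc <- roc_auc(scores, test_set$labels)
    rocs[[f]] <- roc$curve
    rows[[f]] <- data.frame(fold = f, n_test = length(test_idx),
                            Acc = met$Acc, Sens = met$Sens,
                            Spec = met$Spec, Prec = met$Prec,
                            MCC = met$MCC, AUC = roc$auc)
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  folds <- do.call(rbind, rows)
  metric_cols <- c("Acc", "Sens", "Spec", "Prec", "MCC", "AUC")
  means <- colMeans(folds[metric_cols])
  structure(list(folds = folds, mean = means, roc = rocs,
                 model_name = recipe$name, train_seconds = elapsed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 3, ...) {
  cat(sprintf("%d-fold cross-validation of %s (%.1f s)\n",
              nrow(x$folds), x$model_name, x$train_seconds))
  cat("mean metrics:\n")
  print(round(x$mean, digits))
  invisible(x)
}

#' @export
summary.cv_report <- function(object, digits = 3, ...) {
  print(object, digits = digits)
  cat("\nper-fold metrics:\n")
  print(object$folds, digits = digits, row.names = FALSE)
  invisible(object)
}
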