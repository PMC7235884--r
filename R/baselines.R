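#' Classical baseline specification
#'
#' Chooses one of the three classical classifiers run on HOG features:
#' support vector machine (radial-basis kernel), random forest, or
#' k-nearest neighbour.  An optional tuning grid triggers seeded
#' cross-validated grid search over hyperparameters.
#'
#' @param kind `"svm"`, `"rf"` or `"knn"`.
#' @param hyperparameters named list of kind-specific settings.  Defaults:
#'   svm `list(cost = 1, gamma = NULL)` (gamma `NULL` = 1/ncol), rf
#'   `list(ntree = 100)`, knn `list(k = 5)`.
#' @param tuning optional named list of hyperparameter vectors to search
#'   (e.g. `list(cost = c(0.1, 1, 10))`), plus an optional `folds` count
#'   (default 5).  Selection maximizes mean CV accuracy; ties break toward
#'   the earliest grid row.
#' @param seed integer seed controlling fold assignment during tuning and
#'   any classifier-internal randomness.
#' @return An object of class `baseline_spec`.
#' @export
baseline_spec <- function(kind = c("svm", "rf", "knn"),
                          hyperparameters = list(), tuning = NULL,
                          seed = 1L) {
  if (length(kind) != 1L || !kind %in% c("svm", "rf", "knn"))
    stop_config("kind", "must be one of 'svm', 'rf', 'knn'")
  check_scalar_num(seed, "seed", integer = TRUE)
  defaults <- switch(kind,
                     svm = list(cost = 1, gamma = NULL),
                     rf = list(ntree = 100L),
                     knn = list(k = 5L))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(kind = kind, hyperparameters = hp, tuning = tuning,
                 seed = as.integer(seed)),
            class = "baseline_spec")
}

fit_one_baseline <- function(features, labels, kind, hp, seed) {
  yf <- factor(labels, levels = c(0L, 1L))
  switch(kind,
         svm = {
           gamma <- hp$gamma %||% (1 / ncol(features))
           # e1071 default column scaling; constant descriptor dimensions
           # (possible for HOG) only trigger a harmless scaling note
           suppressWarnings(
             e1071::svm(features, yf, kernel = "radial", cost = hp$cost,
                        gamma = gamma, scale = TRUE))
         },
         rf = with_seed(seed,
           randomForest::randomForest(features, yf, ntree = hp$ntree)),
         knn = list(train = features, labels = labels, k = hp$k))
}

#' Fit a classical baseline classifier on a feature matrix
#'
#' Trains the classifier named by `spec` on HOG feature vectors.  When a
#' tuning grid is supplied, hyperparameters are selected first by seeded
#' stratified cross-validated grid search on the training data.
#'
#' @param features `n x p` numeric matrix (rows = samples).
#' @param labels integer 0/1 vector, 1 = AK.
#' @param spec a [baseline_spec()].
#' @return An object of class `hog_baseline` exposing [score_samples()]
#'   and [predict.hog_baseline()].
#' @export
fit_baseline <- function(features, labels, spec = baseline_spec("svm")) {
  if (!inherits(spec, "baseline_spec"))
    stop_config("spec", "must be a baseline_spec")
  features <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(features) != length(labels))
    stop("features and labels disagree in length", call. = FALSE)
  if (min(table(factor(labels, levels = c(0L, 1L)))) < 2L)
    stop("at least 2 samples per class are required", call. = FALSE)

  hp <- spec$hyperparameters
  if (!is.null(spec$tuning)) {
    grid_vars <- spec$tuning[setdiff(names(spec$tuning), "folds")]
    folds <- spec$tuning$folds %||% 5L
    grid <- expand.grid(grid_vars, stringsAsFactors = FALSE)
    plan <- make_folds(labels, k = folds, seed = spec$seed,
                       stratified = TRUE)
    acc <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      hp_gi <- utils::modifyList(hp, as.list(grid[gi, , drop = FALSE]))
      hits <- 0L
      for (f in seq_len(folds)) {
        tr <- plan$assignments != f
        fit <- fit_one_baseline(features[tr, , drop = FALSE], labels[tr],
                                spec$kind, hp_gi, spec$seed)
        obj <- structure(list(kind = spec$kind, fit = fit,
                              hyperparameters = hp_gi),
                         class = "hog_baseline")
        pred <- predict(obj, features[!tr, , drop = FALSE])
        hits <- hits + sum(pred == labels[!tr])
      }
      acc[gi] <- hits / length(labels)
    }
    hp <- utils::modifyList(hp, as.list(grid[which.max(acc), ,
                                             drop = FALSE]))
  }

  structure(list(kind = spec$kind,
                 fit = fit_one_baseline(features, labels, spec$kind, hp,
                                        spec$seed),
                 hyperparameters = hp, seed = spec$seed),
            class = "hog_baseline")
}

#' Per-sample AK scores from a fitted baseline
#'
#' Larger scores mean more AK-like.  For `svm` the signed decision value
#' (oriented so positive favours AK), for `rf` the AK vote fraction, for
#' `knn` the fraction of AK neighbours among the k nearest training
#' samples (Euclidean distance).  Deterministic given the fitted object.
#'
#' @param classifier a fitted `hog_baseline`.
#' @param features `n x p` feature matrix.
#' @return Numeric vector of length `n`.
#' @export
score_samples <- function(classifier, features) {
  if (!inherits(classifier, "hog_baseline"))
    stop("'classifier' is not a fitted hog_baseline", call. = FALSE)
  features <- as.matrix(features)
  switch(classifier$kind,
         svm = {
           dv <- attr(predict(classifier$fit, features,
                              decision.values = TRUE), "decision.values")
           # e1071 orients the decision value toward the first factor
           # level seen in training; flip so positive = AK (level "1")
           s <- as.numeric(dv[, 1])
           if (grepl("^0/", colnames(dv)[1])) -s else s
         },
         rf = {
           as.numeric(predict(classifier$fit, features,
                              type = "prob")[, "1"])
         },
         knn = {
           knn_positive_fraction(classifier$fit, features)
         })
}

# AK-neighbour fraction among k nearest by Euclidean distance; ties in
# distance break toward lower training-row index (stable order).
knn_positive_fraction <- function(fit, features) {
  tr <- fit$train
  k <- fit$k
  tr_sq <- rowSums(tr^2)
  out <- numeric(nrow(features))
  cross <- features %*% t(tr)
  for (i in seq_len(nrow(features))) {
    d2 <- tr_sq - 2 * cross[i, ] + sum(features[i, ]^2)
    nn <- order(d2)[seq_len(k)]
    out[i] <- mean(fit$labels[nn] == 1L)
  }
  out
}

#' Predict 0/1 labels from a fitted baseline
#'
#' Uses each classifier's native decision rule: the SVM decision boundary,
#' random-forest majority vote, and k-nearest-neighbour majority (AK
#' fraction >= 0.5).
#'
#' @param object a fitted `hog_baseline`.
#' @param newdata feature matrix.
#' @param ... ignored.
#' @return Integer 0/1 vector.
#' @export
predict.hog_baseline <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  switch(object$kind,
         svm = as.integer(as.character(predict(object$fit, newdata))),
         rf = as.integer(as.character(predict(object$fit, newdata))),
         knn = as.integer(knn_positive_fraction(object$fit,
                                                newdata) >= 0.5))
}

#' @export
print.hog_baseline <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters,
                     function(v) paste(format(v), collapse = ","),
                     character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("<hog_baseline> kind=%s (%s)\n", x$kind, hp))
  invisible(x)
}
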