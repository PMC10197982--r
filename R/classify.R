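#' Binarize serum potassium at a diagnostic threshold
#'
#' Label 1 if and only if `k >= threshold` (the "greater than or equal"
#' convention of the hyperkalemia definitions: 5.0, 5.5, 6.0 and 6.5 mmol/L
#' are the canonical thresholds; other values are allowed with a warning).
#'
#' @param k numeric potassium values in mmol/L.
#' @param threshold diagnostic threshold in mmol/L.
#' @return integer vector of 0/1 labels.
#' @export
binarize_labels <- function(k, threshold) {
  if (!threshold %in% c(5.0, 5.5, 6.0, 6.5))
    warning("non-canonical hyperkalemia threshold: ", threshold, " mmol/L")
  as.integer(k >= threshold)
}

#' Split a dataset into training and test parts
#'
#' Random 8:2 split by default, deterministic given the seed. With
#' stratification, class proportions in each part differ from the overall
#' proportions by at most one sample.
#'
#' @param n number of rows (or a `labeled_dataset`, whose row count is used).
#' @param labels 0/1 labels, required when `stratify = TRUE`.
#' @param test_frac test fraction (default 0.2); `|test| = round(test_frac * n)`.
#' @param seed integer seed.
#' @param stratify preserve class proportions.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   covering all rows).
#' @export
split_dataset <- function(n, labels = NULL, test_frac = 0.2, seed = 1,
                          stratify = TRUE) {
  if (inherits(n, "labeled_dataset")) n <- nrow(n$features)
  if (n < 10) stop("validation error: need at least 10 rows to split")
  n_test <- round(test_frac * n)
  with_seed(seed, {
    if (stratify) {
      if (is.null(labels) || length(labels) != n)
        stop("validation error: stratified split needs labels of length n")
      classes <- sort(unique(labels))
      per_class <- vapply(classes, function(cl)
        round(test_frac * sum(labels == cl)), 0)
      # reconcile rounding so the total test size is exact
      excess <- sum(per_class) - n_test
      while (excess != 0) {
        j <- which.max(per_class)
        per_class[j] <- per_class[j] - sign(excess)
        excess <- excess - sign(excess)
      }
      if (any(per_class <= 0) || any(per_class >= table(factor(labels, classes))))
        stop("split error: a class would be absent from one part")
      test <- unlist(lapply(seq_along(classes), function(j) {
        idx <- which(labels == classes[j])
        sample(idx, per_class[j])
      }))
      test <- sort(test)
    } else {
      test <- sort(sample.int(n, n_test))
    }
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Model specification for one classifier family
#'
#' Families: `"LR"` (L2-penalized logistic regression), `"SVM"` (RBF
#' support-vector machine scored through its decision function), `"XGB"`
#' (gradient-boosted trees), `"AdaBoost"` (boosted decision stumps), `"CNN"`
#' (small 1-D convolutional network over the 4-lead x 12-feature grid).
#' The default hyperparameter grids are small and overridable.
#'
#' @param family one of `"LR"`, `"SVM"`, `"XGB"`, `"AdaBoost"`, `"CNN"`.
#' @param grid data.frame of hyperparameter combinations (one row per grid
#'   point), or NULL for the family default.
#' @param cv_folds number of cross-validation folds (>= 2).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(family = c("LR", "SVM", "XGB", "AdaBoost", "CNN"),
                       grid = NULL, cv_folds = 5) {
  family <- match.arg(family)
  if (cv_folds < 2) stop("validation error: cv_folds must be >= 2")
  if (is.null(grid)) grid <- default_grid(family)
  if (!nrow(grid)) stop("validation error: empty hyperparameter grid")
  structure(list(family = family, grid = grid, cv_folds = cv_folds),
            class = "model_spec")
}

default_grid <- function(family) {
  switch(family,
    LR = expand.grid(C = c(0.01, 0.1, 1, 10)),
    SVM = expand.grid(C = c(0.1, 1, 10), gamma = c(NA, 0.01, 0.1)),
    XGB = expand.grid(nrounds = c(100, 300), max_depth = c(2, 3, 4),
                      eta = c(0.05, 0.1)),
    AdaBoost = expand.grid(n_estimators = c(100, 300),
                           learning_rate = c(0.5, 1.0)),
    CNN = expand.grid(epochs = 150, lr = 0.01, batch = 64))
}

fit_scaler <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd)
}

apply_scaler <- function(x, sc)
  sweep(sweep(x, 2, sc$mean, "-"), 2, sc$sd, "/")

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_family <- function(family, x, y, params, seed) {
  with_seed(seed, switch(family,
    LR = ridge_logistic_fit(x, y, lambda = 1 / (params$C * nrow(x))),
    SVM = {
      g <- if (is.na(params$gamma))
        1 / (ncol(x) * max(mean(apply(x, 2, stats::var)), 1e-12))
      else params$gamma
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                 cost = params$C, gamma = g, scale = FALSE)
    },
    XGB = xgboost::xgboost(
      x = x, y = factor(y, levels = c(0, 1)), nrounds = params$nrounds,
      max_depth = params$max_depth, learning_rate = params$eta,
      objective = "binary:logistic", nthreads = 1, verbosity = 0),
    AdaBoost = adaboost_fit(x, y, n_estimators = params$n_estimators,
                            learning_rate = params$learning_rate),
    CNN = cnn_fit(x, y, epochs = params$epochs, lr = params$lr,
                  batch = params$batch),
    stop("training error: unknown family ", family)))
}

score_family <- function(family, fit, x) {
  switch(family,
    LR = ridge_logistic_predict(fit, x),
    SVM = {
      pr <- stats::predict(fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # orient so larger decision value means class "1"
      if (grepl("^0/", colnames(dv)[1])) dv <- -dv
      as.numeric(stats::plogis(dv))
    },
    XGB = as.numeric(stats::predict(fit, x)),
    AdaBoost = adaboost_predict(fit, x),
    CNN = cnn_predict(fit, x))
}

#' Tune hyperparameters by stratified cross-validation and train a model
#'
#' For every grid point, the mean validation AUC over `cv_folds` stratified
#' folds of the training data is computed, with per-feature standardization
#' refitted inside each fold (no leakage); the grid point with the maximal
#' mean AUC is selected (ties broken by grid order), and the final model is
#' refitted on the full training split with standardization parameters from
#' the training split only.
#'
#' @param x numeric feature matrix (training split), columns named.
#' @param y 0/1 labels.
#' @param spec a [model_spec()].
#' @param seed integer seed controlling fold assignment and any stochastic
#'   fitting.
#' @return an object of class `hk_model` with elements `family`, `chosen`
#'   (the selected grid row), `cv_table` (grid + mean validation AUC),
#'   `scaler`, `fit` and `feature_names`.
#' @export
hk_train <- function(x, y, spec = model_spec("XGB"), seed = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("training error: training data contain a single class")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("f", seq_len(ncol(x)))
  folds <- with_seed(seed, stratified_folds(y, spec$cv_folds))
  grid <- spec$grid
  cv_auc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    params <- as.list(grid[gi, , drop = FALSE])
    aucs <- vapply(seq_len(spec$cv_folds), function(f) {
      tr <- folds != f
      sc <- fit_scaler(x[tr, , drop = FALSE])
      xtr <- apply_scaler(x[tr, , drop = FALSE], sc)
      xva <- apply_scaler(x[!tr, , drop = FALSE], sc)
      fit <- fit_family(spec$family, xtr, y[tr], params,
                        seed = seed + 1000L * f + gi)
      roc_auc(y[!tr], score_family(spec$family, fit, xva))
    }, 0)
    cv_auc[gi] <- mean(aucs)
  }
  best <- which.max(cv_auc)   # first maximum = first in grid order
  chosen <- as.list(grid[best, , drop = FALSE])
  scaler <- fit_scaler(x)
  fit <- fit_family(spec$family, apply_scaler(x, scaler), y, chosen,
                    seed = seed)
  structure(list(family = spec$family, chosen = chosen,
                 cv_table = cbind(grid, mean_cv_auc = cv_auc),
                 scaler = scaler, fit = fit, feature_names = colnames(x),
                 seed = seed),
            class = "hk_model")
}

#' Predict positive-class scores from a trained model
#'
#' Scores are continuous in `[0, 1]`, monotone in the predicted propensity of
#' the positive (hyperkalemic) class, and deterministic given the trained
#' model. Columns of `newdata` are matched by name to the training layout,
#' so storage order does not matter.
#'
#' @param object an `hk_model`.
#' @param newdata feature matrix with the training columns (any order).
#' @param ... unused.
#' @return numeric score vector, one per row.
#' @export
predict.hk_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$feature_names))
      stop("validation error: expected ", length(object$feature_names),
           " feature columns, got ", ncol(newdata))
    colnames(newdata) <- object$feature_names
  }
  if (!all(object$feature_names %in% colnames(newdata)))
    stop("validation error: missing feature column(s) ",
         paste(setdiff(object$feature_names, colnames(newdata)),
               collapse = ", "))
  newdata <- newdata[, object$feature_names, drop = FALSE]
  score_family(object$family, object$fit,
               apply_scaler(newdata, object$scaler))
}

#' @export
#' @method print hk_model
print.hk_model <- function(x, ...) {
  cat(sprintf("<hk_model %s>  chosen: %s  (best mean CV AUC %.3f over %d grid points)\n",
              x$family,
              paste(names(x$chosen), unlist(x$chosen), sep = "=",
                    collapse = ", "),
              max(x$cv_table$mean_cv_auc), nrow(x$cv_table)))
  invisible(x)
}

#' Dichotomize model scores into class predictions
#'
#' All families are scored on `[0, 1]` with 0.5 the natural decision point
#' (for LR/XGB/CNN this is a calibrated probability of 0.5; for SVM and
#' AdaBoost it corresponds to the zero of the decision function / boosted
#' margin).
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param cutoff decision cutoff (default 0.5).
#' @return integer 0/1 predictions.
#' @export
classify_scores <- function(scores, cutoff = 0.5) as.integer(scores >= cutoff)
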