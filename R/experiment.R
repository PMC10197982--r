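#' Run the full hyperkalemia-prediction experiment
#'
#' The package's central fitting function: given (or simulating) a labeled
#' 48-feature dataset, it binarizes serum potassium at each diagnostic
#' threshold, makes one random 8:2 train/test split shared by all
#' thresholds, tunes and trains every requested model family by stratified
#' 5-fold cross-validation on the training split, scores the held-out test
#' split, and assembles the evaluation report (confusion metrics, F1, AUC
#' with DeLong 95% CIs, pairwise DeLong tests).
#'
#' @param dataset a `labeled_dataset` (features + potassium), or NULL to
#'   simulate one from `config`.
#' @param config a [synthetic_config()] used when `dataset` is NULL.
#' @param thresholds diagnostic thresholds in mmol/L, ascending.
#' @param families model families (see [model_spec()]).
#' @param seed master seed for the split, fold assignment and stochastic
#'   fits.
#' @param test_frac held-out fraction.
#' @param stratify_split stratify the train/test split on the labels of the
#'   first threshold (default FALSE: a plain random split shared across
#'   thresholds, matching the single up-front split of the study design).
#' @param template,effect,noise,pp_config generator and preprocessing
#'   settings for the simulated dataset.
#' @param specs optional named list of [model_spec()] overrides per family.
#' @param verbose print stage progress.
#' @return an object of class `hk_experiment`: the dataset, split, trained
#'   `models[[family]][[threshold]]`, the long `score_table` and the
#'   `report` (an `hk_report`).
#' @export
hk_experiment <- function(dataset = NULL, config = synthetic_config(),
                          thresholds = c(5.0, 5.5, 6.0, 6.5),
                          families = c("LR", "SVM", "XGB", "AdaBoost", "CNN"),
                          seed = 1, test_frac = 0.2, stratify_split = FALSE,
                          template = beat_template(),
                          effect = k_effect_model(), noise = noise_model(),
                          pp_config = preprocess_config(), specs = NULL,
                          verbose = FALSE) {
  if (!length(families)) stop("validation error: empty model family list")
  if (is.unsorted(thresholds))
    stop("validation error: thresholds must be ascending")
  if (is.null(dataset)) {
    if (verbose) message("simulating ", config$n_records, " records ...")
    dataset <- simulate_feature_dataset(config, template, effect, noise,
                                        pp_config, verbose = verbose)
  }
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- nrow(dataset$features)
  y_first <- binarize_labels(dataset$k, thresholds[1])
  split <- split_dataset(n, labels = y_first, test_frac = test_frac,
                         seed = seed, stratify = stratify_split)
  models <- list()
  score_table <- NULL
  for (fam in families) {
    spec <- if (!is.null(specs[[fam]])) specs[[fam]] else model_spec(fam)
    models[[fam]] <- list()
    for (thr in thresholds) {
      if (verbose) message("training ", fam, " at threshold ", thr, " ...")
      y <- binarize_labels(dataset$k, thr)
      fit <- hk_train(dataset$features[split$train, , drop = FALSE],
                      y[split$train], spec,
                      seed = seed + round(1000 * thr))
      models[[fam]][[as.character(thr)]] <- fit
      s <- predict(fit, dataset$features[split$test, , drop = FALSE])
      score_table <- rbind(score_table, data.frame(
        family = fam, threshold = thr,
        record_id = dataset$record_ids[split$test],
        y_true = y[split$test], score = s))
    }
  }
  structure(list(dataset = dataset, split = split, thresholds = thresholds,
                 families = families, models = models,
                 score_table = score_table,
                 report = hk_report(score_table), seed = seed),
            class = "hk_experiment")
}

#' @export
#' @method print hk_experiment
print.hk_experiment <- function(x, ...) {
  cat(sprintf("<hk_experiment> %d records (train %d / test %d), %d families x %d thresholds\n\n",
              nrow(x$dataset$features), length(x$split$train),
              length(x$split$test), length(x$families),
              length(x$thresholds)))
  print(x$report)
  invisible(x)
}

#' @export
#' @method summary hk_experiment
summary.hk_experiment <- function(object, ...) {
  summary(object$report)
  invisible(object)
}

#' @export
plot.hk_experiment <- function(x, ...) plot(x$report, ...)
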