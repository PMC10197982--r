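#' Default pipeline configuration
#'
#' A single nested list drives the whole pipeline; every key has a default,
#' so a minimal config (a seed) is complete. Sections: `seed`, `outdir`,
#' `thresholds`, `families`, `test_frac`, `stratify_split`, `cutoff`, and
#' the sub-configs `synthetic`, `effect`, `noise`, `preprocess` whose fields
#' mirror [synthetic_config()], [k_effect_model()], [noise_model()] and
#' [preprocess_config()].
#'
#' @return a named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(seed = 1L, outdir = "hk_run",
       thresholds = c(5.0, 5.5, 6.0, 6.5),
       families = c("LR", "SVM", "XGB", "AdaBoost", "CNN"),
       test_frac = 0.2, stratify_split = FALSE, cutoff = 0.5,
       synthetic = list(n_records = 1024L, k_mean = 4.83, k_sd = 1.01,
                        k_bounds = c(2.5, 8.0), duration_s = 30, fs = 500),
       effect = unclass(k_effect_model()),
       noise = unclass(noise_model()),
       preprocess = unclass(preprocess_config()))
}

#' Validate a pipeline configuration file or list
#'
#' Reads YAML (if given a path), fills defaults, rejects unknown keys, and
#' reports every schema violation at once rather than only the first.
#' Thresholds outside the plausible potassium range trigger a warning.
#'
#' @param config path to a YAML file, or a (possibly partial) config list.
#' @return a fully defaulted, validated config of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("validation error: no such file ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- pipeline_defaults()
  errors <- character(0)
  merge_section <- function(def, user, path) {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown))
      errors <<- c(errors, paste0("unknown key(s) at ", path, ": ",
                                  paste(unknown, collapse = ", ")))
    for (k in intersect(names(user), names(def))) {
      if (is.list(def[[k]])) def[[k]] <- merge_section(def[[k]],
                                                       as.list(user[[k]]),
                                                       paste0(path, k, "."))
      else def[[k]] <- unlist(user[[k]])
    }
    def
  }
  cfg <- merge_section(defaults, config, "")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    errors <- c(errors, "seed must be a single integer")
  if (is.unsorted(cfg$thresholds))
    errors <- c(errors, "thresholds must be sorted ascending")
  if (!length(cfg$families))
    errors <- c(errors, "families must be non-empty")
  bad_fam <- setdiff(cfg$families, c("LR", "SVM", "XGB", "AdaBoost", "CNN"))
  if (length(bad_fam))
    errors <- c(errors, paste("unknown model family:",
                              paste(bad_fam, collapse = ", ")))
  if (any(unlist(cfg$noise) < 0))
    errors <- c(errors, "noise parameters must be >= 0")
  if (cfg$synthetic$n_records <= 0)
    errors <- c(errors, "synthetic.n_records must be > 0")
  if (cfg$test_frac <= 0 || cfg$test_frac >= 1)
    errors <- c(errors, "test_frac must be in (0, 1)")
  if (length(errors))
    stop("configuration error(s):\n  - ", paste(errors, collapse = "\n  - "))
  if (any(cfg$thresholds < 1 | cfg$thresholds > 10))
    warning("threshold(s) outside the plausible potassium range [1, 10]: ",
            paste(cfg$thresholds[cfg$thresholds < 1 | cfg$thresholds > 10],
                  collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

cfg_objects <- function(cfg) {
  list(synthetic = do.call(synthetic_config,
                           c(cfg$synthetic, list(seed = cfg$seed))),
       effect = do.call(k_effect_model, cfg$effect),
       noise = do.call(noise_model, cfg$noise),
       preprocess = do.call(preprocess_config, cfg$preprocess))
}

hk_log <- function(outdir, ..., verbose = TRUE) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  if (verbose) message(line)
  cat(line, "\n", file = file.path(outdir, "run.log"), append = TRUE)
}

#' Simulate stage: write the features and labels tables
#'
#' Generates the synthetic dataset, preprocesses each record, extracts the
#' 48-feature vectors and writes `features.csv` (record_id, k_mmol_per_l,
#' 48 feature columns) and `labels.csv` to the output directory.
#'
#' @param cfg a `pipeline_config`.
#' @param verbose log to console.
#' @return the `labeled_dataset`, invisibly.
#' @export
pipeline_simulate <- function(cfg, verbose = TRUE) {
  obj <- cfg_objects(cfg)
  ds <- simulate_feature_dataset(obj$synthetic, beat_template(), obj$effect,
                                 obj$noise, obj$preprocess,
                                 verbose = verbose)
  feat <- data.frame(record_id = ds$record_ids, k_mmol_per_l = ds$k,
                     ds$features, check.names = FALSE)
  utils::write.csv(feat, file.path(cfg$outdir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(record_id = ds$record_ids,
                              k_mmol_per_l = ds$k, phase = "synthetic"),
                   file.path(cfg$outdir, "labels.csv"), row.names = FALSE)
  hk_log(cfg$outdir, "simulate: ", length(ds$record_ids), " records in, ",
         nrow(ds$features), " feature vectors out (", ds$n_dropped,
         " dropped)", verbose = verbose)
  invisible(ds)
}

read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  fcols <- setdiff(names(df), c("record_id", "k_mmol_per_l"))
  structure(list(features = as.matrix(df[fcols]), k = df$k_mmol_per_l,
                 record_ids = df$record_id, n_dropped = 0L),
            class = "labeled_dataset")
}

#' Train + evaluate stages: run the experiment on a features table
#'
#' Reads `features.csv` from the output directory (or takes a dataset),
#' runs [hk_experiment()], and writes `scores.csv` (per record x family x
#' threshold), `hyperparameters.json`, `report.csv`, `delong.csv` and
#' `roc.csv`.
#'
#' @param cfg a `pipeline_config`.
#' @param dataset optional `labeled_dataset` (read from disk when NULL).
#' @param verbose log to console.
#' @return the `hk_experiment`, invisibly.
#' @export
pipeline_train_evaluate <- function(cfg, dataset = NULL, verbose = TRUE) {
  if (is.null(dataset))
    dataset <- read_feature_csv(file.path(cfg$outdir, "features.csv"))
  obj <- cfg_objects(cfg)
  exp <- hk_experiment(dataset, thresholds = cfg$thresholds,
                       families = cfg$families, seed = cfg$seed,
                       test_frac = cfg$test_frac,
                       stratify_split = cfg$stratify_split,
                       verbose = verbose)
  utils::write.csv(exp$score_table, file.path(cfg$outdir, "scores.csv"),
                   row.names = FALSE)
  hp <- lapply(exp$models, function(fam) lapply(fam, `[[`, "chosen"))
  jsonlite::write_json(hp, file.path(cfg$outdir, "hyperparameters.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(exp$report$metrics, file.path(cfg$outdir, "report.csv"),
                   row.names = FALSE)
  utils::write.csv(exp$report$delong, file.path(cfg$outdir, "delong.csv"),
                   row.names = FALSE)
  utils::write.csv(exp$report$roc, file.path(cfg$outdir, "roc.csv"),
                   row.names = FALSE)
  hk_log(cfg$outdir, "train/evaluate: ", length(cfg$families),
         " families x ", length(cfg$thresholds), " thresholds on ",
         nrow(dataset$features), " records", verbose = verbose)
  invisible(exp)
}

#' Run the whole pipeline from one config
#'
#' simulate -> preprocess -> extract-features -> train -> evaluate as one
#' reproducible run. With `resume = TRUE`, a stage whose outputs already
#' exist in `outdir` is skipped and its outputs reloaded. Writes a
#' `manifest.json` with the config, per-file MD5 checksums and stage
#' record counts.
#'
#' @param config a config path, list, or `pipeline_config`.
#' @param resume reuse existing stage outputs.
#' @param verbose log to console as well as to `outdir/run.log`.
#' @return the manifest, invisibly (class `hk_manifest`).
#' @export
run_pipeline <- function(config = list(), resume = FALSE, verbose = TRUE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  feat_path <- file.path(cfg$outdir, "features.csv")
  ds <- tryCatch({
    if (resume && file.exists(feat_path)) {
      hk_log(cfg$outdir, "simulate: resumed from ", feat_path,
             verbose = verbose)
    } else {
      pipeline_simulate(cfg, verbose = verbose)
    }
    # the on-disk table is the canonical representation, so fresh and
    # resumed runs see bit-identical features
    read_feature_csv(feat_path)
  }, error = function(e) stop("stage 'simulate' failed: ",
                              conditionMessage(e)))
  exp <- tryCatch(pipeline_train_evaluate(cfg, ds, verbose = verbose),
                  error = function(e) stop("stage 'train/evaluate' failed: ",
                                           conditionMessage(e)))
  files <- list.files(cfg$outdir, pattern = "\\.(csv|json)$",
                      full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("hyperkECG")),
    created = format(t0, "%Y-%m-%dT%H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    config = unclass(cfg),
    n_records = length(ds$record_ids),
    n_dropped = ds$n_dropped,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  hk_log(cfg$outdir, "pipeline complete in ",
         round(manifest$elapsed_s, 1), " s", verbose = verbose)
  invisible(structure(manifest, class = "hk_manifest"))
}

#' @export
#' @method print hk_manifest
print.hk_manifest <- function(x, ...) {
  cat("<hk_manifest>", x$n_records, "records,", length(x$checksums),
      "artifacts,", round(x$elapsed_s, 1), "s\n")
  invisible(x)
}

#' Write a generated dataset to disk as records + labels + truth manifest
#'
#' Materializes every record of a [generate_dataset()] result as WFDB-style
#' header/Format-212 files (or CSV), alongside `labels.csv` and
#' `truth.json`, a manifest of the generator's ground truth (true potassium,
#' per-record heart rate and atypia flag) usable as a test oracle.
#'
#' @param ds a list with `records` and `labels` as from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @param format `"wfdb"` or `"csv"`.
#' @return invisibly, the directory.
#' @export
write_dataset <- function(ds, dir, format = c("wfdb", "csv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- list()
  for (rec in ds$records) {
    id <- rec$record_id
    if (format == "wfdb")
      write_ecg(rec, file.path(dir, paste0(id, ".hea")),
                file.path(dir, paste0(id, ".dat")))
    else
      write_ecg_csv(rec, file.path(dir, paste0(id, ".csv")))
    tr <- attr(rec, "truth")
    truth[[id]] <- list(k_mmol_per_l = tr$k,
                        heart_rate_bpm = tr$heart_rate_bpm,
                        atypical = isTRUE(tr$atypical),
                        t_amp_mv = unname(tr$template$amp[["T"]]),
                        t_width_s = unname(tr$template$width[["T"]]))
  }
  utils::write.csv(ds$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
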