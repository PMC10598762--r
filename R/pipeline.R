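# Model-bundle serialization and the end-to-end pipeline entry point
# wiring simulate -> train -> evaluate -> predict.

#' Save / load a model bundle as a directory
#'
#' The bundle directory holds the engine model file (`model.ubj` for
#' boosting, `model.rds` otherwise), `vocabulary.txt` (one token per
#' line), `label_map.tsv`, `config.json` (algorithm, k, tuned
#' hyperparameters, seed), and — when present — `cv_report.tsv` and
#' `search_history.tsv`.
#'
#' @param bundle A `model_bundle`.
#' @param dir Target directory (created if needed).
#' @return `dir` (for `save_model_bundle`) or the restored
#'   `model_bundle` (for `load_model_bundle`).
#' @export
save_model_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "model_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(bundle$fit, "xgb.Booster")) {
    xgboost::xgb.save(bundle$fit, file.path(dir, "model.ubj"))
  } else {
    saveRDS(bundle$fit, file.path(dir, "model.rds"))
  }
  writeLines(bundle$vocab$tokens, file.path(dir, "vocabulary.txt"))
  write.table(data.frame(species = names(bundle$label_map),
                         label = unname(bundle$label_map)),
              file.path(dir, "label_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(algorithm = bundle$algorithm,
                            k = bundle$vocab$k, config = bundle$config,
                            seed = bundle$seed,
                            cv_accuracy = bundle$cv_accuracy),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(bundle$cv_report)) {
    write.table(bundle$cv_report, file.path(dir, "cv_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bundle$search_history)) {
    write.table(bundle$search_history, file.path(dir, "search_history.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  tokens <- readLines(file.path(dir, "vocabulary.txt"))
  vocab <- structure(list(k = as.integer(cfg$k), tokens = tokens,
                          index = setNames(seq_along(tokens), tokens)),
                     class = "kmer_vocab")
  lm <- read.delim(file.path(dir, "label_map.tsv"),
                   stringsAsFactors = FALSE)
  fit <- if (file.exists(file.path(dir, "model.ubj"))) {
    xgboost::xgb.load(file.path(dir, "model.ubj"))
  } else {
    readRDS(file.path(dir, "model.rds"))
  }
  cv_report <- if (file.exists(file.path(dir, "cv_report.tsv"))) {
    read.delim(file.path(dir, "cv_report.tsv"))
  }
  new_model_bundle(cfg$algorithm, fit, vocab,
                   setNames(as.integer(lm$label), lm$species),
                   as.list(cfg$config), cv_report = cv_report,
                   seed = cfg$seed)
}

#' Run the full pipeline
#'
#' Stages: load (or simulate) a labeled dataset, apply the minimum-count
#' filter, hold out a stratified test split, tune and fit the classifier,
#' evaluate on CV folds and on the holdout, and (optionally) predict a
#' query FASTA. All artifacts — dataset summary, model bundle directory,
#' metrics TSVs, predictions, and a JSON run manifest recording the seed
#' — are written under `out_dir`.
#'
#' @param out_dir Output directory.
#' @param fasta,manifest Paths to the input FASTA and manifest TSV;
#'   `NULL` to simulate instead.
#' @param simulate A [synthetic_config()] used when no FASTA is given.
#' @param query_fasta Optional FASTA of new sequences to classify.
#' @param k k-mer size (default 7).
#' @param min_count Minimum records per retained species (default 7).
#' @param test_fraction Holdout fraction (default 0.2).
#' @param algorithm `"gbdt"` (tuned) or a baseline name (fit with
#'   defaults).
#' @param budget Search budget `c(init_points, n_iter)` for the tuned
#'   classifier.
#' @param seed Master seed, recorded in every artifact.
#' @param cv A [cv_plan()].
#' @return Invisibly, a list with `bundle`, `cv_report`,
#'   `holdout_report`, `predictions`, and the artifact paths.
#' @export
run_pipeline <- function(out_dir, fasta = NULL, manifest = NULL,
                         simulate = synthetic_config(),
                         query_fasta = NULL, k = 7L, min_count = 7L,
                         test_fraction = 0.2, algorithm = "gbdt",
                         budget = c(5L, 25L), seed = 1L,
                         cv = cv_plan()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(fasta)) {
    simulate$seed <- seed
    sim <- generate_dataset(simulate)
    write_synthetic(sim, file.path(out_dir, "simulated"))
    records <- sim$dataset$records
  } else {
    records <- read_barcodes(fasta, manifest)
  }
  dataset <- filter_min_count(records, min_count)
  dataset_summary(dataset, file.path(out_dir, "dataset_summary.tsv"))
  parts <- split_train_test(dataset, test_fraction, seed)
  if (algorithm %in% c("gbdt", "gbdt2")) {
    bundle <- train_best_classifier(
      parts$train, k = k, cv = cv, budget = budget, seed = seed,
      variant = if (algorithm == "gbdt2") "lossguide" else "depthwise")
  } else {
    bundle <- train_baseline(parts$train, algorithm, k = k, seed = seed)
  }
  save_model_bundle(bundle, file.path(out_dir, "model"))
  holdout <- suppressWarnings(evaluate_model(bundle, parts$test))
  write_metrics_report(holdout, file.path(out_dir, "holdout_metrics.tsv"),
                       roc_dir = file.path(out_dir, "roc"))
  predictions <- NULL
  if (!is.null(query_fasta)) {
    queries <- read_fasta(query_fasta)
    predictions <- predict_species(bundle, queries)
    write.table(predictions, file.path(out_dir, "predictions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(seed = seed, k = k, min_count = min_count,
         test_fraction = test_fraction, algorithm = algorithm,
         budget = budget, n_records = nrow(dataset$records),
         n_species = length(dataset$label_map),
         cv_accuracy = bundle$cv_accuracy,
         holdout_accuracy = holdout$accuracy,
         holdout_macro_auroc = holdout$macro_auc,
         package_version = as.character(utils::packageVersion("barcodeboost"))),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(list(bundle = bundle, cv_report = bundle$cv_report,
                 holdout_report = holdout, predictions = predictions,
                 out_dir = out_dir))
}
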