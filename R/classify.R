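# Train/test splitting, stratified cross-validation, the classification
# engines (gradient-boosted trees, multinomial naive Bayes, random
# forest), and species prediction for new sequences.

#' Default gradient-boosted tree configuration and search ranges
#'
#' The tunable hyperparameters are the tree count `n_estimators`
#' (100-400), `max_depth` (5-10), the leaf penalty `gamma` (0-1), and the
#' `learning_rate` (0-1, sampled on (1e-3, 1] to avoid the degenerate 0
#' endpoint). The L2 leaf-weight penalty `lambda` stays at the engine
#' default; the objective is multiclass log-loss.
#'
#' @param n_estimators,max_depth,gamma,learning_rate Scalar values for a
#'   concrete configuration.
#' @return Named list.
#' @export
gbdt_config <- function(n_estimators = 200L, max_depth = 6L, gamma = 0,
                        learning_rate = 0.3) {
  list(n_estimators = as.integer(round(n_estimators)),
       max_depth = as.integer(round(max_depth)),
       gamma = gamma, learning_rate = learning_rate)
}

#' @rdname gbdt_config
#' @export
gbdt_space <- function() {
  list(max_depth = c(5, 10), gamma = c(0, 1),
       learning_rate = c(1e-3, 1), n_estimators = c(100, 400))
}

#' Cross-validation plan
#'
#' Stratified k-fold settings used both as the inner loop of
#' hyperparameter search and for reporting per-fold metrics.
#'
#' @param n_splits Number of folds (default 5).
#' @param shuffle Shuffle within class before assigning folds.
#' @param random_state Seed for the shuffle (default 2020).
#' @return Named list of class `cv_plan`.
#' @export
cv_plan <- function(n_splits = 5L, shuffle = TRUE, random_state = 2020L) {
  stopifnot(n_splits >= 2L)
  structure(list(n_splits = as.integer(n_splits), shuffle = shuffle,
                 random_state = as.integer(random_state)),
            class = "cv_plan")
}

# run expr under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Assign stratified cross-validation folds
#'
#' Samples of each class are distributed across folds so that per-fold
#' class counts differ by at most one from an even split.
#'
#' @param y Integer class labels.
#' @param plan A [cv_plan()].
#' @return Integer fold id (1..n_splits) per sample.
#' @export
cv_folds <- function(y, plan = cv_plan()) {
  stopifnot(inherits(plan, "cv_plan"))
  k <- plan$n_splits
  fold <- integer(length(y))
  with_seed(plan$random_state, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      if (plan$shuffle && length(idx) > 1L) idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified train/test split
#'
#' @param dataset A `barcode_dataset`.
#' @param test_fraction Fraction of each species held out (default 0.2).
#' @param seed Integer seed; fixed seed gives an identical partition.
#' @return List with `train` and `test`, both `barcode_dataset`s sharing
#'   the parent's label map.
#' @export
split_train_test <- function(dataset, test_fraction = 0.2, seed = 1L) {
  stopifnot(inherits(dataset, "barcode_dataset"),
            test_fraction > 0, test_fraction < 1)
  sp <- dataset$records$species
  singleton <- names(which(table(sp) < 2L))
  if (length(singleton)) {
    stop("species with a single record cannot be split (",
         paste(head(singleton, 3), collapse = ", "),
         "); raise min_count or merge the split")
  }
  test_idx <- integer(0)
  with_seed(seed, {
    for (cls in unique(sp)) {
      idx <- which(sp == cls)
      n_test <- min(max(1L, round(length(idx) * test_fraction)),
                    length(idx) - 1L)
      test_idx <- c(test_idx, sample(idx, n_test))
    }
  })
  test_idx <- sort(test_idx)
  subset_ds <- function(i) {
    structure(list(records = {
      r <- dataset$records[i, , drop = FALSE]; rownames(r) <- NULL; r
    }, label_map = dataset$label_map, min_count = dataset$min_count),
    class = "barcode_dataset")
  }
  list(train = subset_ds(setdiff(seq_along(sp), test_idx)),
       test = subset_ds(test_idx))
}

## ---- engines ---------------------------------------------------------

fit_gbdt <- function(X, y, num_class, config, seed = 1L,
                     early_stopping_rounds = 50L, variant = c("depthwise",
                                                              "lossguide")) {
  variant <- match.arg(variant)
  params <- list(objective = "multi:softprob", num_class = num_class,
                 max_depth = config$max_depth, eta = config$learning_rate,
                 gamma = config$gamma, tree_method = "hist",
                 nthread = 1L, seed = as.integer(seed) %% .Machine$integer.max)
  if (variant == "lossguide") {
    params$grow_policy <- "lossguide"
    params$max_leaves <- 2L^config$max_depth
  }
  nrounds <- config$n_estimators
  if (!is.null(early_stopping_rounds) && nrow(X) >= 4L * num_class) {
    # carve a 10% stratified validation split out of the training data
    val <- integer(0)
    with_seed(seed + 77L, {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        if (length(idx) >= 4L) val <- c(val, sample(idx, max(1L,
                                          floor(0.1 * length(idx)))))
      }
    })
    tr <- setdiff(seq_len(nrow(X)), val)
    dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
    dva <- xgboost::xgb.DMatrix(X[val, , drop = FALSE], label = y[val])
    fit <- xgboost::xgb.train(params, dtr, nrounds = nrounds,
                              evals = list(val = dva),
                              early_stopping_rounds = early_stopping_rounds,
                              verbose = 0)
  } else {
    fit <- xgboost::xgb.train(params,
                              xgboost::xgb.DMatrix(X, label = y),
                              nrounds = nrounds, verbose = 0)
  }
  fit
}

# multinomial naive Bayes with Laplace smoothing on sparse counts;
# no installed package offers the multinomial variant
fit_multinomial_nb <- function(X, y, num_class, alpha = 1) {
  V <- ncol(X)
  feat_log_prob <- matrix(0, num_class, V)
  class_log_prior <- numeric(num_class)
  for (c in seq_len(num_class) - 1L) {
    rows <- which(y == c)
    counts <- if (length(rows)) Matrix::colSums(X[rows, , drop = FALSE]) else
      numeric(V)
    feat_log_prob[c + 1L, ] <- log(counts + alpha) - log(sum(counts) +
                                                           alpha * V)
    class_log_prior[c + 1L] <- log(max(length(rows), .Machine$double.xmin) /
                                     length(y))
  }
  structure(list(feat_log_prob = feat_log_prob,
                 class_log_prior = class_log_prior, alpha = alpha),
            class = "multinomial_nb")
}

fit_random_forest <- function(X, y, num_class, seed = 1L, num_trees = 500L) {
  ranger::ranger(x = as.matrix(X),
                 y = factor(y, levels = seq_len(num_class) - 1L),
                 probability = TRUE, num.trees = num_trees,
                 seed = as.integer(seed), num.threads = 1L)
}

# n x num_class probability matrix, rows summing to 1
predict_proba <- function(fit, X, num_class) {
  if (inherits(fit, "multinomial_nb")) {
    lp <- as.matrix(X %*% t(fit$feat_log_prob))
    lp <- sweep(lp, 2L, fit$class_log_prior, `+`)
    lp <- lp - apply(lp, 1L, max)
    p <- exp(lp)
    return(p / rowSums(p))
  }
  if (inherits(fit, "ranger")) {
    p <- predict(fit, data = as.matrix(X), num.threads = 1L)$predictions
    return(p[, as.character(seq_len(num_class) - 1L), drop = FALSE])
  }
  predict(fit, xgboost::xgb.DMatrix(X))
}

fit_algorithm <- function(algorithm, X, y, num_class, config = gbdt_config(),
                          seed = 1L, early_stopping_rounds = 50L) {
  switch(algorithm,
    gbdt = fit_gbdt(X, y, num_class, config, seed, early_stopping_rounds,
                    variant = "depthwise"),
    gbdt2 = fit_gbdt(X, y, num_class, config, seed, early_stopping_rounds,
                     variant = "lossguide"),
    naive_bayes = fit_multinomial_nb(X, y, num_class),
    random_forest = fit_random_forest(X, y, num_class, seed),
    stop("unknown algorithm '", algorithm,
         "' (expected one of gbdt, gbdt2, naive_bayes, random_forest)")
  )
}

new_model_bundle <- function(algorithm, fit, vocab, label_map, config,
                             cv_report = NULL, search_history = NULL,
                             seed = NA_integer_) {
  structure(list(algorithm = algorithm, fit = fit, vocab = vocab,
                 label_map = label_map, config = config,
                 cv_report = cv_report, search_history = search_history,
                 seed = seed),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat("<model_bundle> ", x$algorithm, ", k=", x$vocab$k, ", ",
      length(x$label_map), " species, V=", length(x$vocab$tokens), "\n",
      sep = "")
  if (!is.null(x$config)) {
    cat("  config:", paste(names(x$config), unlist(x$config), sep = "=",
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Train a baseline classifier with library-default hyperparameters
#'
#' All algorithms consume the identical k-mer count matrix: multinomial
#' naive Bayes, random forest, and the two gradient-boosting variants
#' (`gbdt` = depth-wise trees, `gbdt2` = leaf-wise / lossguide growth).
#'
#' @param train A `barcode_dataset`.
#' @param algorithm One of `"naive_bayes"`, `"random_forest"`, `"gbdt"`,
#'   `"gbdt2"`.
#' @param k k-mer size (default 7).
#' @param config GBDT configuration for the boosting variants.
#' @param seed Integer seed.
#' @return A `model_bundle`.
#' @export
train_baseline <- function(train, algorithm, k = 7L,
                           config = gbdt_config(), seed = 1L) {
  stopifnot(inherits(train, "barcode_dataset"))
  fx <- featurize(train$records$sequence, k = k)
  y <- dataset_labels(train)
  fit <- fit_algorithm(algorithm, fx$matrix, y, length(train$label_map),
                       config = config, seed = seed)
  new_model_bundle(algorithm, fit, fx$vocab, train$label_map, config,
                   seed = seed)
}

#' Predict species for new barcode sequences
#'
#' Each record is tokenized at the bundle's k-mer size, vectorized against
#' the frozen training vocabulary, and scored. Records shorter than k
#' (no tokens at all) are flagged `unclassifiable` rather than silently
#' scored.
#'
#' @param bundle A `model_bundle`.
#' @param records Record data frame (`record_id`, `sequence`; `species`
#'   optional and ignored).
#' @return Data frame with `record_id`, `species` (predicted, `NA` when
#'   unclassifiable), `probability` (of the predicted class), and
#'   `unclassifiable`; the full class-probability matrix (columns named
#'   by species) is attached as attribute `"probabilities"`.
#' @export
predict_species <- function(bundle, records) {
  stopifnot(inherits(bundle, "model_bundle"), nrow(records) >= 1L)
  toks <- kmerize_all(records$sequence, bundle$vocab$k)
  unclassifiable <- lengths(toks) == 0L
  species_by_code <- names(sort(bundle$label_map))
  S <- length(bundle$label_map)
  P <- matrix(NA_real_, nrow(records), S,
              dimnames = list(records$record_id, species_by_code))
  ok <- which(!unclassifiable)
  if (length(ok)) {
    X <- vectorize(toks[ok], bundle$vocab)
    P[ok, ] <- predict_proba(bundle$fit, X, S)
  }
  pred_code <- apply(P, 1L, function(p) if (anyNA(p)) NA_integer_ else
    which.max(p))
  out <- data.frame(
    record_id = records$record_id,
    species = ifelse(is.na(pred_code), NA_character_,
                     species_by_code[pred_code]),
    probability = ifelse(is.na(pred_code), NA_real_,
                         P[cbind(seq_len(nrow(P)),
                                 ifelse(is.na(pred_code), 1L, pred_code))]),
    unclassifiable = unclassifiable,
    stringsAsFactors = FALSE)
  attr(out, "probabilities") <- P
  out
}

#' Evaluate a fitted bundle on a labeled dataset
#'
#' @param bundle A `model_bundle`.
#' @param dataset A labeled `barcode_dataset` (same label map as the
#'   bundle).
#' @return A `metrics_report` (see [metrics_report()]).
#' @export
evaluate_model <- function(bundle, dataset) {
  stopifnot(inherits(dataset, "barcode_dataset"))
  fx <- featurize(dataset$records$sequence, vocab = bundle$vocab)
  y <- dataset_labels(dataset)
  P <- predict_proba(bundle$fit, fx$matrix, length(bundle$label_map))
  metrics_report(y, P)
}
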