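# Hyperparameter search: stratified 5-fold CV as the objective, wrapped
# in Bayesian optimization (random initial design + Gaussian-process
# expected-improvement proposals, or pure random search).

# --- minimal GP regression surrogate (RBF kernel, fixed lengthscale) ---
# Inputs are normalized to [0,1]^d; a small nugget keeps the Cholesky
# stable. Deliberately simple: the search space is 4-dimensional and the
# budget tens of points, where a fixed-lengthscale GP is adequate.

gp_fit <- function(X, y, lengthscale = 0.2, nugget = 1e-6) {
  y_mu <- mean(y)
  y_sd <- max(stats::sd(y), 1e-12)
  ys <- (y - y_mu) / y_sd
  K <- gp_kernel(X, X, lengthscale)
  diag(K) <- diag(K) + nugget
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  list(X = X, L = L, alpha = alpha, y_mu = y_mu, y_sd = y_sd,
       lengthscale = lengthscale)
}

gp_kernel <- function(A, B, lengthscale) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  exp(-pmax(d2, 0) / (2 * lengthscale^2))
}

gp_predict <- function(gp, Xnew) {
  Ks <- gp_kernel(Xnew, gp$X, gp$lengthscale)
  mu <- drop(Ks %*% gp$alpha)
  v <- forwardsolve(t(gp$L), t(Ks))
  var <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = mu * gp$y_sd + gp$y_mu, sd = sqrt(var) * gp$y_sd)
}

# expected improvement over the incumbent best (maximization)
expected_improvement <- function(mu, sd, best) {
  z <- (mu - best) / sd
  (mu - best) * stats::pnorm(z) + sd * stats::dnorm(z)
}

# map a point in [0,1]^4 to a concrete GBDT configuration
unit_to_config <- function(u, space) {
  lin <- function(x, r) r[1] + x * (r[2] - r[1])
  gbdt_config(
    n_estimators = round(lin(u[4], space$n_estimators)),
    max_depth = round(lin(u[1], space$max_depth)),
    gamma = lin(u[2], space$gamma),
    learning_rate = lin(u[3], space$learning_rate))
}

#' Cross-validated objective for one hyperparameter configuration
#'
#' Fits the chosen GBDT variant on each training fold and scores the held
#' fold; the search objective is the mean fold accuracy. Per-fold
#' accuracy, precision, recall, F1 and macro AUROC are returned for
#' reporting.
#'
#' @param X Sparse count matrix; `y` integer labels; `fold` fold ids from
#'   [cv_folds()].
#' @param config A [gbdt_config()].
#' @param seed Engine seed.
#' @param variant `"depthwise"` or `"lossguide"`.
#' @param early_stopping_rounds Early-stopping patience (`NULL` = off).
#' @return List with `objective` (mean CV accuracy) and `folds` (per-fold
#'   metric data frame).
#' @export
cv_score <- function(X, y, fold, config, seed = 1L,
                     variant = "depthwise", early_stopping_rounds = 50L) {
  num_class <- max(y) + 1L
  rows <- lapply(sort(unique(fold)), function(f) {
    tr <- fold != f
    fit <- fit_gbdt(X[tr, , drop = FALSE], y[tr], num_class, config,
                    seed = seed + f, variant = variant,
                    early_stopping_rounds = early_stopping_rounds)
    P <- predict_proba(fit, X[!tr, , drop = FALSE], num_class)
    rep <- suppressWarnings(metrics_report(y[!tr], P,
                                           n_classes = num_class))
    data.frame(fold = f, accuracy = rep$accuracy,
               precision = rep$macro[["precision"]],
               recall = rep$macro[["recall"]], f1 = rep$macro[["f1"]],
               macro_auroc = rep$macro_auc)
  })
  folds <- do.call(rbind, rows)
  list(objective = mean(folds$accuracy), folds = folds)
}

#' Train the best gradient-boosted classifier (CV inside Bayesian search)
#'
#' The training set is featurized at k-mer size `k`; a stratified 5-fold
#' plan (shuffled, `random_state = 2020`) defines the objective — mean
#' fold accuracy — which Bayesian optimization maximizes over `max_depth`
#' in \[5,10\], `gamma` in \[0,1\], `learning_rate` in (0,1\] and
#' `n_estimators` in \[100,400\]. The search runs `budget[1]` random
#' initial points followed by `budget[2]` proposals (expected improvement
#' under a Gaussian-process surrogate, or uniform random when
#' `method = "random"`). Ties on the objective are broken by mean macro
#' AUROC, then by smaller `n_estimators`. The winning configuration is
#' refit on the full training set.
#'
#' @param train A `barcode_dataset`.
#' @param k k-mer size (default 7).
#' @param space Hyperparameter ranges, see [gbdt_space()].
#' @param cv A [cv_plan()].
#' @param budget Integer pair `c(init_points, n_iter)` (default 5, 25).
#' @param seed Master seed: fixes the initial design, the proposal
#'   stream, and the engine seeds.
#' @param method `"ei"` (guided) or `"random"`.
#' @param variant GBDT variant, `"depthwise"` (default) or `"lossguide"`.
#' @param early_stopping_rounds Early-stopping patience (default 50;
#'   `NULL` disables).
#' @param verbose Print per-evaluation progress.
#' @return A `model_bundle` whose `config` is the tuned configuration,
#'   `cv_report` the per-fold metrics of the winner, and
#'   `search_history` one row per evaluated configuration.
#' @export
train_best_classifier <- function(train, k = 7L, space = gbdt_space(),
                                  cv = cv_plan(), budget = c(5L, 25L),
                                  seed = 1L, method = c("ei", "random"),
                                  variant = "depthwise",
                                  early_stopping_rounds = 50L,
                                  verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(train, "barcode_dataset"), length(budget) == 2L,
            budget[1] >= 1L)
  check_space(space)
  fx <- featurize(train$records$sequence, k = k)
  y <- dataset_labels(train)
  fold <- cv_folds(y, cv)
  n_total <- budget[1] + budget[2]
  U <- matrix(NA_real_, n_total, 4L)
  history <- vector("list", n_total)
  objective <- rep(-Inf, n_total)

  propose_random <- function() runif(4)
  with_seed(seed, {
    for (t in seq_len(n_total)) {
      if (t <= budget[1] || method == "random") {
        u <- propose_random()
      } else {
        done <- which(is.finite(objective[seq_len(t - 1L)]))
        if (length(done) < 2L) {
          u <- propose_random()
        } else {
          gp <- gp_fit(U[done, , drop = FALSE], objective[done])
          cand <- matrix(runif(4L * 500L), ncol = 4L)
          pr <- gp_predict(gp, cand)
          ei <- expected_improvement(pr$mean, pr$sd, max(objective[done]))
          u <- cand[which.max(ei), ]
        }
      }
      U[t, ] <- u
      config <- unit_to_config(u, space)
      res <- tryCatch(
        cv_score(fx$matrix, y, fold, config, seed = seed,
                 variant = variant,
                 early_stopping_rounds = early_stopping_rounds),
        error = function(e) {
          warning("configuration scored -Inf (", conditionMessage(e), ")",
                  call. = FALSE)
          NULL
        })
      if (!is.null(res) && is.finite(res$objective)) {
        objective[t] <- res$objective
        history[[t]] <- data.frame(iteration = t, config,
                                   cv_accuracy = res$objective,
                                   cv_macro_auroc = mean(res$folds$macro_auroc))
      } else {
        history[[t]] <- data.frame(iteration = t, config,
                                   cv_accuracy = NA_real_,
                                   cv_macro_auroc = NA_real_)
      }
      if (verbose) {
        message(sprintf("eval %02d/%d: acc=%.4f (best %.4f)", t, n_total,
                        objective[t], max(objective[seq_len(t)])))
      }
    }
  })
  history <- do.call(rbind, history)
  best <- best_iteration(objective, split(history, history$iteration),
                         n_total)
  if (!is.finite(objective[best])) {
    stop("hyperparameter search failed on every configuration")
  }
  best_config <- unit_to_config(U[best, ], space)
  # make sure the stored fold report matches the winner
  winner <- cv_score(fx$matrix, y, fold, best_config, seed = seed,
                     variant = variant,
                     early_stopping_rounds = early_stopping_rounds)
  fit <- fit_gbdt(fx$matrix, y, length(train$label_map), best_config,
                  seed = seed, variant = variant,
                  early_stopping_rounds = early_stopping_rounds)
  bundle <- new_model_bundle(if (variant == "lossguide") "gbdt2" else "gbdt",
                             fit, fx$vocab, train$label_map, best_config,
                             cv_report = winner$folds,
                             search_history = history, seed = seed)
  bundle$cv_accuracy <- winner$objective
  bundle$fold_assignment <- fold
  bundle
}

# argmax of objective with ties broken by mean macro AUROC then by
# smaller n_estimators
best_iteration <- function(objective, history_rows, upto) {
  idx <- seq_len(upto)
  top <- idx[is.finite(objective[idx]) &
               objective[idx] == max(objective[idx], na.rm = TRUE)]
  if (length(top) == 1L) return(top)
  aur <- vapply(top, function(i) {
    h <- history_rows[[i]]
    if (is.null(h)) -Inf else h$cv_macro_auroc[1]
  }, numeric(1))
  top <- top[aur == max(aur)]
  if (length(top) == 1L) return(top)
  nest <- vapply(top, function(i) history_rows[[i]]$n_estimators[1],
                 numeric(1))
  top[which.min(nest)]
}

check_space <- function(space) {
  full <- gbdt_space()
  for (nm in names(full)) {
    stopifnot(nm %in% names(space))
    if (space[[nm]][1] < full[[nm]][1] || space[[nm]][2] > full[[nm]][2]) {
      stop("search range for ", nm, " outside the declared bounds [",
           full[[nm]][1], ", ", full[[nm]][2], "]")
    }
  }
  invisible(space)
}

#' Sweep k-mer sizes and algorithms
#'
#' Trains one model per (algorithm, k) cell on a stratified train split
#' and scores accuracy and macro AUROC on the holdout. Boosting cells use
#' `config`; baselines use library defaults. A failing cell is recorded
#' as `NA` with a warning rather than aborting the sweep.
#'
#' @param dataset A `barcode_dataset`.
#' @param k_values Integer vector of k-mer sizes (3..10 is the supported
#'   range).
#' @param algorithms Subset of `c("naive_bayes", "random_forest", "gbdt",
#'   "gbdt2")`.
#' @param test_fraction Holdout fraction (default 0.2).
#' @param seed Seed shared by every cell (same split throughout).
#' @param config GBDT configuration for boosting cells.
#' @param path Optional TSV output path.
#' @return Data frame `algorithm`, `k`, `accuracy`, `macro_auroc`; the
#'   best cell (max accuracy, ties by AUROC) is attached as attribute
#'   `"best"`.
#' @export
kmer_sweep <- function(dataset, k_values = 3:10,
                       algorithms = c("naive_bayes", "random_forest",
                                      "gbdt", "gbdt2"),
                       test_fraction = 0.2, seed = 1L,
                       config = gbdt_config(), path = NULL) {
  stopifnot(length(k_values) >= 1L)
  parts <- split_train_test(dataset, test_fraction, seed)
  grid <- expand.grid(algorithm = algorithms, k = k_values,
                      stringsAsFactors = FALSE)
  grid$accuracy <- NA_real_
  grid$macro_auroc <- NA_real_
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      bundle <- train_baseline(parts$train, grid$algorithm[i],
                               k = grid$k[i], config = config, seed = seed)
      rep <- suppressWarnings(evaluate_model(bundle, parts$test))
      c(rep$accuracy, rep$macro_auc)
    }, error = function(e) {
      warning("sweep cell (", grid$algorithm[i], ", k=", grid$k[i],
              ") failed: ", conditionMessage(e), call. = FALSE)
      c(NA_real_, NA_real_)
    })
    grid$accuracy[i] <- res[1]
    grid$macro_auroc[i] <- res[2]
  }
  ok <- which(!is.na(grid$accuracy))
  if (length(ok)) {
    best <- ok[order(-grid$accuracy[ok], -grid$macro_auroc[ok])][1]
    attr(grid, "best") <- grid[best, c("algorithm", "k"), drop = FALSE]
  }
  if (!is.null(path)) {
    write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  grid
}
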