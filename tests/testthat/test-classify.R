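test_that("stratified split partitions the data reproducibly", {
  sim <- easy_sim(n_species = 3L, counts = 10L)
  p1 <- split_train_test(sim$dataset, 0.2, seed = 5L)
  p2 <- split_train_test(sim$dataset, 0.2, seed = 5L)
  expect_identical(p1$test$records$record_id, p2$test$records$record_id)
  # exactly 2 of 10 per class in the test set
  expect_equal(unname(table(p1$test$records$species)), rep(2L, 3),
               ignore_attr = TRUE)
  # partition: union is the input, intersection empty
  all_ids <- c(p1$train$records$record_id, p1$test$records$record_id)
  expect_setequal(all_ids, sim$dataset$records$record_id)
  expect_length(intersect(p1$train$records$record_id,
                          p1$test$records$record_id), 0L)
  # both halves keep the full label map
  expect_identical(p1$train$label_map, sim$dataset$label_map)
})

test_that("singleton classes make the split fail loudly", {
  rec <- rbind(records_from_counts("Sp_a", 5L),
               data.frame(record_id = "solo", species = "Sp_b",
                          sequence = "ACGTACGTACGT"))
  ds <- filter_min_count(rec, 0L)
  expect_error(split_train_test(ds, 0.2, 1L), "single record")
})

test_that("cross-validation folds are a stratified partition", {
  set.seed(10)
  y <- rep(0:3, times = c(23, 11, 7, 5))
  fold <- cv_folds(y, cv_plan(n_splits = 5L))
  expect_setequal(unique(fold), 1:5)
  expect_length(fold, length(y))
  for (cls in 0:3) {
    per_fold <- tabulate(fold[y == cls], 5L)
    expect_lte(diff(range(per_fold)), 1L)  # within one record per fold
  }
  # the plan's random_state fixes the assignment
  expect_identical(fold, cv_folds(y, cv_plan()))
  expect_false(identical(fold, cv_folds(y, cv_plan(random_state = 7L))))
})

test_that("all four algorithms consume the identical count matrix", {
  sim <- easy_sim(n_species = 2L, counts = 8L, within_noise = 0)
  parts <- split_train_test(sim$dataset, 0.25, seed = 2L)
  for (alg in c("naive_bayes", "random_forest", "gbdt", "gbdt2")) {
    bundle <- train_baseline(parts$train, alg, k = 5L, seed = 2L)
    rep <- suppressWarnings(evaluate_model(bundle, parts$test))
    # noiseless two-species fixture is trivially separable
    expect_equal(rep$accuracy, 1, info = alg)
  }
  expect_error(train_baseline(parts$train, "svm"), "unknown algorithm")
})

test_that("multinomial naive Bayes matches the closed-form posterior", {
  # two classes, two tokens; Laplace alpha = 1
  X <- Matrix::sparseMatrix(i = c(1, 1, 2, 2), j = c(1, 2, 1, 2),
                            x = c(3, 1, 1, 3), dims = c(2, 2))
  y <- c(0L, 1L)
  nb <- barcodeboost:::fit_multinomial_nb(X, y, 2L, alpha = 1)
  # class 0: token counts (3,1) -> p = (4/6, 2/6); class 1: (2/6, 4/6)
  expect_equal(exp(nb$feat_log_prob[1, ]), c(4, 2) / 6)
  expect_equal(exp(nb$feat_log_prob[2, ]), c(2, 4) / 6)
  # query with counts (2, 0): posterior odds = prior-equal, so
  # P(0|x)/P(1|x) = (4/6)^2 / (2/6)^2 = 4
  Xq <- Matrix::sparseMatrix(i = 1, j = 1, x = 2, dims = c(1, 2))
  P <- barcodeboost:::predict_proba(nb, Xq, 2L)
  expect_equal(P[1, 1] / P[1, 2], 4)
  expect_equal(rowSums(P), 1)
})

test_that("search stays in the declared ranges and is seed-deterministic", {
  sim <- easy_sim(n_species = 3L, counts = 8L)
  parts <- split_train_test(sim$dataset, 0.25, seed = 3L)
  b1 <- train_best_classifier(parts$train, k = 5L, budget = c(2L, 2L),
                              seed = 3L, cv = cv_plan(n_splits = 3L))
  b2 <- train_best_classifier(parts$train, k = 5L, budget = c(2L, 2L),
                              seed = 3L, cv = cv_plan(n_splits = 3L))
  expect_identical(b1$config, b2$config)
  expect_identical(b1$fold_assignment, b2$fold_assignment)
  expect_equal(b1$search_history$cv_accuracy, b2$search_history$cv_accuracy)

  space <- gbdt_space()
  h <- b1$search_history
  expect_true(all(h$max_depth >= space$max_depth[1] &
                    h$max_depth <= space$max_depth[2]))
  expect_true(all(h$max_depth == round(h$max_depth)))
  expect_true(all(h$gamma >= 0 & h$gamma <= 1))
  expect_true(all(h$learning_rate > 0 & h$learning_rate <= 1))
  expect_true(all(h$n_estimators >= 100 & h$n_estimators <= 400))
  expect_true(all(h$n_estimators == round(h$n_estimators)))
  # the winner's CV accuracy is the maximum over the history
  expect_equal(b1$cv_accuracy, max(h$cv_accuracy, na.rm = TRUE))
  # a range outside the declared bounds is rejected
  bad <- space; bad$max_depth <- c(5, 50)
  expect_error(train_best_classifier(parts$train, space = bad), "bounds")
})

test_that("best-so-far objective is non-decreasing over iterations", {
  sim <- easy_sim(n_species = 3L, counts = 8L, within_noise = 0.05)
  parts <- split_train_test(sim$dataset, 0.25, seed = 9L)
  b <- train_best_classifier(parts$train, k = 4L, budget = c(3L, 3L),
                             seed = 9L, cv = cv_plan(n_splits = 3L))
  running <- cummax(b$search_history$cv_accuracy)
  expect_true(all(diff(running) >= 0))
})

test_that("prediction decodes labels, normalizes, and flags short queries", {
  sim <- easy_sim(n_species = 3L, counts = 10L, within_noise = 0)
  parts <- split_train_test(sim$dataset, 0.2, seed = 1L)
  bundle <- train_baseline(parts$train, "gbdt", k = 5L, seed = 1L)
  queries <- rbind(parts$train$records[1:3, ],
                   data.frame(record_id = "short", species = NA,
                              sequence = "ACG"))
  pred <- predict_species(bundle, queries)
  # training sequences replay to their own species on a separable fixture
  expect_equal(pred$species[1:3], parts$train$records$species[1:3])
  expect_true(pred$unclassifiable[4])
  expect_true(is.na(pred$species[4]))
  P <- attr(pred, "probabilities")
  expect_equal(rowSums(P[1:3, ]), rep(1, 3), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("model bundles round-trip through their directory layout", {
  sim <- easy_sim(n_species = 3L, counts = 8L, within_noise = 0)
  parts <- split_train_test(sim$dataset, 0.25, seed = 4L)
  bundle <- train_baseline(parts$train, "gbdt", k = 5L, seed = 4L)
  dir <- withr::local_tempdir()
  save_model_bundle(bundle, dir)
  expect_true(all(file.exists(file.path(dir, c("model.ubj",
                                               "vocabulary.txt",
                                               "label_map.tsv",
                                               "config.json")))))
  back <- load_model_bundle(dir)
  p1 <- predict_species(bundle, parts$test$records)
  p2 <- predict_species(back, parts$test$records)
  expect_equal(p1$species, p2$species)
  expect_equal(attr(p1, "probabilities"), attr(p2, "probabilities"),
               tolerance = 1e-6)
})

test_that("sweep evaluates every (algorithm, k) cell and finds the best", {
  sim <- easy_sim(n_species = 3L, counts = 10L, within_noise = 0.01)
  res <- kmer_sweep(sim$dataset, k_values = c(3L, 5L),
                    algorithms = c("naive_bayes", "gbdt"),
                    test_fraction = 0.2, seed = 6L)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1, na.rm = TRUE))
  expect_true(all(res$macro_auroc >= 0 & res$macro_auroc <= 1,
                  na.rm = TRUE))
  best <- attr(res, "best")
  expect_s3_class(best, "data.frame")
  best_row <- res[res$algorithm == best$algorithm & res$k == best$k, ]
  expect_equal(best_row$accuracy, max(res$accuracy, na.rm = TRUE))
  # single-cell sweep equals direct evaluation of that model
  single <- kmer_sweep(sim$dataset, k_values = 5L, algorithms = "gbdt",
                       test_fraction = 0.2, seed = 6L)
  parts <- split_train_test(sim$dataset, 0.2, seed = 6L)
  direct <- suppressWarnings(evaluate_model(
    train_baseline(parts$train, "gbdt", k = 5L, seed = 6L), parts$test))
  expect_equal(single$accuracy, direct$accuracy)
  expect_equal(single$macro_auroc, direct$macro_auc)
})
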