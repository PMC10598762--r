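# pairwise-concordance AUROC oracle: P(score_pos > score_neg) + 0.5 ties
auc_concordance <- function(labels, scores) {
  pos <- scores[labels]
  neg <- scores[!labels]
  pairs <- outer(pos, neg, `-`)
  (sum(pairs > 0) + 0.5 * sum(pairs == 0)) / length(pairs)
}

test_that("one-vs-rest confusion counts are tallied correctly", {
  expect_equal(confusion(c(1, 1, 0, 0), c(1, 0, 0, 0), 1),
               list(TP = 1L, FN = 1L, FP = 0L, TN = 2L))
  same <- confusion(c(2, 0, 1), c(2, 0, 1), 2)
  expect_equal(same$FP + same$FN, 0L)
  # swapping positive/negative swaps (TP,FN) <-> (TN,FP) in a 2-class task
  a <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0), 1)
  b <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0), 0)
  expect_equal(list(a$TP, a$FN), list(b$TN, b$FP))
  expect_error(confusion(1:3, 1:2, 1), "length")
})

test_that("scalar metrics match closed-form fractions", {
  m <- scalar_metrics(list(TP = 1L, FN = 1L, FP = 0L, TN = 2L))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 1)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1)
  expect_equal(m$fpr, 0)
  expect_equal(m$f1, 2 / 3)

  perfect <- scalar_metrics(list(TP = 5L, FN = 0L, FP = 0L, TN = 5L))
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity",
                                   "specificity", "precision",
                                   "f1")]) == 1))
  expect_equal(perfect$fpr, 0)

  # precision == recall == p implies F1 == p (harmonic-mean identity)
  m2 <- scalar_metrics(list(TP = 3L, FN = 1L, FP = 1L, TN = 5L))
  expect_equal(m2$precision, m2$sensitivity)
  expect_equal(m2$f1, m2$precision)

  expect_warning(scalar_metrics(list(TP = 0L, FN = 0L, FP = 2L, TN = 2L)),
                 "zero-denominator")
  expect_error(scalar_metrics(list(TP = 0L, FN = 0L, FP = 0L, TN = 0L)))
})

test_that("OvR AUROC matches the pairwise-concordance oracle", {
  set.seed(41)
  y <- rep(0:2, each = 4)                       # 12-sample 3-class toy
  P <- matrix(runif(36), 12, 3)
  P <- P / rowSums(P)
  roc <- ovr_roc(y, P)
  for (j in 1:3) {
    expect_equal(roc$auc[[j]], auc_concordance(y == j - 1, P[, j]))
  }
  expect_equal(roc$macro_auc, mean(roc$auc))
})

test_that("AUROC hits the degenerate endpoints and handles ties", {
  y <- c(0L, 0L, 1L, 1L)
  perfect <- cbind(c(.9, .8, .1, .2), c(.1, .2, .9, .8))
  expect_equal(ovr_roc(y, perfect)$auc, c(1, 1), ignore_attr = TRUE)
  constant <- matrix(0.5, 4, 2)
  expect_equal(ovr_roc(y, constant)$auc, c(0.5, 0.5), ignore_attr = TRUE)
  # for binary problems the two per-class OvR AUROCs coincide
  set.seed(8)
  p1 <- runif(20)
  P <- cbind(p1, 1 - p1)
  yb <- rbinom(20, 1, 0.5)
  r <- ovr_roc(yb, P)
  expect_equal(r$auc[[1]], r$auc[[2]])
})

test_that("AUROC is invariant under strictly monotone score transforms", {
  set.seed(13)
  y <- rbinom(30, 1, 0.5)
  p <- runif(30)
  base <- ovr_roc(y, cbind(1 - p, p))$auc
  # strictly increasing maps of the positive-class score
  for (g in list(function(x) x^3, function(x) stats::plogis(5 * x - 2),
                 function(x) sqrt(x))) {
    q <- g(p)
    transformed <- ovr_roc(y, cbind(1 - q, q))$auc
    expect_equal(transformed, base, ignore_attr = TRUE)
  }
})

test_that("ovr_roc validates inputs and flags absent classes", {
  y <- c(0L, 0L, 1L, 1L)
  bad <- matrix(1, 4, 2)
  expect_error(ovr_roc(y, bad), "sum to 1")
  P <- matrix(runif(9), 3, 3); P <- P / rowSums(P)
  expect_warning(r <- ovr_roc(c(0L, 0L, 1L), P), "absent")
  expect_true(is.na(r$auc[[3]]))
  expect_equal(r$macro_auc, mean(r$auc[1:2]))
})

test_that("ovr_roc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  y <- sample(0:1, 40, replace = TRUE)
  p1 <- runif(40)
  ours <- ovr_roc(y, cbind(1 - p1, p1))$auc[[2]]
  theirs <- as.numeric(pROC::auc(pROC::roc(y, p1, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs)
})

test_that("multiclass report aggregates per-class metrics", {
  y <- c(0L, 0L, 1L, 1L, 2L, 2L)
  pred <- c(0L, 1L, 1L, 1L, 2L, 0L)
  rep <- metrics_report(y, y_pred = pred, n_classes = 3L)
  expect_equal(rep$accuracy, 4 / 6)  # raw-label accuracy, not an OvR mean
  expect_equal(rep$per_class$recall, c(0.5, 1, 0.5))
  expect_equal(rep$macro[["recall"]], 2 / 3)
  expect_equal(rep$weighted[["recall"]], 2 / 3)  # balanced support
  expect_equal(rep$per_class$fpr, 1 - rep$per_class$specificity)

  # with probabilities: argmax predictions and AUROC columns
  set.seed(3)
  P <- matrix(runif(18), 6, 3); P <- P / rowSums(P)
  rep2 <- suppressWarnings(metrics_report(y, P))  # random argmax may skip a class
  expect_equal(rep2$accuracy, mean(max.col(P) - 1L == y))
  expect_true(all(rep2$per_class$auroc >= 0 & rep2$per_class$auroc <= 1))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_metrics_report(rep2, tsv)
  tab <- read.delim(tsv)
  expect_equal(nrow(tab), 5L)  # 3 classes + macro + weighted
  expect_equal(tab$accuracy[tab$class == "macro"], rep2$accuracy)
})

test_that("macro_average is the unweighted mean", {
  expect_equal(macro_average(c(0.7, 0.7, 0.7)), 0.7)
  expect_equal(macro_average(c(0, 1)), 0.5)
  set.seed(6)
  v <- runif(11)
  expect_equal(macro_average(v), sum(v) / length(v))
})
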