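# Performance metrics: one-vs-rest confusion counts, scalar metrics
# (accuracy, sensitivity, specificity, FPR, precision, F1), per-class ROC
# curves with trapezoidal AUC, and macro averaging.

#' One-vs-rest confusion counts for a single positive class
#'
#' Labels are binarized against `positive_class` (everything else is
#' negative) and tallied into the standard 2x2 table.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param positive_class The class treated as positive.
#' @return Named list with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(y_true, y_pred, positive_class) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred differ in length (", length(y_true), " vs ",
         length(y_pred), ")")
  }
  tp <- y_true == positive_class
  pp <- y_pred == positive_class
  list(TP = sum(tp & pp), FN = sum(tp & !pp),
       FP = sum(!tp & pp), TN = sum(!tp & !pp))
}

#' Scalar metrics from one-vs-rest confusion counts
#'
#' accuracy = (TP+TN)/N, sensitivity (recall/TPR) = TP/(TP+FN),
#' specificity = TN/(TN+FP), FPR = 1 - specificity,
#' precision = TP/(TP+FP), F1 = 2PR/(P+R). Zero-denominator cases return
#' 0 and set the `degenerate` flag.
#'
#' @param counts Output of [confusion()].
#' @return Named list of the six metrics plus a logical `degenerate`.
#' @export
scalar_metrics <- function(counts) {
  n <- counts$TP + counts$TN + counts$FP + counts$FN
  if (n == 0L) stop("all-zero confusion counts")
  safe_div <- function(num, den) if (den > 0) num / den else 0
  degenerate <- (counts$TP + counts$FN) == 0L ||
    (counts$TN + counts$FP) == 0L || (counts$TP + counts$FP) == 0L
  if (degenerate) {
    warning("zero-denominator metric(s) reported as 0", call. = FALSE)
  }
  sens <- safe_div(counts$TP, counts$TP + counts$FN)
  spec <- safe_div(counts$TN, counts$TN + counts$FP)
  prec <- safe_div(counts$TP, counts$TP + counts$FP)
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  list(accuracy = (counts$TP + counts$TN) / n,
       sensitivity = sens, specificity = spec, fpr = 1 - spec,
       precision = prec, f1 = f1, degenerate = degenerate)
}

# ROC curve for one score vector: thresholds at every distinct score plus
# +/-Inf sentinels, trapezoidal AUC
roc_curve_binary <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  P <- sum(labels)
  N <- sum(!labels)
  if (P == 0L || N == 0L) {
    return(list(fpr = NA_real_, tpr = NA_real_, thresholds = NA_real_,
                auc = NA_real_))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # cumulative counts at each distinct score boundary
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_tie]
  fp <- cumsum(!l)[last_of_tie]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  thresholds <- c(Inf, s[last_of_tie])
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = thresholds, auc = auc)
}

#' One-vs-rest ROC curves and AUROC for multiclass probabilities
#'
#' For each class c, the ROC curve of P(class = c) against the binarized
#' truth (c vs rest) is traced over all distinct scores, and its area
#' computed by the trapezoidal rule. The macro AUROC is the unweighted
#' mean over classes present in `y_true`; a class absent from `y_true`
#' gets `NA` and is excluded with a warning.
#'
#' @param y_true Integer class labels `0..S-1`.
#' @param class_probabilities n x S probability matrix (rows sum to 1
#'   within `tol`); column j holds P(class = j-1).
#' @param tol Row-sum tolerance (default 1e-6).
#' @return List with `per_class` (list of ROC curves with `auc`), `auc`
#'   (named per-class vector), and `macro_auc`.
#' @export
ovr_roc <- function(y_true, class_probabilities, tol = 1e-6) {
  P <- as.matrix(class_probabilities)
  stopifnot(nrow(P) == length(y_true), ncol(P) >= 2L)
  if (any(abs(rowSums(P) - 1) > tol)) {
    stop("probability rows must sum to 1 (tolerance ", tol, ")")
  }
  S <- ncol(P)
  per_class <- vector("list", S)
  auc <- setNames(rep(NA_real_, S), colnames(P))
  for (j in seq_len(S)) {
    cls <- j - 1L
    per_class[[j]] <- roc_curve_binary(y_true == cls, P[, j])
    auc[j] <- per_class[[j]]$auc
  }
  if (anyNA(auc)) {
    warning("class(es) absent from y_true excluded from macro AUROC: ",
            paste(which(is.na(auc)) - 1L, collapse = ", "), call. = FALSE)
  }
  list(per_class = per_class, auc = auc,
       macro_auc = macro_average(auc[!is.na(auc)]))
}

#' Unweighted macro average of per-class scores
#'
#' @param per_class_scores Nonempty numeric vector.
#' @return Arithmetic mean.
#' @export
macro_average <- function(per_class_scores) {
  stopifnot(length(per_class_scores) >= 1L)
  mean(per_class_scores)
}

#' Full multiclass metrics report
#'
#' Multiclass accuracy is computed on the raw labels; per-class
#' precision/recall/specificity/FPR/F1 come from one-vs-rest reductions,
#' aggregated both macro (unweighted, the default headline) and weighted
#' (by class support). Per-class OvR AUROC and the macro AUROC are
#' included when `class_probabilities` is given.
#'
#' @param y_true Integer labels `0..S-1`.
#' @param class_probabilities Optional n x S probability matrix; when
#'   supplied, predictions are its row-wise argmax.
#' @param y_pred Optional hard predictions (required when no probability
#'   matrix is given).
#' @param n_classes Number of classes (default: inferred).
#' @return A `metrics_report`: list with `accuracy`, `per_class` data
#'   frame, `macro`/`weighted` aggregate rows, `auc`, `macro_auc`, `roc`.
#' @export
metrics_report <- function(y_true, class_probabilities = NULL,
                           y_pred = NULL, n_classes = NULL) {
  if (is.null(y_pred)) {
    stopifnot(!is.null(class_probabilities))
    y_pred <- max.col(as.matrix(class_probabilities), ties.method = "first") - 1L
  }
  if (is.null(n_classes)) {
    n_classes <- if (!is.null(class_probabilities))
      ncol(class_probabilities) else max(y_true, y_pred) + 1L
  }
  per <- lapply(seq_len(n_classes) - 1L, function(cls) {
    m <- scalar_metrics(confusion(y_true, y_pred, cls))
    data.frame(class = cls, support = sum(y_true == cls),
               precision = m$precision, recall = m$sensitivity,
               specificity = m$specificity, fpr = m$fpr, f1 = m$f1)
  })
  per <- do.call(rbind, per)
  roc <- NULL
  auc <- NULL
  macro_auc <- NA_real_
  if (!is.null(class_probabilities)) {
    roc <- ovr_roc(y_true, class_probabilities)
    auc <- roc$auc
    macro_auc <- roc$macro_auc
    per$auroc <- unname(auc)
  }
  present <- per$support > 0
  agg <- function(w) {
    cols <- c("precision", "recall", "specificity", "fpr", "f1",
              if (!is.null(auc)) "auroc")
    vapply(cols, function(col) {
      v <- per[[col]][present]
      ok <- !is.na(v)
      sum(v[ok] * w[ok]) / sum(w[ok])
    }, numeric(1))
  }
  structure(list(
    accuracy = mean(y_true == y_pred),
    per_class = per,
    macro = agg(rep(1, sum(present))),
    weighted = agg(per$support[present]),
    auc = auc, macro_auc = macro_auc, roc = roc,
    n = length(y_true)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("<metrics_report> n=", x$n, "\n", sep = "")
  cat("  accuracy:    ", round(x$accuracy, digits), "\n", sep = "")
  if (!is.na(x$macro_auc)) {
    cat("  macro AUROC: ", round(x$macro_auc, digits), "\n", sep = "")
  }
  cat("  macro P/R/F1: ",
      paste(round(x$macro[c("precision", "recall", "f1")], digits),
            collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' Write a metrics report as TSV
#'
#' One row per class plus `macro` and `weighted` aggregate rows, in the
#' column order AUROC, accuracy, precision, recall, F1 (plus
#' specificity/FPR/support).
#'
#' @param report A `metrics_report`.
#' @param path Output TSV path.
#' @param roc_dir Optional directory for per-class ROC curve points
#'   (one TSV per class: `threshold`, `fpr`, `tpr`).
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path, roc_dir = NULL) {
  per <- report$per_class
  rows <- data.frame(class = as.character(per$class),
                     auroc = if ("auroc" %in% names(per)) per$auroc else NA,
                     accuracy = NA_real_,
                     precision = per$precision, recall = per$recall,
                     f1 = per$f1, specificity = per$specificity,
                     fpr = per$fpr, support = per$support,
                     stringsAsFactors = FALSE)
  add <- function(name, v) data.frame(class = name,
    auroc = if ("auroc" %in% names(v)) v[["auroc"]] else NA,
    accuracy = report$accuracy, precision = v[["precision"]],
    recall = v[["recall"]], f1 = v[["f1"]],
    specificity = v[["specificity"]], fpr = v[["fpr"]],
    support = sum(per$support), stringsAsFactors = FALSE)
  rows <- rbind(rows, add("macro", report$macro), add("weighted",
                                                      report$weighted))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(roc_dir) && !is.null(report$roc)) {
    dir.create(roc_dir, showWarnings = FALSE, recursive = TRUE)
    for (j in seq_along(report$roc$per_class)) {
      rc <- report$roc$per_class[[j]]
      if (all(is.na(rc$auc))) next
      write.table(data.frame(threshold = rc$thresholds, fpr = rc$fpr,
                             tpr = rc$tpr),
                  file.path(roc_dir, sprintf("roc_class_%02d.tsv", j - 1L)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
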