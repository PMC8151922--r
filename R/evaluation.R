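#' Confusion matrix in canonical class order
#'
#' Rows are true classes, columns predicted, both ordered
#' normal / mild_moderate / severe.
#'
#' @param truth,predicted Vectors of class labels, equal length.
#' @return 3 x 3 integer matrix.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop_renotex("truth and predicted must have equal length",
                 class = "renotex_eval_error")
  truth <- as.character(truth); predicted <- as.character(predicted)
  bad <- setdiff(unique(c(truth, predicted)), CLASS_LEVELS)
  if (length(bad) > 0)
    stop_renotex("unknown class label(s): %s", paste(bad, collapse = ", "),
                 class = "renotex_eval_error")
  tab <- table(factor(truth, CLASS_LEVELS), factor(predicted, CLASS_LEVELS))
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(truth = CLASS_LEVELS, predicted = CLASS_LEVELS))
  m
}

#' Classification and misclassification rates
#'
#' `100 * trace / total` percent; the misclassification rate is its
#' complement to 100.
#'
#' @param cm A [confusion_matrix()].
#' @return Named list with `classification_rate` and
#'   `misclassification_rate`, both in percent.
#' @export
classification_rate <- function(cm) {
  total <- sum(cm)
  if (total == 0)
    stop_renotex("cannot compute rates of an empty confusion matrix",
                 class = "renotex_eval_error")
  rate <- 100 * sum(diag(cm)) / total
  list(classification_rate = rate, misclassification_rate = 100 - rate)
}

#' One-vs-rest ROC curve and trapezoidal AUC
#'
#' Threshold sweep over the distinct scores of the positive class, ties
#' grouped (each distinct score contributes one ROC vertex, merging the
#' horizontal and vertical steps), points running from (0, 0) to (1, 1).
#' The trapezoidal AUC then equals the Mann-Whitney concordance with ties
#' counted one half.
#'
#' @param scores Numeric vector (or the positive-class column of a
#'   probability matrix) of scores, higher = more positive.
#' @param truth Vector of class labels.
#' @param positive_class The class treated as positive.
#' @return List with `points` (data frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_one_vs_rest <- function(scores, truth, positive_class) {
  if (is.matrix(scores)) scores <- scores[, positive_class]
  truth <- as.character(truth)
  if (length(scores) != length(truth))
    stop_renotex("scores and truth must have equal length",
                 class = "renotex_eval_error")
  pos <- truth == positive_class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop_renotex("AUC undefined: class '%s' absent from truth or no negatives",
                 positive_class, class = "renotex_eval_error")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & pos), 0) / n_pos)
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & !pos), 0) / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr,
                           threshold = c(Inf, thr)),
       auc = auc)
}

#' Evaluate a trained network on one partition
#'
#' Produces the full report: confusion matrix, classification and
#' misclassification rates, and the three one-vs-rest ROC curves with AUC.
#'
#' @param net A [train_network()] result.
#' @param tab The `feature_table` it was trained on (or a compatible one).
#' @param partition `"train"`, `"val"`, `"test"` or `"all"`.
#' @return Object of class `eval_report`.
#' @export
evaluate_network <- function(net, tab, partition = "test") {
  stopifnot(inherits(net, "trained_network"))
  idx <- if (partition == "all") seq_len(nrow(tab)) else
    which(net$split[tab$id] == partition)
  if (length(idx) == 0)
    stop_renotex("partition '%s' holds no records", partition,
                 class = "renotex_eval_error")
  sub <- tab[idx, , drop = FALSE]
  class(sub) <- class(tab)
  proba <- predict_proba(net, sub)
  pred <- CLASS_LEVELS[max.col(proba, ties.method = "first")]
  cm <- confusion_matrix(sub$label, pred)
  rates <- classification_rate(cm)
  roc <- list()
  for (cls in CLASS_LEVELS) {
    roc[[cls]] <- if (cls %in% sub$label)
      roc_one_vs_rest(proba[, cls], sub$label, cls) else NULL
  }
  structure(list(partition = partition, n = length(idx), confusion = cm,
                 classification_rate = rates$classification_rate,
                 misclassification_rate = rates$misclassification_rate,
                 roc = roc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation on partition '%s' (n = %d)\n", x$partition, x$n))
  cat(sprintf("  classification rate   %.1f%%\n", x$classification_rate))
  cat(sprintf("  misclassification     %.1f%%\n", x$misclassification_rate))
  for (cls in names(x$roc))
    if (!is.null(x$roc[[cls]]))
      cat(sprintf("  AUC (%s vs rest)  %.3f\n", cls, x$roc[[cls]]$auc))
  cat("Confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' Full precision; ROC vertex lists included per class.
#'
#' @param report An `eval_report`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  payload <- list(
    partition = report$partition, n = report$n,
    confusion = list(classes = CLASS_LEVELS,
                     counts = unname(apply(report$confusion, 1, as.list))),
    classification_rate = report$classification_rate,
    misclassification_rate = report$misclassification_rate,
    roc = lapply(report$roc, function(r)
      if (is.null(r)) NULL else list(auc = r$auc, points = r$points)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
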