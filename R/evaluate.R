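# Classifier evaluation: confusion matrix, per-class precision/recall with
# normal-approximation confidence intervals, and macro averages over the
# three known classes (unknown excluded).

.prop_ci <- function(p, n) {
  if (is.na(p) || n == 0) return(c(NA_real_, NA_real_))
  half <- 1.96 * sqrt(p * (1 - p) / n)
  c(p - half, p + half)
}

#' Evaluate predicted smoking-status labels against gold labels
#'
#' Per-class precision is TP/(TP+FP) and recall TP/(TP+FN); 95% confidence
#' intervals use the normal approximation p +/- 1.96*sqrt(p(1-p)/n) with n
#' the metric's denominator. A metric with zero denominator is reported as
#' `NA`, never as 0. Macro precision/recall are unweighted means over the
#' three known classes (current, ex, never); because the published
#' weighting of the average recall is ambiguous, a support-weighted mean
#' over the known classes is reported as well. Accuracy is over all four
#' classes. The function is invariant to the order of the sentence pairs.
#'
#' @param gold,predicted equal-length label vectors over the four classes.
#' @return object of class `nlp_evaluation`: list with `confusion` (4 x 4,
#'   rows = gold), `per_class` (data frame with precision/recall and CIs),
#'   `accuracy` (+ CI), `macro_precision_known`, `macro_recall_known`,
#'   `weighted_recall_known`.
#' @export
evaluate <- function(gold, predicted) {
  if (length(gold) != length(predicted))
    stop("gold and predicted must have equal length", call. = FALSE)
  g <- factor(gold, levels = SMOKING_CLASSES)
  p <- factor(predicted, levels = SMOKING_CLASSES)
  if (anyNA(g) || anyNA(p))
    stop("labels must be one of ", paste(SMOKING_CLASSES, collapse = "/"),
         call. = FALSE)
  cm <- table(gold = g, predicted = p)
  per <- data.frame(class = SMOKING_CLASSES, stringsAsFactors = FALSE)
  per$tp <- diag(cm)
  per$support <- rowSums(cm)
  per$assigned <- colSums(cm)
  per$precision <- ifelse(per$assigned > 0, per$tp / per$assigned, NA)
  per$recall <- ifelse(per$support > 0, per$tp / per$support, NA)
  pci <- t(mapply(.prop_ci, per$precision, per$assigned))
  rci <- t(mapply(.prop_ci, per$recall, per$support))
  per$precision_lo <- pci[, 1]; per$precision_hi <- pci[, 2]
  per$recall_lo <- rci[, 1]; per$recall_hi <- rci[, 2]
  n <- length(g)
  acc <- sum(diag(cm)) / n
  known <- per[per$class %in% KNOWN_CLASSES, ]
  wrec <- if (sum(known$support) > 0)
    sum(known$recall * known$support, na.rm = TRUE) / sum(known$support)
  else NA_real_
  structure(list(
    confusion = cm, per_class = per,
    accuracy = acc, accuracy_ci = .prop_ci(acc, n),
    macro_precision_known = mean(known$precision),
    macro_recall_known = mean(known$recall),
    weighted_recall_known = wrec,
    n = n), class = "nlp_evaluation")
}

#' @export
print.nlp_evaluation <- function(x, ...) {
  cat("Confusion matrix (rows = gold):\n")
  print(x$confusion)
  fmt <- function(v) ifelse(is.na(v), "  --", sprintf("%.3f", v))
  cat("\nclass      precision (95% CI)        recall (95% CI)\n")
  for (i in seq_len(nrow(x$per_class))) {
    r <- x$per_class[i, ]
    cat(sprintf("%-9s  %s (%s-%s)   %s (%s-%s)\n", r$class,
                fmt(r$precision), fmt(r$precision_lo), fmt(r$precision_hi),
                fmt(r$recall), fmt(r$recall_lo), fmt(r$recall_hi)))
  }
  cat(sprintf("\naccuracy %.3f (%.3f-%.3f), n = %d\n", x$accuracy,
              x$accuracy_ci[1], x$accuracy_ci[2], x$n))
  cat(sprintf("macro over known classes: precision %.3f, recall %.3f",
              x$macro_precision_known, x$macro_recall_known),
      sprintf("(support-weighted recall %.3f)\n", x$weighted_recall_known))
  invisible(x)
}

#' Stratified k-fold cross-validation of the sentence classifier
#'
#' Folds are stratified by label; each sentence appears in exactly one test
#' fold. Classes with fewer members than folds degrade to a plain
#' (unstratified) assignment for those sentences, with a message. Fold
#' membership is deterministic given `seed`.
#'
#' @param corpus labelled corpus.
#' @param k number of folds (>= 2).
#' @param config an [nlp_config()] used for each fold's training.
#' @param seed seed controlling fold assignment.
#' @return list with `fold_reports` (one [evaluate()] report per fold),
#'   `pooled` (report over the concatenated test predictions), and `folds`
#'   (the fold index per sentence).
#' @export
cross_validate <- function(corpus, k = 5L, config = nlp_config(),
                           seed = 1L) {
  stopifnot(k >= 2, nrow(corpus) >= k)
  fold <- integer(nrow(corpus))
  with_seed(seed, {
    for (cls in unique(corpus$label)) {
      ix <- which(corpus$label == cls)
      if (length(ix) < k) {
        message("class '", cls, "' has fewer than ", k,
                " members; plain split used for it")
        fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
      } else {
        fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
      }
    }
  })
  gold_all <- character(0)
  pred_all <- character(0)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    test <- corpus[fold == f, , drop = FALSE]
    train <- corpus[fold != f, , drop = FALSE]
    model <- train_classifier(train, config)
    pred <- predict(model, test, type = "class")
    reports[[f]] <- evaluate(test$label, pred)
    gold_all <- c(gold_all, test$label)
    pred_all <- c(pred_all, pred)
  }
  list(fold_reports = reports, pooled = evaluate(gold_all, pred_all),
       folds = fold)
}
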