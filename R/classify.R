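# Classifiers over the fused components and the evaluation metrics.
# Road hypnosis is the positive class throughout. LDA/QDA are fitted with
# MASS; KNN is a small deterministic implementation (Euclidean distance on
# the fused components, prediction ties broken by the single nearest
# neighbour's label) so that identical training data always yields identical
# predictions.

#' Train a classifier on fused component scores
#'
#' @param kind `"lda"`, `"qda"`, or `"knn"`.
#' @param scores numeric matrix of component scores (rows = epochs), or a
#'   data.frame from [pca_transform()] with a `state` column.
#' @param labels state labels (`"normal"`/`"hypnosis"`); taken from
#'   `scores$state` when omitted and available.
#' @param k neighbour count for KNN (default 9, within the tried range 5-10).
#' @return object of class `hypno_classifier` with a [predict()] method.
#' @export
train_classifier <- function(kind = c("knn", "lda", "qda"), scores,
                             labels = NULL, k = 9) {
  kind <- match.arg(kind)
  if (is.data.frame(scores)) {
    if (is.null(labels) && "state" %in% names(scores)) labels <- scores$state
    scores <- score_matrix(scores)
  }
  scores <- as.matrix(scores)
  labels <- factor(as.character(labels), levels = STATES)
  if (any(is.na(labels))) stop("labels must be 'normal' or 'hypnosis'", call. = FALSE)
  if (length(labels) != nrow(scores)) stop("one label per score row required", call. = FALSE)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  fit <- switch(kind,
    knn = {
      if (k < 1 || k > nrow(scores)) {
        stop(sprintf("`k` must be in 1..%d (the training size)", nrow(scores)), call. = FALSE)
      }
      list(train = scores, labels = labels, k = as.integer(k))
    },
    lda = MASS::lda(scores, grouping = labels),
    qda = MASS::qda(scores, grouping = labels)
  )
  structure(list(kind = kind, fit = fit, k = if (kind == "knn") as.integer(k) else NULL),
            class = "hypno_classifier")
}

score_matrix <- function(df) {
  pc_cols <- grep("^pc[0-9]+$", names(df), value = TRUE)
  if (length(pc_cols) == 0L) stop("no pc1, pc2, ... columns found", call. = FALSE)
  as.matrix(df[, pc_cols, drop = FALSE])
}

knn_predict <- function(fit, newdata) {
  train_t <- t(fit$train)
  out <- character(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    d2 <- colSums((train_t - newdata[i, ])^2)
    ord <- order(d2)  # ties resolved by training-row order: deterministic
    nn <- fit$labels[ord[seq_len(fit$k)]]
    tab <- table(nn)
    top <- names(tab)[tab == max(tab)]
    out[i] <- if (length(top) == 1L) top else as.character(fit$labels[ord[1L]])
  }
  factor(out, levels = STATES)
}

#' @export
predict.hypno_classifier <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- score_matrix(newdata)
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(factor(character(0), levels = STATES))
  switch(object$kind,
    knn = knn_predict(object$fit, newdata),
    lda = factor(as.character(stats::predict(object$fit, newdata)$class), levels = STATES),
    qda = factor(as.character(stats::predict(object$fit, newdata)$class), levels = STATES)
  )
}

#' @export
print.hypno_classifier <- function(x, ...) {
  cat(sprintf("<hypno_classifier> %s%s\n", toupper(x$kind),
              if (x$kind == "knn") sprintf(" (k = %d)", x$k) else ""))
  invisible(x)
}

#' Confusion counts with hypnosis as the positive class
#'
#' TP: hypnosis correctly identified; TN: normal correctly identified;
#' FP: normal misread as hypnosis; FN: hypnosis misread as normal.
#'
#' @param pred,truth label vectors of equal length.
#' @return list of class `confusion_counts` with integers `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as.character(pred); truth <- as.character(truth)
  if (length(pred) != length(truth)) {
    stop("`pred` and `truth` must have equal length", call. = FALSE)
  }
  structure(list(
    TP = sum(pred == "hypnosis" & truth == "hypnosis"),
    TN = sum(pred == "normal" & truth == "normal"),
    FP = sum(pred == "hypnosis" & truth == "normal"),
    FN = sum(pred == "normal" & truth == "hypnosis")
  ), class = "confusion_counts")
}

add_counts <- function(a, b) {
  structure(list(TP = a$TP + b$TP, TN = a$TN + b$TN,
                 FP = a$FP + b$FP, FN = a$FN + b$FN),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' AC = 100 (TP + TN) / (TP + TN + FP + FN) (percent);
#' SE = TP / (TP + FN); SP = TN / (TN + FP). A rate whose denominator is
#' zero (no positives, or no negatives, evaluated) is reported as `NA`, not
#' as 0.
#'
#' @param counts a `confusion_counts`.
#' @return list with `AC` (percent), `SE`, `SP` (fractions).
#' @export
#' @examples
#' classification_metrics(confusion_counts(
#'   rep(c("hypnosis", "normal"), c(4, 6)), rep(c("hypnosis", "normal"), c(4, 6))))
classification_metrics <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stop("cannot compute metrics from all-zero counts", call. = FALSE)
  list(
    AC = 100 * (counts$TP + counts$TN) / total,
    SE = if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN) else NA_real_,
    SP = if (counts$TN + counts$FP > 0) counts$TN / (counts$TN + counts$FP) else NA_real_
  )
}
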