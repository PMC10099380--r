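# The fitted identification model: PCA fusion of the six bispectral features
# to two components, then a classifier over the component scores. This is the
# object refitted inside every cross-validation training fold, so fold
# evaluation can never leak test-set statistics through the standardization
# or the loadings.

#' Fit a road-hypnosis identification model
#'
#' Fits the PCA fusion (z-scored features, top `n_components` eigenvectors of
#' the covariance matrix) on the training feature rows, then trains the
#' requested classifier on the fused component scores.
#'
#' @param features feature data.frame (from [extract_features()] or
#'   [read_features()]) with a `state` column and the six feature columns.
#' @param classifier `"knn"` (default), `"lda"`, or `"qda"`.
#' @param k KNN neighbour count (default 9).
#' @param n_components retained PCA components (default 2).
#' @return object of class `hypnosis_model`.
#' @export
#' @seealso [predict.hypnosis_model()], [group_kfold_cv()], [random_cv()]
hypnosis_model <- function(features, classifier = c("knn", "lda", "qda"),
                           k = 9, n_components = 2) {
  classifier <- match.arg(classifier)
  if (!"state" %in% names(features)) stop("`features` must carry a `state` column", call. = FALSE)
  pca <- fit_pca(features, n_components = n_components)
  scores <- pca_transform(pca, features)
  clf <- train_classifier(classifier, score_matrix(scores),
                          labels = features$state, k = k)
  structure(
    list(pca = pca, classifier = clf, classifier_kind = classifier,
         k = if (classifier == "knn") as.integer(k) else NULL,
         n_train = nrow(features),
         train_class_counts = table(factor(features$state, levels = STATES)),
         call = match.call()),
    class = "hypnosis_model"
  )
}

#' Predict driver state for new feature rows
#'
#' @param object a fitted `hypnosis_model`.
#' @param newdata feature data.frame or matrix (same six features).
#' @param ... unused.
#' @return factor of predicted states (`normal`/`hypnosis`).
#' @export
predict.hypnosis_model <- function(object, newdata, ...) {
  scores <- pca_transform(object$pca, newdata)
  if (is.data.frame(scores)) scores <- score_matrix(scores)
  stats::predict(object$classifier, scores)
}

#' @export
print.hypnosis_model <- function(x, ...) {
  cat("Road-hypnosis identification model\n")
  cat(sprintf("  classifier: %s%s on %d fused component(s)\n",
              toupper(x$classifier_kind),
              if (!is.null(x$k)) sprintf(" (k = %d)", x$k) else "",
              x$pca$n_components))
  cat(sprintf("  trained on %d epochs (%d normal, %d hypnosis)\n",
              x$n_train, x$train_class_counts[["normal"]],
              x$train_class_counts[["hypnosis"]]))
  invisible(x)
}

#' @export
summary.hypnosis_model <- function(object, ...) {
  ev <- object$pca$explained_variance
  cat("Road-hypnosis identification model\n\n")
  print(object$pca)
  cat("\nComponent loadings (standardized features):\n")
  print(round(object$pca$components, 3))
  cat(sprintf("\nEigenvalues: %s\n", paste(round(ev, 3), collapse = ", ")))
  print(object$classifier)
  invisible(object)
}

#' Scatter of training epochs in the fused component plane
#'
#' @param x a fitted `hypnosis_model`.
#' @param features feature rows to display (with `state`).
#' @param ... passed to [plot()].
#' @export
plot.hypnosis_model <- function(x, features, ...) {
  sc <- pca_transform(x$pca, features)
  cls <- factor(features$state, levels = STATES)
  graphics::plot(sc$pc1, sc$pc2, col = c("steelblue", "firebrick")[as.integer(cls)],
                 pch = 19, cex = 0.6, xlab = "PC1", ylab = "PC2", ...)
  graphics::legend("topright", legend = STATES, col = c("steelblue", "firebrick"),
                   pch = 19, bty = "n")
  invisible(x)
}
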