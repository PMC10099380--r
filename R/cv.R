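# Cross-validation. Two schemes:
#  - random: repeated stratified 70/30 shuffle-splits of the epochs. Fast and
#    optimistic — epochs from the same subject routinely land on both sides,
#    so same-subject leakage inflates the scores.
#  - group_kfold: subjects (not epochs) are partitioned into k folds; every
#    epoch is tested exactly once and no subject ever contributes to both
#    sides of a fold. This is the scheme that estimates generalization to
#    unseen drivers.
# In both schemes the PCA fusion and the classifier are refitted inside each
# training side only.

new_cv_result <- function(scheme, classifier, k, folds, seed, extra = list()) {
  pooled <- Reduce(add_counts, lapply(folds, `[[`, "counts"))
  structure(
    c(list(scheme = scheme, classifier = classifier, k = k, folds = folds,
           pooled_counts = pooled, pooled_metrics = classification_metrics(pooled),
           seed = seed), extra),
    class = "hypno_cv"
  )
}

#' @export
print.hypno_cv <- function(x, ...) {
  m <- x$pooled_metrics
  cat(sprintf("<hypno_cv> %s / %s%s over %d fold(s)\n", x$scheme,
              toupper(x$classifier),
              if (!is.null(x$k) && x$classifier == "knn") sprintf("(k=%d)", x$k) else "",
              length(x$folds)))
  cat(sprintf("  pooled: AC %.1f%%  SE %.3f  SP %.3f  (TP %d TN %d FP %d FN %d)\n",
              m$AC, m$SE, m$SP, x$pooled_counts$TP, x$pooled_counts$TN,
              x$pooled_counts$FP, x$pooled_counts$FN))
  invisible(x)
}

#' Flatten a CV result for reporting
#'
#' @param cv a `hypno_cv`.
#' @return plain list (JSON-ready): scheme, classifier, pooled counts and
#'   metrics, per-fold metrics, mean fold accuracy.
#' @export
cv_result_summary <- function(cv) {
  fold_ac <- vapply(cv$folds, function(f) f$metrics$AC, numeric(1))
  list(
    scheme = cv$scheme, classifier = cv$classifier, k = cv$k, seed = cv$seed,
    n_folds = length(cv$folds),
    pooled_counts = unclass(cv$pooled_counts),
    pooled_metrics = cv$pooled_metrics,
    mean_fold_accuracy = mean(fold_ac),
    fold_metrics = lapply(cv$folds, `[[`, "metrics")
  )
}

fit_fold <- function(train, test, classifier, k, n_components) {
  model <- hypnosis_model(train, classifier = classifier, k = k,
                          n_components = n_components)
  pred <- stats::predict(model, test)
  counts <- confusion_counts(pred, test$state)
  list(counts = counts, metrics = classification_metrics(counts),
       model_means = model$pca$feature_means,
       test_subjects = sort(unique(test$subject_id)))
}

# Stratified train-row selection summing exactly to round(frac * n): floor
# per class, remaining slots to the classes with the largest remainders.
stratified_train_idx <- function(states, frac) {
  n <- length(states)
  target <- round(frac * n)
  idx_by_class <- split(seq_len(n), states)
  raw <- vapply(idx_by_class, length, numeric(1)) * frac
  base <- floor(raw)
  extra <- target - sum(base)
  if (extra > 0) {
    up <- order(raw - base, decreasing = TRUE)[seq_len(extra)]
    base[up] <- base[up] + 1
  } else if (extra < 0) {
    down <- order(raw - base)[seq_len(-extra)]
    base[down] <- base[down] - 1
  }
  unlist(lapply(seq_along(idx_by_class), function(i) {
    pool <- idx_by_class[[i]]
    sample(pool, min(base[i], length(pool)))
  }), use.names = FALSE)
}

#' Repeated random (shuffle-split) cross-validation
#'
#' Per repeat: a stratified random split at `train_frac`, PCA + classifier
#' fitted on the training side, metrics on the test side. Reported as one
#' "fold" per repeat plus pooled counts. Reproducible under `seed`.
#'
#' @param features feature data.frame with `subject_id`, `state` and the six
#'   feature columns.
#' @param classifier `"knn"`, `"lda"`, or `"qda"`.
#' @param k KNN neighbour count (default 9).
#' @param train_frac training fraction (default 0.7).
#' @param n_repeats number of random splits (default 20).
#' @param seed integer seed.
#' @param n_components retained PCA components (default 2).
#' @return object of class `hypno_cv`.
#' @export
random_cv <- function(features, classifier = c("knn", "lda", "qda"), k = 9,
                      train_frac = 0.7, n_repeats = 20, seed = 1,
                      n_components = 2) {
  classifier <- match.arg(classifier)
  states <- factor(features$state, levels = STATES)
  if (nlevels(droplevels(states)) < 2L) stop("both classes must be present", call. = FALSE)
  folds <- with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      for (attempt in 1:25) {
        tr <- stratified_train_idx(states, train_frac)
        te <- setdiff(seq_len(nrow(features)), tr)
        ok <- length(unique(states[tr])) == 2L && length(te) > 0L
        if (ok) break
        warning("a split lost a class; resampling the split")
      }
      fit_fold(features[tr, , drop = FALSE], features[te, , drop = FALSE],
               classifier, k, n_components)
    })
  })
  new_cv_result("random", classifier, if (classifier == "knn") k else NULL,
                folds, seed, extra = list(train_frac = train_frac))
}

#' Subject-grouped k-fold cross-validation
#'
#' Subjects are shuffled (under `seed`) and partitioned into `k_folds`
#' near-equal folds. For each fold the PCA fusion and the classifier are
#' fitted on the other folds' subjects only and evaluated on the held-out
#' subjects, so no subject ever appears on both sides and every epoch is
#' tested exactly once.
#'
#' @inheritParams random_cv
#' @param k_folds number of folds (default 5); must not exceed the number of
#'   distinct subjects.
#' @return object of class `hypno_cv`; each fold records its held-out
#'   subjects.
#' @export
group_kfold_cv <- function(features, classifier = c("knn", "lda", "qda"),
                           k_folds = 5, k = 9, seed = 1, n_components = 2) {
  classifier <- match.arg(classifier)
  subjects <- unique(features$subject_id)
  if (length(subjects) < k_folds) {
    stop(sprintf("need at least %d distinct subjects for %d folds (have %d)",
                 k_folds, k_folds, length(subjects)), call. = FALSE)
  }
  assignment <- with_seed(seed, {
    shuffled <- sample(subjects)
    stats::setNames(rep_len(seq_len(k_folds), length(shuffled)), shuffled)
  })
  folds <- lapply(seq_len(k_folds), function(f) {
    test_subj <- names(assignment)[assignment == f]
    te <- features$subject_id %in% test_subj
    train <- features[!te, , drop = FALSE]
    if (length(unique(train$state)) < 2L) {
      stop("a training side lost a class; use more subjects or fewer folds", call. = FALSE)
    }
    fit_fold(train, features[te, , drop = FALSE], classifier, k, n_components)
  })
  new_cv_result("group_kfold", classifier, if (classifier == "knn") k else NULL,
                folds, seed, extra = list(fold_assignment = assignment))
}

#' Select the KNN neighbour count by cross-validated accuracy
#'
#' Evaluates every K in `k_range` under the requested scheme and returns the
#' K with the highest mean fold accuracy; exact ties go to the smallest K.
#'
#' @param features feature data.frame.
#' @param k_range candidate neighbour counts (default 5:10).
#' @param cv `"group_kfold"` (default) or `"random"`.
#' @param seed integer seed (same folds reused for every K).
#' @param ... passed to the CV function.
#' @return list with `best_k` and the per-K `accuracy` table (mean fold
#'   accuracy, named by K).
#' @export
select_knn_k <- function(features, k_range = 5:10,
                         cv = c("group_kfold", "random"), seed = 1, ...) {
  cv <- match.arg(cv)
  if (length(k_range) == 0L) stop("`k_range` must be nonempty", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  acc <- vapply(k_range, function(kk) {
    res <- if (cv == "group_kfold") {
      group_kfold_cv(features, classifier = "knn", k = kk, seed = seed, ...)
    } else {
      random_cv(features, classifier = "knn", k = kk, seed = seed, ...)
    }
    mean(vapply(res$folds, function(f) f$metrics$AC, numeric(1)))
  }, numeric(1))
  names(acc) <- k_range
  list(best_k = k_range[which.max(acc)], accuracy = acc)
}
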