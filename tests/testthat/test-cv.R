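# Cross-validation schemes: split arithmetic, determinism, leakage control.

test_that("random CV splits 10 rows into 7 train / 3 test", {
  feats <- make_feature_df(n_subjects = 1, epochs_per_state = 5, effect = 3,
                           seed = 1)
  cv <- random_cv(feats, "lda", n_repeats = 4, seed = 2)
  for (f in cv$folds) {
    total <- f$counts$TP + f$counts$TN + f$counts$FP + f$counts$FN
    expect_equal(total, 3)
  }
})

test_that("random CV is reproducible under its seed", {
  feats <- make_feature_df(n_subjects = 3, epochs_per_state = 6, effect = 1,
                           seed = 3)
  cv1 <- random_cv(feats, "knn", k = 5, n_repeats = 5, seed = 11)
  cv2 <- random_cv(feats, "knn", k = 5, n_repeats = 5, seed = 11)
  expect_identical(cv1, cv2)
  cv3 <- random_cv(feats, "knn", k = 5, n_repeats = 5, seed = 12)
  expect_false(identical(cv1$pooled_counts, cv3$pooled_counts))
})

test_that("random CV sits at chance when the classes are identical", {
  feats <- make_feature_df(n_subjects = 5, epochs_per_state = 20, effect = 0,
                           seed = 4)
  cv <- random_cv(feats, "lda", n_repeats = 20, seed = 5)
  mean_ac <- mean(vapply(cv$folds, function(f) f$metrics$AC, numeric(1)))
  expect_gte(mean_ac, 40)
  expect_lte(mean_ac, 60)
})

test_that("group k-fold partitions subjects exactly", {
  feats <- make_feature_df(n_subjects = 10, epochs_per_state = 4, effect = 2,
                           seed = 6)
  cv <- group_kfold_cv(feats, "lda", k_folds = 5, seed = 7)
  test_sets <- lapply(cv$folds, `[[`, "test_subjects")
  expect_true(all(lengths(test_sets) == 2))
  expect_setequal(unlist(test_sets), unique(feats$subject_id))
  expect_equal(sum(lengths(test_sets)), 10)  # each subject tested once

  # every epoch tested exactly once
  totals <- vapply(cv$folds, function(f) {
    f$counts$TP + f$counts$TN + f$counts$FP + f$counts$FN
  }, numeric(1))
  expect_equal(sum(totals), nrow(feats))

  expect_error(group_kfold_cv(feats, "lda", k_folds = 11), "at least 11")
})

test_that("per-fold models are fitted on the training subjects only", {
  feats <- make_feature_df(n_subjects = 6, epochs_per_state = 5, effect = 1,
                           seed = 8)
  cv <- group_kfold_cv(feats, "lda", k_folds = 3, seed = 9)
  for (f in cv$folds) {
    train_rows <- feats[!feats$subject_id %in% f$test_subjects, ]
    expected_means <- colMeans(as.matrix(train_rows[, roadhos:::feature_columns()]))
    expect_equal(f$model_means, expected_means, tolerance = 1e-12)
  }
})

test_that("subject confounding inflates random CV relative to group k-fold", {
  # each subject gets a private feature offset and a tiny class effect:
  # epoch-level shuffling lets classifiers exploit subject identity
  feats <- make_feature_df(n_subjects = 10, epochs_per_state = 12,
                           effect = 0.4, subject_offset_sd = 3, seed = 10)
  rcv <- random_cv(feats, "knn", k = 9, n_repeats = 10, seed = 11)
  gcv <- group_kfold_cv(feats, "knn", k_folds = 5, k = 9, seed = 11)
  expect_gt(rcv$pooled_metrics$AC, gcv$pooled_metrics$AC)
})

test_that("fold-internal PCA differs from globally fitted PCA", {
  # one subject with an extreme feature scale dominates a global fit; folds
  # that exclude it must not see it through the fusion model
  feats <- make_feature_df(n_subjects = 5, epochs_per_state = 6, effect = 1,
                           seed = 12)
  big <- feats$subject_id == "S01"
  feats[big, roadhos:::feature_columns()] <-
    feats[big, roadhos:::feature_columns()] * 100
  global_pca <- fit_pca(feats)
  cv <- group_kfold_cv(feats, "lda", k_folds = 5, seed = 13)
  excl <- which(vapply(cv$folds, function(f) "S01" %in% f$test_subjects,
                       logical(1)))
  expect_gt(max(abs(cv$folds[[excl]]$model_means - global_pca$feature_means)), 1)
})

test_that("K selection recomputes the accuracy table and breaks ties low", {
  feats <- make_feature_df(n_subjects = 8, epochs_per_state = 8, effect = 0.8,
                           subject_offset_sd = 0.8, seed = 14)
  sel <- select_knn_k(feats, k_range = 5:10, cv = "group_kfold", seed = 15)
  # independent re-evaluation of the per-K table
  manual <- vapply(5:10, function(kk) {
    cv <- group_kfold_cv(feats, "knn", k_folds = 5, k = kk, seed = 15)
    mean(vapply(cv$folds, function(f) f$metrics$AC, numeric(1)))
  }, numeric(1))
  expect_equal(unname(sel$accuracy), manual)
  expect_equal(sel$best_k, (5:10)[which.max(manual)])

  expect_equal(select_knn_k(feats, k_range = 7, seed = 16)$best_k, 7)

  # perfectly separable data: every K attains 100%, tie goes to the smallest
  sep <- make_feature_df(n_subjects = 8, epochs_per_state = 6, effect = 12,
                         seed = 17)
  expect_equal(select_knn_k(sep, k_range = 5:10, cv = "group_kfold",
                            seed = 18)$best_k, 5)
  expect_error(select_knn_k(feats, k_range = integer(0)), "nonempty")
})
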