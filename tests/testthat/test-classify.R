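# Classifier training/prediction and the evaluation metrics.

two_blob_scores <- function(n_per_class, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * 2), ncol = 2),
             matrix(rnorm(n_per_class * 2, mean = sep), ncol = 2))
  colnames(x) <- c("pc1", "pc2")
  list(scores = x,
       labels = rep(c("normal", "hypnosis"), each = n_per_class))
}

test_that("KNN with K = 1 predicts a training point's own label", {
  d <- two_blob_scores(10)
  clf <- train_classifier("knn", d$scores, d$labels, k = 1)
  pred <- predict(clf, d$scores)
  expect_identical(as.character(pred), d$labels)
})

test_that("KNN matches an exhaustive nearest-neighbour oracle", {
  set.seed(2)
  train <- matrix(rnorm(60), ncol = 2)
  labels <- sample(c("normal", "hypnosis"), 30, replace = TRUE)
  clf <- train_classifier("knn", train, labels, k = 5)
  query <- matrix(rnorm(100), ncol = 2)
  pred <- predict(clf, query)
  for (i in 1:50) {
    d2 <- rowSums((train - matrix(query[i, ], 30, 2, byrow = TRUE))^2)
    nn <- labels[order(d2)[1:5]]
    expect_identical(as.character(pred[i]), names(which.max(table(nn))))
  }
})

test_that("KNN vote ties fall back to the single nearest neighbour", {
  # two training points equidistant classes; K = 2 forces a 1-1 vote
  train <- rbind(c(0, 0), c(3, 0))
  labels <- c("hypnosis", "normal")
  clf <- train_classifier("knn", train, labels, k = 2)
  expect_identical(as.character(predict(clf, rbind(c(1, 0)))), "hypnosis")
  expect_identical(as.character(predict(clf, rbind(c(2, 0)))), "normal")
})

test_that("LDA separates well-separated Gaussian blobs", {
  d <- two_blob_scores(200, sep = 6, seed = 3)
  ho <- two_blob_scores(200, sep = 6, seed = 4)
  clf <- train_classifier("lda", d$scores, d$labels)
  acc <- mean(as.character(predict(clf, ho$scores)) == ho$labels)
  expect_gte(acc, 0.99)
})

test_that("QDA agrees with LDA near the midpoint of symmetric classes", {
  set.seed(5)
  base <- matrix(rnorm(400), ncol = 2)
  scores <- rbind(base, base + 4)  # identical within-class covariances
  labels <- rep(c("normal", "hypnosis"), each = 200)
  lda_fit <- train_classifier("lda", scores, labels)
  qda_fit <- train_classifier("qda", scores, labels)
  probe <- rbind(c(1.2, 1.2), c(2.8, 2.8), c(0, 0), c(4, 4))
  expect_identical(as.character(predict(lda_fit, probe)),
                   as.character(predict(qda_fit, probe)))
})

test_that("prediction is stateless and handles empty queries", {
  d <- two_blob_scores(20, seed = 6)
  clf <- train_classifier("knn", d$scores, d$labels, k = 3)
  expect_length(predict(clf, d$scores[0, , drop = FALSE]), 0)
  q <- matrix(rnorm(40), ncol = 2)
  p1 <- predict(clf, q)
  p2 <- predict(clf, q[c(11:20, 1:10), ])
  expect_identical(p1[c(11:20, 1:10)], p2)
})

test_that("degenerate training sets are rejected", {
  d <- two_blob_scores(10, seed = 7)
  expect_error(train_classifier("knn", d$scores, rep("normal", 20)),
               "both classes")
  expect_error(train_classifier("knn", d$scores, d$labels, k = 21), "1..20")
})

test_that("confusion counts treat hypnosis as the positive class", {
  truth <- rep(c("hypnosis", "normal"), c(4, 6))
  cc <- confusion_counts(truth, truth)
  expect_equal(unclass(cc), list(TP = 4L, TN = 6L, FP = 0L, FN = 0L),
               ignore_attr = TRUE)
  all_hyp <- confusion_counts(rep("hypnosis", 10), truth)
  expect_equal(unclass(all_hyp), list(TP = 4L, TN = 0L, FP = 6L, FN = 0L),
               ignore_attr = TRUE)

  set.seed(8)
  pred <- sample(c("hypnosis", "normal"), 50, TRUE)
  tr <- sample(c("hypnosis", "normal"), 50, TRUE)
  got <- confusion_counts(pred, tr)
  hand <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (i in 1:50) {
    cell <- if (tr[i] == "hypnosis") {
      if (pred[i] == "hypnosis") "TP" else "FN"
    } else {
      if (pred[i] == "hypnosis") "FP" else "TN"
    }
    hand[cell] <- hand[cell] + 1
  }
  expect_equal(unlist(unclass(got)), hand, ignore_attr = TRUE)
  expect_error(confusion_counts("hypnosis", truth), "equal length")
})

test_that("metrics follow the accuracy/sensitivity/specificity formulas", {
  m <- classification_metrics(structure(list(TP = 3, TN = 5, FP = 1, FN = 1),
                                        class = "confusion_counts"))
  expect_equal(m$AC, 80)
  expect_equal(m$SE, 0.75)
  expect_equal(m$SP, 5 / 6)

  perfect <- classification_metrics(structure(list(TP = 7, TN = 9, FP = 0, FN = 0),
                                              class = "confusion_counts"))
  expect_equal(unlist(perfect), c(AC = 100, SE = 1, SP = 1))

  none_pos <- classification_metrics(structure(list(TP = 0, TN = 5, FP = 2, FN = 0),
                                               class = "confusion_counts"))
  expect_true(is.na(none_pos$SE))
  expect_error(classification_metrics(structure(list(TP = 0, TN = 0, FP = 0, FN = 0),
                                                class = "confusion_counts")),
               "all-zero")
})

test_that("metric identity holds over all small confusion tables", {
  for (TP in 0:6) for (TN in 0:6) for (FP in 0:6) for (FN in 0:6) {
    total <- TP + TN + FP + FN
    if (total == 0 || total > 12) next
    m <- classification_metrics(structure(list(TP = TP, TN = TN, FP = FP, FN = FN),
                                          class = "confusion_counts"))
    P <- TP + FN; Nn <- TN + FP
    if (P > 0 && Nn > 0) {
      expect_equal(m$AC / 100, (m$SE * P + m$SP * Nn) / (P + Nn))
    }
  }
})
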