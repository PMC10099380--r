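# PCA fusion of the ECG and EMG feature triples. The two channel triples are
# concatenated into one 6-vector per epoch and a single joint PCA retains the
# top two components. Features are z-scored first (S1 and S3 differ by orders
# of magnitude; unstandardized PCA would be dominated by S1), and the
# covariance uses divisor N (population form) throughout — the choice does
# not alter the eigenvectors.

#' Population covariance of two equal-length samples
#'
#' cov(X:Y) = sum_i (x_i - xbar)(y_i - ybar) / N — divisor N, not N - 1.
#'
#' @param x,y numeric vectors of equal nonzero length.
#' @return scalar covariance.
#' @export
#' @examples
#' pop_covariance(c(1, 2, 3), c(1, 2, 3))  # 2/3
pop_covariance <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) == 0L) stop("`x` and `y` must be nonempty", call. = FALSE)
  mean((x - mean(x)) * (y - mean(y)))
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    cols <- intersect(feature_columns(), names(features))
    if (length(cols) != length(feature_columns())) {
      cols <- names(features)[vapply(features, is.numeric, logical(1))]
      cols <- setdiff(cols, "epoch_start_s")
    }
    as.matrix(features[, cols, drop = FALSE])
  } else {
    as.matrix(features)
  }
}

#' Fit the PCA fusion model
#'
#' Standardizes the training features (z-score with population standard
#' deviations), eigendecomposes the resulting covariance (= correlation)
#' matrix, and retains the leading `n_components` eigenvectors. Sign
#' convention: within each component the largest-magnitude loading is
#' positive, so refitting on permuted rows reproduces the components exactly.
#'
#' @param features feature data.frame or numeric matrix (rows = epochs).
#' @param n_components number of retained components (default 2).
#' @return object of class `hos_pca`: `feature_means`, `feature_scales`,
#'   `components` (`n_components` x p, orthonormal rows),
#'   `explained_variance` (all p eigenvalues, descending).
#' @export
fit_pca <- function(features, n_components = 2) {
  X <- feature_matrix(features)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 training rows to fit the PCA", call. = FALSE)
  if (n_components < 1L || n_components > p) {
    stop(sprintf("`n_components` must be in 1..%d", p), call. = FALSE)
  }
  mu <- colMeans(X)
  sdev <- apply(X, 2, pop_sd)
  zero_var <- sdev < 1e-12
  if (any(zero_var)) {
    warning(sprintf("zero-variance feature(s) %s: scale floored at 1e-12",
                    paste(colnames(X)[zero_var], collapse = ", ")))
    sdev[zero_var] <- 1e-12
  }
  Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
  C <- crossprod(Z) / n
  eig <- eigen(C, symmetric = TRUE)
  comps <- t(eig$vectors[, seq_len(n_components), drop = FALSE])
  for (i in seq_len(n_components)) {
    jmax <- which.max(abs(comps[i, ]))
    if (comps[i, jmax] < 0) comps[i, ] <- -comps[i, ]
  }
  rownames(comps) <- paste0("pc", seq_len(n_components))
  colnames(comps) <- colnames(X)
  structure(
    list(feature_means = mu, feature_scales = sdev, components = comps,
         explained_variance = eig$values, n_components = n_components,
         feature_names = colnames(X)),
    class = "hos_pca"
  )
}

#' @export
print.hos_pca <- function(x, ...) {
  ev <- x$explained_variance
  cat(sprintf("<hos_pca> %d of %d components retained; variance explained %.1f%%\n",
              x$n_components, length(ev),
              100 * sum(ev[seq_len(x$n_components)]) / sum(ev)))
  invisible(x)
}

#' Project feature rows onto the fused components
#'
#' @param model a fitted `hos_pca`.
#' @param features feature data.frame or matrix.
#' @return numeric matrix of scores (columns `pc1`, `pc2`, ...); when
#'   `features` is a data.frame with metadata columns, they are carried over
#'   as a data.frame with `subject_id`/`state` plus the scores.
#' @export
pca_transform <- function(model, features) {
  if (!inherits(model, "hos_pca")) stop("`model` must be a fitted `hos_pca`", call. = FALSE)
  X <- feature_matrix(features)
  Z <- sweep(sweep(X, 2, model$feature_means), 2, model$feature_scales, "/")
  scores <- Z %*% t(model$components)
  if (is.data.frame(features) && all(c("subject_id", "state") %in% names(features))) {
    out <- data.frame(subject_id = features$subject_id, state = features$state,
                      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(scores))
  } else {
    scores
  }
}

#' Reconstruct standardized-space features from component scores
#'
#' With all p components the transform/inverse pair is the identity; with
#' fewer, the reconstruction error is the variance in the dropped components.
#'
#' @param model a fitted `hos_pca`.
#' @param scores score matrix from [pca_transform()].
#' @return feature matrix on the original scale.
#' @export
pca_inverse_transform <- function(model, scores) {
  scores <- as.matrix(scores)
  Z <- scores %*% model$components[seq_len(ncol(scores)), , drop = FALSE]
  sweep(sweep(Z, 2, model$feature_scales, "*"), 2, model$feature_means, "+")
}

#' Persist / load a PCA fusion model as JSON
#'
#' @param model a fitted `hos_pca`.
#' @param path file path.
#' @export
write_pca_model <- function(model, path) {
  jsonlite::write_json(
    list(feature_names = model$feature_names,
         feature_means = unname(model$feature_means),
         feature_scales = unname(model$feature_scales),
         components = lapply(seq_len(nrow(model$components)),
                             function(i) unname(model$components[i, ])),
         explained_variance = model$explained_variance,
         n_components = model$n_components),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- if (is.matrix(j$components)) j$components else
    matrix(unlist(j$components), nrow = j$n_components, byrow = TRUE)
  rownames(comps) <- paste0("pc", seq_len(j$n_components))
  colnames(comps) <- j$feature_names
  structure(
    list(feature_means = stats::setNames(j$feature_means, j$feature_names),
         feature_scales = stats::setNames(j$feature_scales, j$feature_names),
         components = comps, explained_variance = j$explained_variance,
         n_components = j$n_components, feature_names = j$feature_names),
    class = "hos_pca"
  )
}
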