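# Higher-order spectra: moments/cumulants, power spectrum, the direct
# (FFT-based, segment-averaged) bispectrum estimator, and the three
# bispectral features used for classification:
#   S1 = sum of log bispectral magnitudes over the principal region Omega,
#   S2 = the same sum restricted to the diagonal f1 = f2,
#   S3 = the first-order spectral moment of the diagonal log-magnitudes
#        (bin-index-weighted sum).
# Frequencies are normalized so f = bin/(L/2) runs from 0 to 1 at Nyquist;
# Omega = {0 <= f2 <= f1, f1 + f2 <= 1} on the grid.

# Mean of the lagged product prod_j x[k + lags_j] over all valid k, divided
# by the number of valid terms. Accepts negative lags.
lagged_product_mean <- function(xc, lags) {
  n <- length(xc)
  lo <- 1L - min(c(lags, 0L))
  hi <- n - max(c(lags, 0L))
  if (hi < lo) stop("lags out of range for this signal length", call. = FALSE)
  k <- lo:hi
  acc <- rep(1, length(k))
  for (tau in lags) acc <- acc * xc[k + tau]
  sum(acc) / length(k)
}

#' Sample moments of a signal up to a maximum lag
#'
#' Computes the first moment (mean), the autocorrelation m2 and the third
#' moment m3 as sample averages over the valid index range after mean
#' removal; with the mean removed, m2 and m3 equal the second and third
#' cumulants c2 and c3.
#'
#' @param x numeric signal.
#' @param max_lag maximum lag in samples (< `length(x)`).
#' @return list with `m1` (scalar), `m2` (numeric vector, lags `0:max_lag`;
#'   the estimator is even in the lag), and `m3` (matrix over lag pairs
#'   `0:max_lag` x `0:max_lag`).
#' @export
#' @examples
#' signal_moments(c(1, 2, 3, 4), max_lag = 1)
signal_moments <- function(x, max_lag) {
  if (max_lag >= length(x) || max_lag < 0) {
    stop("`max_lag` must satisfy 0 <= max_lag < length(x)", call. = FALSE)
  }
  m1 <- mean(x)
  xc <- x - m1
  lags <- 0:max_lag
  m2 <- vapply(lags, function(tau) lagged_product_mean(xc, c(0L, tau)), numeric(1))
  m3 <- outer(lags, lags, Vectorize(function(t1, t2) {
    lagged_product_mean(xc, c(0L, t1, t2))
  }))
  dimnames(m3) <- list(lag1 = lags, lag2 = lags)
  list(m1 = m1, m2 = stats::setNames(m2, lags), m3 = m3)
}

#' Fourth-order cumulant at a lag triple
#'
#' Unlike orders up to three, the fourth moment is not a cumulant; the
#' Gaussian part must be subtracted:
#' c4(t1,t2,t3) = m4(t1,t2,t3) - c2(t1) c2(t3-t2) - c2(t2) c2(t3-t1)
#'              - c2(t3) c2(t2-t1).
#' For Gaussian input c4 tends to zero as the record grows. Implemented for
#' completeness and testing; the classification features use only the
#' bispectrum.
#'
#' @param x numeric signal.
#' @param t1,t2,t3 lags in samples (may be negative).
#' @return scalar c4 estimate.
#' @export
fourth_cumulant <- function(x, t1, t2, t3) {
  n <- length(x)
  lags <- c(t1, t2, t3)
  if (any(abs(lags) >= n) || any(abs(c(t3 - t2, t3 - t1, t2 - t1)) >= n)) {
    stop("lags out of range for this signal length", call. = FALSE)
  }
  xc <- x - mean(x)
  c2 <- function(tau) lagged_product_mean(xc, c(0L, tau))
  m4 <- lagged_product_mean(xc, c(0L, t1, t2, t3))
  m4 - c2(t1) * c2(t3 - t2) - c2(t2) * c2(t3 - t1) - c2(t3) * c2(t2 - t1)
}

#' One-sided power spectrum
#'
#' Periodogram of the mean-removed signal, P(f) = |X(f)|^2 / L, returned
#' one-sided. Summed over the full two-sided grid it equals L times the
#' (population) variance of the mean-removed signal (Parseval).
#'
#' @param x numeric signal (nonempty).
#' @return list with `freq` (normalized, bin/(L/2), from 0 to 1) and `power`
#'   (nonnegative, length `floor(L/2) + 1`).
#' @export
power_spectrum <- function(x) {
  if (length(x) == 0L) stop("`x` must be nonempty", call. = FALSE)
  L <- length(x)
  X <- stats::fft(x - mean(x))
  P <- Mod(X)^2 / L
  h <- floor(L / 2)
  list(freq = (0:h) / (L / 2), power = P[1:(h + 1)])
}

hann_window <- function(L) 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))

#' Direct (segment-averaged) bispectrum estimator
#'
#' Splits the signal into overlapping segments; each segment is mean-removed,
#' windowed, and Fourier-transformed, and the triple products
#' X(f1) X(f2) X*(f1+f2) are averaged across segments — the expectation in
#' the definition B(f1,f2) = E[X(f1) X(f2) X*(f1+f2)] realized by segment
#' averaging. With a single rectangular segment the estimate is the literal
#' triple product of the DFT.
#'
#' @param x numeric signal, `length(x) >= seg_len`.
#' @param seg_len segment length in samples (even; default 256).
#' @param overlap fraction of overlap between consecutive segments, in
#'   `[0, 1)` (default 0.5).
#' @param window `"hann"` or `"rect"`.
#' @param two_sided keep the full L x L two-sided grid (frequencies indexed
#'   modulo L)? Default `FALSE`: store the nonnegative-frequency quadrant
#'   `0..L/2` x `0..L/2`, which contains the principal region.
#' @return object of class `bispectrum`: complex matrix `values`, normalized
#'   frequency axis `freq` (bin/(L/2)), `seg_len`, `n_segments`, `window`,
#'   `overlap`, `two_sided`.
#' @export
estimate_bispectrum <- function(x, seg_len = 256, overlap = 0.5,
                                window = c("hann", "rect"), two_sided = FALSE) {
  window <- match.arg(window)
  n <- length(x)
  if (seg_len > n) stop("`seg_len` must not exceed the signal length", call. = FALSE)
  if (seg_len < 4 || seg_len %% 2 != 0) stop("`seg_len` must be an even number >= 4", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("`overlap` must be in [0, 1)", call. = FALSE)
  L <- as.integer(seg_len)
  h <- L %/% 2L
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq.int(1L, n - L + 1L, by = step)
  win <- if (window == "hann") hann_window(L) else rep(1, L)

  dimn <- if (two_sided) L else h + 1L
  bins <- if (two_sided) 0:(L - 1L) else 0:h
  # Each bin (j, k) is the product X(j) X(k) X(m) with m = (-j-k) mod L
  # (using X(-f) = X*(f) for real input). All twelve symmetry images of a
  # bin share one frequency triple up to permutation and negation, so every
  # bin is evaluated from the canonical (sorted, lexicographically smaller
  # of triple/negated-triple) representative; the symmetries of the output
  # then hold exactly, not merely to rounding.
  J <- matrix(bins, dimn, dimn)
  K <- t(J)
  M <- (-J - K) %% L
  a <- pmin(J, K, M); cc <- pmax(J, K, M); b <- J + K + M - a - cc
  na_ <- (L - a) %% L; nb_ <- (L - b) %% L; nc_ <- (L - cc) %% L
  nlo <- pmin(na_, nb_, nc_); nhi <- pmax(na_, nb_, nc_)
  nmid <- na_ + nb_ + nc_ - nlo - nhi
  use_neg <- (nlo < a) | (nlo == a & (nmid < b | (nmid == b & nhi < cc)))
  i1 <- ifelse(use_neg, nlo, a) + 1L
  i2 <- ifelse(use_neg, nmid, b) + 1L
  i3 <- ifelse(use_neg, nhi, cc) + 1L
  acc <- matrix(0 + 0i, dimn, dimn)
  for (st in starts) {
    seg <- x[st:(st + L - 1L)]
    X <- stats::fft((seg - mean(seg)) * win)
    # the DFT of a real sequence is Hermitian; enforce it exactly
    X[1L] <- Re(X[1L])
    X[h + 1L] <- Re(X[h + 1L])
    X[L - seq_len(h - 1L) + 1L] <- Conj(X[seq_len(h - 1L) + 1L])
    P <- X[i1] * X[i2] * X[i3]
    P[use_neg] <- Conj(P[use_neg])
    acc <- acc + P
  }
  dim(acc) <- c(dimn, dimn)
  structure(
    list(values = acc / length(starts), freq = bins / h, seg_len = L,
         n_segments = length(starts), window = window, overlap = overlap,
         two_sided = two_sided),
    class = "bispectrum"
  )
}

#' @export
print.bispectrum <- function(x, ...) {
  cat(sprintf("<bispectrum> seg_len %d, %d segment(s), %s window, %s grid\n",
              x$seg_len, x$n_segments, x$window,
              if (x$two_sided) "two-sided" else "quadrant"))
  invisible(x)
}

# Nonnegative-frequency quadrant of an estimate (identity unless two-sided).
bispectrum_quadrant <- function(B) {
  h <- B$seg_len %/% 2L
  if (B$two_sided) B$values[1:(h + 1L), 1:(h + 1L)] else B$values
}

# Logical mask of the principal region Omega = {k <= j, j + k <= L/2} over
# the quadrant grid (rows index j = f1 bins, columns k = f2 bins).
principal_region_mask <- function(h) {
  j <- matrix(0:h, h + 1L, h + 1L)
  k <- t(j)
  k <= j & (j + k) <= h
}

#' Bispectral features S1, S2, S3
#'
#' S1 sums log bispectral magnitudes over the principal region Omega; S2 sums
#' them over the diagonal bins of Omega (f1 = f2, i.e. bins `0..L/4`); S3 is
#' the first-order spectral moment of the diagonal log-magnitudes: the N
#' diagonal bins are indexed k = 1..N in frequency order and weighted by k.
#' Magnitudes are floored at `log_floor` before the (natural) log so
#' zero-valued bins stay finite.
#'
#' @param B a `bispectrum` estimate.
#' @param log_floor magnitude floor (default 1e-12).
#' @return list with numeric `S1`, `S2` (nats) and `S3` (dimensionless).
#' @export
bispectral_features <- function(B, log_floor = 1e-12) {
  Bq <- bispectrum_quadrant(B)
  h <- nrow(Bq) - 1L
  mag <- pmax(Mod(Bq), log_floor)
  lm <- log(mag)
  S1 <- sum(lm[principal_region_mask(h)])
  diag_bins <- 0:(h %/% 2L)  # f_k + f_k <= 1 keeps bins up to L/4
  dl <- lm[cbind(diag_bins + 1L, diag_bins + 1L)]
  S2 <- sum(dl)
  S3 <- sum(seq_along(dl) * dl)
  list(S1 = S1, S2 = S2, S3 = S3)
}

#' Estimator settings for the bispectral features
#'
#' @param seg_len segment length in samples (default 256).
#' @param overlap segment overlap fraction (default 0.5).
#' @param window `"hann"` (default) or `"rect"`.
#' @param log_floor magnitude floor before the log (default 1e-12).
#' @return list of class `hos_config`.
#' @export
hos_config <- function(seg_len = 256, overlap = 0.5, window = "hann",
                       log_floor = 1e-12) {
  structure(list(seg_len = seg_len, overlap = overlap, window = window,
                 log_floor = log_floor), class = "hos_config")
}

#' Extract the six bispectral features from one epoch
#'
#' Runs the bispectrum estimator on each (already preprocessed) channel and
#' returns the per-channel feature triple plus the epoch's metadata.
#'
#' @param epoch an `epoch` (see [epoch_recording()]), ideally already passed
#'   through [preprocess_epoch()].
#' @param hos an `hos_config`.
#' @return one-row data.frame: `subject_id`, `state`, `epoch_start_s`,
#'   `ecg_S1..S3`, `emg_S1..S3`.
#' @export
extract_epoch_features <- function(epoch, hos = hos_config()) {
  if (length(epoch$ecg) < hos$seg_len) {
    stop(sprintf("epoch too short: %d samples per channel but seg_len = %d",
                 length(epoch$ecg), hos$seg_len), call. = FALSE)
  }
  feats <- lapply(list(ecg = epoch$ecg, emg = epoch$emg), function(ch) {
    B <- estimate_bispectrum(ch, seg_len = hos$seg_len, overlap = hos$overlap,
                             window = hos$window)
    bispectral_features(B, log_floor = hos$log_floor)
  })
  data.frame(
    subject_id = epoch$subject_id, state = epoch$state,
    epoch_start_s = epoch$start_s,
    ecg_S1 = feats$ecg$S1, ecg_S2 = feats$ecg$S2, ecg_S3 = feats$ecg$S3,
    emg_S1 = feats$emg$S1, emg_S2 = feats$emg$S2, emg_S3 = feats$emg$S3,
    stringsAsFactors = FALSE
  )
}

#' Epoch, preprocess and featurize a cohort
#'
#' Convenience wrapper: cuts each recording into labeled epochs, applies the
#' channel-specific filters, and extracts the six bispectral features per
#' epoch.
#'
#' @param recordings list of `recording` objects.
#' @param labels label data.frame covering all subjects.
#' @param epoch_len epoch length in seconds (default 5).
#' @param ecg_filter,emg_filter `filter_spec`s (see [preprocess_epoch()]).
#' @param hos an `hos_config`.
#' @return feature data.frame, one row per epoch.
#' @export
extract_features <- function(recordings, labels, epoch_len = 5,
                             ecg_filter = filter_spec("butterworth", 45),
                             emg_filter = filter_spec("chebyshev1", c(20, 100)),
                             hos = hos_config()) {
  rows <- list()
  for (rec in recordings) {
    sub_labels <- labels[labels$subject_id == rec$subject_id, , drop = FALSE]
    if (nrow(sub_labels) == 0L) next
    ecg_f <- design_filter(ecg_filter, rec$fs)
    emg_f <- design_filter(emg_filter, rec$fs)
    for (ep in epoch_recording(rec, sub_labels, epoch_len)) {
      ep$ecg <- apply_filter(ep$ecg, ecg_f)
      ep$emg <- apply_filter(ep$emg, emg_f)
      rows[[length(rows) + 1L]] <- extract_epoch_features(ep, hos)
    }
  }
  if (length(rows) == 0L) {
    stop("no epochs could be extracted from the given recordings/labels", call. = FALSE)
  }
  do.call(rbind, rows)
}
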