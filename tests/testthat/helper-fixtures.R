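# Fixtures built in code: synthetic feature tables and small epochs, so
# classifier/CV mechanics can be exercised without paying for full signal
# synthesis and bispectrum estimation.

# Gaussian feature rows in the package's six-column layout. `effect` shifts
# the hypnosis class mean; `subject_offset_sd` adds a per-subject random
# intercept (subject-level confounding for leakage experiments).
make_feature_df <- function(n_subjects = 10, epochs_per_state = 10,
                            effect = 0, subject_offset_sd = 0, seed = 1,
                            states_per_subject = c("normal", "hypnosis")) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    offs <- rnorm(6, 0, subject_offset_sd)
    for (st in states_per_subject) {
      shift <- if (st == "hypnosis") effect else 0
      X <- matrix(rnorm(epochs_per_state * 6), ncol = 6) +
        matrix(offs, epochs_per_state, 6, byrow = TRUE) + shift
      colnames(X) <- c("ecg_S1", "ecg_S2", "ecg_S3", "emg_S1", "emg_S2", "emg_S3")
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("S%02d", s), state = st,
        epoch_start_s = seq_len(epochs_per_state) * 5 - 5, X,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

# A tiny epoch object with given channel content.
make_epoch <- function(ecg, emg = ecg, fs = 500, subject = "S01",
                       state = "normal", start_s = 0) {
  structure(list(subject_id = subject, state = state, fs = fs,
                 ecg = ecg, emg = emg, start_s = start_s),
            class = "epoch")
}

# Forge a bispectrum estimate with a prescribed quadrant magnitude matrix.
forge_bispectrum <- function(values) {
  structure(list(values = values, freq = (0:(nrow(values) - 1)) / (nrow(values) - 1),
                 seg_len = 2L * (nrow(values) - 1L), n_segments = 1L,
                 window = "rect", overlap = 0, two_sided = FALSE),
            class = "bispectrum")
}

# Threshold R-peak detector used as an independent oracle: local maxima above
# half the global maximum, 0.3 s refractory.
detect_r_peaks <- function(x, fs) {
  cand <- which(diff(sign(diff(x))) == -2) + 1L
  cand <- cand[x[cand] > 0.5 * max(x)]
  keep <- integer(0); last <- -Inf
  for (p in cand) {
    if ((p - last) / fs > 0.3) { keep <- c(keep, p); last <- p }
  }
  keep
}
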