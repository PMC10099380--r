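# Synthetic two-state ECG/EMG cohort generator.
#
# The generator emulates the statistical structure the bispectral pipeline is
# designed to detect: the two driver states differ in heart-rate statistics
# (RR-interval mean and spread), EMG amplitude, and the strength of a
# quadratically phase-coupled harmonic pair inside the EMG band. It does not
# attempt physiologically faithful morphology beyond a stylized PQRST beat.

#' Per-state simulation parameters
#'
#' Bundles the quantities through which the two driving states (normal vs
#' road hypnosis) differ in the synthetic cohort: RR-interval statistics for
#' the ECG, and amplitude/band/phase-coupling settings for the EMG.
#'
#' Defaults encode a recoverable-but-not-trivial contrast: hypnosis slows and
#' regularizes the heart (longer mean RR, smaller spread), relaxes the
#' musculature (lower EMG RMS), and strengthens quadratic phase coupling.
#' Real road-hypnosis physiology is not characterized quantitatively in the
#' literature; these directions and magnitudes are placeholders chosen once
#' for the simulation study, not measured values.
#'
#' @param state `"normal"` or `"hypnosis"`.
#' @param mean_rr mean RR interval in seconds (> 0).
#' @param sd_rr standard deviation of RR intervals in seconds (>= 0).
#' @param emg_rms target RMS of the band-limited EMG noise component, mV.
#' @param emg_band numeric length-2, EMG noise band (low, high) in Hz.
#' @param qpc_strength amplitude of the quadratically phase-coupled cosine
#'   triple, as a multiple of `emg_rms` (>= 0).
#' @param coupling_freqs numeric length-2, the coupled pair (f1, f2) in Hz;
#'   the third component sits at f1 + f2.
#' @return an object of class `state_params`.
#' @export
#' @examples
#' state_params("hypnosis")
state_params <- function(state = c("normal", "hypnosis"),
                         mean_rr = if (state == "hypnosis") 0.95 else 0.80,
                         sd_rr = if (state == "hypnosis") 0.03 else 0.06,
                         emg_rms = if (state == "hypnosis") 0.05 else 0.12,
                         emg_band = c(20, 100),
                         qpc_strength = if (state == "hypnosis") 1.0 else 0.2,
                         coupling_freqs = c(30, 40)) {
  state <- match.arg(state)
  stopifnot_scalar_number(mean_rr, "mean_rr", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(sd_rr, "sd_rr", min = 0)
  stopifnot_scalar_number(emg_rms, "emg_rms", min = 0)
  stopifnot_scalar_number(qpc_strength, "qpc_strength", min = 0)
  if (length(emg_band) != 2L || emg_band[1] <= 0 || emg_band[1] >= emg_band[2]) {
    stop("`emg_band` must be (low, high) with 0 < low < high", call. = FALSE)
  }
  if (length(coupling_freqs) != 2L || any(coupling_freqs <= 0)) {
    stop("`coupling_freqs` must be two positive frequencies", call. = FALSE)
  }
  structure(
    list(state = state, mean_rr = mean_rr, sd_rr = sd_rr, emg_rms = emg_rms,
         emg_band = as.numeric(emg_band), qpc_strength = qpc_strength,
         coupling_freqs = as.numeric(coupling_freqs)),
    class = "state_params"
  )
}

#' Cohort simulation configuration
#'
#' @param preset `"default"` (every subject contributes both states, useful
#'   for subject-grouped cross-validation), `"paper_vehicle"` (35 single-state
#'   subjects: 25 normal, 10 hypnosis, mirroring the vehicle-experiment
#'   screening counts), or `"paper_simulated"` (43 subjects: 27 normal,
#'   16 hypnosis, mirroring the simulator-experiment counts).
#' @param n_subjects number of subjects; ignored by the two cohort presets,
#'   which fix it at 35 and 43 respectively.
#' @param minutes_per_state minutes of signal per subject per contributed
#'   state (default 10, the amount screened per group in the study design).
#' @param fs sampling rate in Hz (default 500; must exceed twice the EMG band
#'   high edge).
#' @param seed master integer seed; all subject-level randomness derives from
#'   it deterministically.
#' @param normal_params,hypnosis_params `state_params` objects.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(preset = c("default", "paper_vehicle", "paper_simulated"),
                          n_subjects = 20,
                          minutes_per_state = 10,
                          fs = 500,
                          seed = 1,
                          normal_params = state_params("normal"),
                          hypnosis_params = state_params("hypnosis")) {
  preset <- match.arg(preset)
  stopifnot_scalar_number(minutes_per_state, "minutes_per_state", 0, TRUE)
  stopifnot_scalar_number(fs, "fs", 0, TRUE)
  stopifnot_scalar_number(n_subjects, "n_subjects", 1)
  for (p in list(normal_params, hypnosis_params)) {
    if (!inherits(p, "state_params")) stop("state params must be `state_params` objects")
    if (p$emg_band[2] >= fs / 2) {
      stop("EMG band high edge must be below the Nyquist frequency fs/2", call. = FALSE)
    }
  }
  if (preset == "paper_vehicle") n_subjects <- 35L
  if (preset == "paper_simulated") n_subjects <- 43L
  structure(
    list(preset = preset, n_subjects = as.integer(n_subjects),
         minutes_per_state = minutes_per_state, fs = fs,
         seed = as.integer(seed),
         normal_params = normal_params, hypnosis_params = hypnosis_params),
    class = "cohort_config"
  )
}

#' Generate a series of RR intervals
#'
#' Draws RR intervals from a truncated Gaussian: draws at or below 0.25 s are
#' resampled, so every interval is physiologically plausible and positive.
#'
#' @param params a `state_params` object (uses `mean_rr`, `sd_rr`).
#' @param n_beats number of intervals (>= 0).
#' @param seed integer seed; identical seeds reproduce the series exactly.
#' @return numeric vector of `n_beats` RR intervals in seconds.
#' @export
#' @examples
#' generate_rr_series(state_params("normal"), n_beats = 5, seed = 1)
generate_rr_series <- function(params, n_beats, seed = 1) {
  if (!is.numeric(n_beats) || length(n_beats) != 1L || is.na(n_beats) || n_beats < 0) {
    stop("`n_beats` must be a nonnegative count", call. = FALSE)
  }
  n_beats <- as.integer(n_beats)
  if (n_beats == 0L) return(numeric(0))
  with_seed(seed, {
    rr <- stats::rnorm(n_beats, params$mean_rr, params$sd_rr)
    bad <- which(rr <= 0.25)
    guard <- 0L
    while (length(bad) > 0L && guard < 1000L) {
      rr[bad] <- stats::rnorm(length(bad), params$mean_rr, params$sd_rr)
      bad <- which(rr <= 0.25)
      guard <- guard + 1L
    }
    if (length(bad) > 0L) rr[bad] <- params$mean_rr
    rr
  })
}

# Default PQRST morphology: Gaussian bump amplitudes (mV), centers relative to
# the R peak (s), and widths (s).
default_ecg_morphology <- function() {
  list(
    amplitude = c(P = 0.12, Q = -0.1, R = 1.0, S = -0.25, T = 0.3),
    center    = c(P = -0.20, Q = -0.040, R = 0.0, S = 0.040, T = 0.30),
    width     = c(P = 0.025, Q = 0.010, R = 0.012, S = 0.012, T = 0.060)
  )
}

#' Synthesize an ECG signal from RR intervals
#'
#' Places one stylized template beat (a sum of localized P, Q, R, S and T
#' Gaussian bumps) per RR interval. Deterministic: no noise is added here.
#'
#' @param rr numeric vector of RR intervals, seconds.
#' @param fs sampling rate in Hz (>= 100, so the narrow QRS bumps are resolved).
#' @param morphology list with named numeric vectors `amplitude`, `center`,
#'   `width` (see `default_ecg_morphology` in the sources); all-zero
#'   amplitudes yield an all-zero signal.
#' @return numeric vector of length `round(fs * sum(rr))`, millivolts.
#' @export
synthesize_ecg <- function(rr, fs, morphology = default_ecg_morphology()) {
  if (fs < 100) stop("`fs` must be >= 100 Hz: the beat template is undersampled below that", call. = FALSE)
  n <- round(fs * sum(rr))
  sig <- numeric(n)
  if (length(rr) == 0L || n == 0L) return(sig)
  t <- (seq_len(n) - 1) / fs
  onsets <- c(0, cumsum(rr)[-length(rr)])
  # R peak placed 40% into each interval so P and T waves stay inside it
  r_times <- onsets + 0.4 * rr
  for (b in seq_along(rr)) {
    for (w in seq_along(morphology$amplitude)) {
      a <- morphology$amplitude[w]
      if (a == 0) next
      mu <- r_times[b] + morphology$center[w]
      sd <- morphology$width[w]
      lo <- max(1L, floor((mu - 5 * sd) * fs) + 1L)
      hi <- min(n, ceiling((mu + 5 * sd) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      sig[idx] <- sig[idx] + a * exp(-0.5 * ((t[idx] - mu) / sd)^2)
    }
  }
  sig
}

#' Synthesize a surface-EMG-like signal
#'
#' Band-limited Gaussian noise scaled to a target RMS, plus a quadratically
#' phase-coupled cosine triple at (f1, f2, f1+f2) whose phases satisfy
#' phi3 = phi1 + phi2 — the canonical structure producing a bispectral peak.
#' Cosine amplitudes are `qpc_strength * emg_rms` each.
#'
#' @param params a `state_params` object.
#' @param duration seconds of signal.
#' @param fs sampling rate in Hz; must exceed twice the band high edge.
#' @param seed integer seed.
#' @return numeric vector of `round(duration * fs)` samples, millivolts.
#' @export
synthesize_emg <- function(params, duration, fs, seed = 1) {
  if (fs <= 2 * params$emg_band[2]) {
    stop("`fs` must exceed twice the EMG band high edge", call. = FALSE)
  }
  n <- round(duration * fs)
  if (n == 0L) return(numeric(0))
  with_seed(seed, {
    sig <- numeric(n)
    if (params$emg_rms > 0) {
      noise <- stats::rnorm(n)
      bp <- signal::butter(4, params$emg_band / (fs / 2), type = "pass")
      noise <- signal::filtfilt(bp, noise)
      sig <- noise * (params$emg_rms / rms(noise))
    }
    amp <- params$qpc_strength * params$emg_rms
    if (amp > 0) {
      t <- (seq_len(n) - 1) / fs
      f1 <- params$coupling_freqs[1]
      f2 <- params$coupling_freqs[2]
      ph <- stats::runif(2, 0, 2 * pi)
      sig <- sig +
        amp * cos(2 * pi * f1 * t + ph[1]) +
        amp * cos(2 * pi * f2 * t + ph[2]) +
        amp * cos(2 * pi * (f1 + f2) * t + ph[1] + ph[2])
    }
    sig
  })
}

# Build one subject's recording: concatenated state segments with matching
# label intervals.
simulate_subject <- function(subject_id, states, config, subject_seed) {
  fs <- config$fs
  dur <- config$minutes_per_state * 60
  n_seg <- round(dur * fs)
  ecg <- numeric(0)
  emg <- numeric(0)
  intervals <- data.frame(subject_id = character(0), start_s = numeric(0),
                          end_s = numeric(0), state = character(0),
                          stringsAsFactors = FALSE)
  t0 <- 0
  for (si in seq_along(states)) {
    st <- states[si]
    p <- if (st == "hypnosis") config$hypnosis_params else config$normal_params
    n_beats <- ceiling(dur / p$mean_rr * 1.25) + 10L
    rr <- generate_rr_series(p, n_beats, seed = derive_seed(subject_seed, 2L * si))
    e <- synthesize_ecg(rr, fs)
    if (length(e) < n_seg) e <- c(e, numeric(n_seg - length(e)))
    ecg <- c(ecg, e[seq_len(n_seg)])
    emg <- c(emg, synthesize_emg(p, dur, fs, seed = derive_seed(subject_seed, 2L * si + 1L)))
    intervals <- rbind(intervals, data.frame(
      subject_id = subject_id, start_s = t0, end_s = t0 + dur, state = st,
      stringsAsFactors = FALSE))
    t0 <- t0 + dur
  }
  list(
    recording = new_recording(subject_id, fs, ecg, emg),
    labels = intervals
  )
}

#' Generate a synthetic two-state cohort
#'
#' Produces one recording and one label track per subject, deterministically
#' under the config's seed. Under the `default` preset every subject
#' contributes one normal and one hypnosis segment (back to back); under the
#' `paper_vehicle` / `paper_simulated` presets each subject contributes a
#' single state, with the cohort split 25/10 (of 35) and 27/16 (of 43)
#' respectively.
#'
#' @param config a `cohort_config` object.
#' @return list with elements `recordings` (list of `recording` objects) and
#'   `labels` (one data.frame of labeled intervals, columns
#'   `subject_id,start_s,end_s,state`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 1, minutes_per_state = 1))
#' cohort$labels
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("`config` must be a `cohort_config`")
  subject_states <- switch(config$preset,
    default = replicate(config$n_subjects, c("normal", "hypnosis"), simplify = FALSE),
    paper_vehicle = c(replicate(25, "normal", simplify = FALSE),
                      replicate(10, "hypnosis", simplify = FALSE)),
    paper_simulated = c(replicate(27, "normal", simplify = FALSE),
                        replicate(16, "hypnosis", simplify = FALSE))
  )
  n <- length(subject_states)
  ids <- sprintf("S%02d", seq_len(n))
  recordings <- vector("list", n)
  labels <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- simulate_subject(ids[i], subject_states[[i]], config,
                            subject_seed = derive_seed(config$seed, i))
    recordings[[i]] <- sub$recording
    labels[[i]] <- sub$labels
  }
  list(recordings = recordings, labels = do.call(rbind, labels))
}
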