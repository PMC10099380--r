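# Channel-specific denoising: 4th-order Butterworth low-pass at 45 Hz for the
# ECG, 4th-order Chebyshev type-I band-pass 20-100 Hz for the EMG. The 45 Hz
# specification is interpreted as a LOW-PASS cutoff (standard ECG denoising
# against powerline and EMG contamination); a notch or band-edge reading is
# also defensible, so the interpretation is stated prominently in the docs.

#' Filter specification
#'
#' @param family `"butterworth"` (low-pass) or `"chebyshev1"` (band-pass,
#'   type I with passband ripple).
#' @param band scalar cutoff in Hz (butterworth) or length-2 `(low, high)` Hz
#'   (chebyshev1). All edges must be below the Nyquist frequency.
#' @param order filter order (default 4).
#' @param ripple_db passband ripple in dB, chebyshev only (default 0.5).
#' @param zero_phase apply forward-backward (no group delay; squares the
#'   magnitude response)? Default `TRUE`.
#' @return an object of class `filter_spec`.
#' @export
#' @examples
#' filter_spec("butterworth", 45)
#' filter_spec("chebyshev1", c(20, 100))
filter_spec <- function(family = c("butterworth", "chebyshev1"), band,
                        order = 4, ripple_db = 0.5, zero_phase = TRUE) {
  family <- match.arg(family)
  if (family == "butterworth" && length(band) != 1L) {
    stop("butterworth spec takes a scalar cutoff in Hz", call. = FALSE)
  }
  if (family == "chebyshev1" && (length(band) != 2L || band[1] >= band[2])) {
    stop("chebyshev1 spec takes (low, high) Hz with low < high", call. = FALSE)
  }
  if (any(band <= 0)) stop("band frequencies must be positive", call. = FALSE)
  structure(list(family = family, band = as.numeric(band), order = order,
                 ripple_db = ripple_db, zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Design digital filter coefficients from a spec
#'
#' @param spec a `filter_spec`.
#' @param fs sampling rate, Hz.
#' @return list with `b`, `a` coefficient vectors plus the spec and `fs`;
#'   class `designed_filter`. Stability (all poles strictly inside the unit
#'   circle) is verified at design time.
#' @export
design_filter <- function(spec, fs) {
  if (!inherits(spec, "filter_spec")) stop("`spec` must be a `filter_spec`")
  if (any(spec$band >= fs / 2)) {
    stop(sprintf("filter band (%s Hz) must lie below the Nyquist frequency %g Hz",
                 paste(spec$band, collapse = "-"), fs / 2), call. = FALSE)
  }
  w <- spec$band / (fs / 2)
  flt <- switch(spec$family,
    butterworth = signal::butter(spec$order, w, type = "low"),
    chebyshev1  = signal::cheby1(spec$order, spec$ripple_db, w, type = "pass")
  )
  poles <- polyroot(rev(flt$a))
  if (any(Mod(poles) >= 1)) stop("designed filter is unstable", call. = FALSE)
  structure(list(b = as.numeric(flt$b), a = as.numeric(flt$a),
                 spec = spec, fs = fs),
            class = "designed_filter")
}

#' Complex frequency response of a designed filter
#'
#' Evaluates H(e^{-i 2 pi f / fs}) from the coefficients; in zero-phase mode
#' the effective magnitude response is |H|^2.
#'
#' @param filt a `designed_filter`.
#' @param f frequencies in Hz.
#' @param single_pass return the single-pass response even if the spec is
#'   zero-phase? Default `FALSE` (response of the applied operation).
#' @return complex vector (zero-phase responses are real nonnegative).
#' @export
filter_response <- function(filt, f, single_pass = FALSE) {
  z <- exp(-1i * 2 * pi * f / filt$fs)
  num <- vapply(z, function(zz) sum(filt$b * zz^(seq_along(filt$b) - 1)), complex(1))
  den <- vapply(z, function(zz) sum(filt$a * zz^(seq_along(filt$a) - 1)), complex(1))
  H <- num / den
  if (filt$spec$zero_phase && !single_pass) Mod(H)^2 + 0i else H
}

#' Apply a filter to a signal
#'
#' @param x numeric signal.
#' @param spec a `filter_spec` or an already-designed `designed_filter`.
#' @param fs sampling rate in Hz (ignored when `spec` is already designed).
#' @return filtered signal, same length as `x`.
#' @export
apply_filter <- function(x, spec, fs = NULL) {
  filt <- if (inherits(spec, "designed_filter")) spec else design_filter(spec, fs)
  min_len <- 3 * filt$spec$order
  if (length(x) <= min_len) {
    stop(sprintf("signal too short to filter: need more than %d samples", min_len),
         call. = FALSE)
  }
  flt <- signal::Arma(b = filt$b, a = filt$a)
  if (filt$spec$zero_phase) {
    as.numeric(signal::filtfilt(flt, x))
  } else {
    as.numeric(signal::filter(flt, x))
  }
}

#' Denoise an epoch's channels
#'
#' Routes the ECG channel through the Butterworth low-pass and the EMG channel
#' through the Chebyshev band-pass; metadata (subject, state, start time) is
#' untouched.
#'
#' @param epoch an `epoch`.
#' @param ecg_filter,emg_filter `filter_spec` objects (defaults: Butterworth
#'   45 Hz low-pass, Chebyshev I 20-100 Hz band-pass, both order 4,
#'   zero-phase).
#' @return the epoch with filtered channels.
#' @export
preprocess_epoch <- function(epoch,
                             ecg_filter = filter_spec("butterworth", 45),
                             emg_filter = filter_spec("chebyshev1", c(20, 100))) {
  epoch$ecg <- apply_filter(epoch$ecg, ecg_filter, epoch$fs)
  epoch$emg <- apply_filter(epoch$emg, emg_filter, epoch$fs)
  epoch
}
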