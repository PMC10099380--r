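---
title: "Bispectral identification of road hypnosis: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bispectral identification of road hypnosis: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roadhos)
```

## The problem and the model

Road hypnosis is an unconscious driving state: in a monotonous or highly
predictable environment the driver continues to steer, hold the lane and
keep speed, yet with reduced alertness and often no later memory of the
stretch. Because overt behaviour stays near normal, identification leans on
physiology. This package uses two channels with complementary information:
the ECG carries heart-rate dynamics, and the surface EMG carries muscle
tone and action.

The discriminative representation is the bispectrum,
\[
B(f_1, f_2) \;=\; \mathrm{E}\!\left[\,X(f_1)\,X(f_2)\,X^{*}(f_1+f_2)\,\right],
\]
the Fourier dual of the third-order cumulant. Unlike the power spectrum it
retains phase relations: it is non-zero precisely where components at
$f_1$, $f_2$ and $f_1+f_2$ are *quadratically phase-coupled*
($\varphi_3=\varphi_1+\varphi_2$), the canonical signature of quadratic
nonlinearity in a signal-generating system. Each epoch and channel is
summarized by three functionals of the estimated bispectrum over the
principal region $\Omega=\{0\le f_2\le f_1,\ f_1+f_2\le 1\}$ (frequencies
normalized to 1 at Nyquist):

* $S_1=\sum_{\Omega}\log|B(f_1,f_2)|$,
* $S_2=\sum_{k}\log|B(f_k,f_k)|$ over the diagonal bins of $\Omega$,
* $S_3=\sum_{k} k\,\log|B(f_k,f_k)|$, the first-order spectral moment of
  the diagonal log magnitudes.

The six per-epoch features (three per channel) are z-scored, fused by PCA
retaining the top two eigenvectors of the covariance matrix, and classified
with LDA, QDA or KNN. Evaluation reports accuracy, sensitivity and
specificity (hypnosis positive) under random shuffle-split CV and under
subject-grouped k-fold CV.

Assumptions worth stating: epochs are treated as weakly stationary at the
5 s scale; the expectation in $B$ is realized by segment averaging within
an epoch; and class information is assumed to express itself in heart-rate
statistics, EMG amplitude/band content, and phase-coupling strength — the
three axes the synthetic generator controls.

## Estimator and its numerical choices

The bispectrum uses the direct (FFT-based) method: segments of
`seg_len = 256` samples with 50% overlap, per-segment mean removal, a Hann
window, and averaging of the triple products across segments. The defining
equation fixes no estimator; segment averaging is the standard
variance-reducing choice, and at 500 Hz a 256-sample segment gives a
1.95 Hz bifrequency resolution with 18 (overlapping) segments per 5 s
epoch.

Three numerical details matter:

* **Hermitian enforcement.** The DFT of a real segment is Hermitian in
  exact arithmetic but not in floating point. Each segment's DFT is
  symmetrized exactly before the triple products are formed.
* **Canonical orbit evaluation.** Every bifrequency bin is the product of
  DFT values at the frequency triple $(j, k, -j-k)$. All twelve symmetry
  images of a bin share one triple up to permutation and negation, so each
  bin is evaluated from a canonical representative (sorted indices,
  lexicographically smaller of the triple and its negation, conjugated
  back). The symmetry relations of the output therefore hold *exactly*,
  not merely to rounding.
* **Log floor.** Magnitudes are floored at `log_floor = 1e-12` before the
  natural log, so bins that vanish (e.g. the DC bin after mean removal
  with a rectangular window) contribute a large negative constant instead
  of $-\infty$.

With the mean removed per segment, the second and third moments equal the
second and third cumulants, which is what makes the triple-product form of
$B$ the transform of the third cumulant. The fourth-order cumulant (where
moment and cumulant first diverge) is implemented and tested for
completeness but takes no part in the feature pipeline.

$S_3$'s diagonal runs over the bins with $f_k+f_k\le 1$, i.e. `L/4 + 1`
bins including DC; the bins are indexed $k=1..N$ in frequency order. The
sums use $|B|$: the features are defined on amplitudes, and the complex
phase of an averaged estimate is not a stable epoch statistic.

## Preprocessing

ECG is low-pass filtered with a 4th-order Butterworth at 45 Hz; EMG is
band-passed with a 4th-order Chebyshev type I at 20–100 Hz. Two points are
deliberate interpretations and are flagged as such:

* "Butterworth at 45 Hz" is read as a **low-pass cutoff** — the standard
  ECG denoising choice, suppressing powerline interference and EMG
  contamination while keeping QRS energy. A notch or band-edge reading
  would also be defensible; the choice is configurable
  (`ecg_filter.cutoff_hz`).
* The Chebyshev type (I) and its passband ripple (0.5 dB) are unstated in
  the method's source tradition; type I with 0.5 dB is the common default.

Both filters apply forward–backward (zero phase) by default, which
preserves waveform timing, doubles the effective order, and squares the
magnitude response — hence the design contract that the squared-magnitude
gain of the ECG filter at its 45 Hz cutoff is 0.5. Single-pass application
is available by flag.

## The synthetic cohort generator

No public road-hypnosis recordings exist, so the generator emulates the
statistical structure the method targets, not driving physiology in full:

* **ECG**: RR intervals from a truncated Gaussian (draws ≤ 0.25 s
  resampled), one stylized PQRST template beat (sum of five Gaussian
  bumps) per interval.
* **EMG**: band-limited Gaussian noise (20–100 Hz) scaled to a target RMS,
  plus a cosine triple at (30, 40, 70) Hz with
  $\varphi_3=\varphi_1+\varphi_2$, each cosine's amplitude
  `qpc_strength × emg_rms`.

Default state contrasts (hypnosis vs normal): mean RR 0.95 s vs 0.80 s, RR
spread 0.03 s vs 0.06 s, EMG RMS 0.05 mV vs 0.12 mV, coupling strength 1.0
vs 0.2. The direction and magnitude of real road-hypnosis effects are not
quantitatively characterized in the literature; these values are
placeholders chosen once to be recoverable but not degenerate, and they
encode the qualitative reading "slower, more regular heart; relaxed
musculature; stronger nonlinear coupling". The sampling rate defaults to
500 Hz (no canonical value exists; 500 Hz supports the 20–100 Hz EMG band
and ECG morphology).

Cohort presets mirror the screening counts of the study design the package
follows: `paper_vehicle` gives 35 single-state subjects (25 normal, 10
hypnosis), `paper_simulated` 43 (27/16), both with 10 min of signal per
subject. The `default` preset instead gives every subject one normal *and*
one hypnosis segment, which is the useful layout for subject-grouped CV
(single-state subjects make fold-level class balance fragile).

What passing tests on this generator shows — and what it does not: the
pipeline provably recovers class structure expressed through heart-rate
statistics, EMG amplitude and quadratic phase coupling, at realistic SNR,
without subject leakage; it does not show that real drivers express road
hypnosis along these axes, nor at these effect sizes. Motion artifacts,
electrode noise, respiration coupling and morphology pathology are
explicitly out of scope.

## Fusion and classification choices

* **Fusion architecture.** The two channel triples are concatenated into
  one 6-vector and fused by a single joint PCA — the minimal reading of
  "fusing the signals with PCA". Per-channel PCAs with later concatenation
  would be a different (unrequested) architecture.
* **Standardization.** $S_1$ sums thousands of log-magnitude bins while
  $S_2$ sums tens; without z-scoring, PCA would be an $S_1$ detector.
  Population (divisor $N$) covariance is used throughout, matching the
  defining formula; the divisor does not alter eigenvectors.
* **Two components, fixed.** The retained dimension is fixed at 2 a
  priori, not chosen by a variance threshold. On default cohorts the two
  components carry ~95% of the standardized variance.
* **Sign convention.** Within each component the largest-magnitude loading
  is made positive, so refits (e.g. across permuted row orders) are
  reproducible.
* **KNN** uses Euclidean distance on the two fused components; ties in the
  vote (possible for even K) fall back to the single nearest neighbour's
  label, making prediction deterministic. K defaults to 9; `select_knn_k`
  scans 5–10 by cross-validated accuracy with ties to the smallest K. On
  fully separable synthetic cohorts every K ties at 100%, so the scan
  returns 5 — the tie rule, not a contradiction of the K = 9 default.
* **LDA/QDA** are fitted with `MASS`. The fused 2-D scores of any
  non-degenerate cohort give well-conditioned class covariances; a
  training set whose within-class covariance is singular is rejected with
  an informative error rather than silently regularized.

## Cross-validation design

Random CV stratifies a 70/30 shuffle-split and repeats it (20 repeats by
default, averaged) — one shuffle would be an unstable estimate. Its known
defect is deliberate: epochs from the same subject land on both sides, so
subject identity leaks and scores are optimistic. Subject-grouped k-fold
(k = 5 by default; the grouping unit is the subject because same-subject
leakage is the failure mode being controlled) partitions *subjects*, tests
every epoch exactly once, and refits the PCA and the classifier inside
each fold's training side only. The test suite asserts the leakage
properties structurally (no subject on both sides of any fold; fold models
depend only on training rows) and demonstrates the inflation on cohorts
with injected per-subject offsets.

The classification unit is the 5 s epoch: at 500 Hz it holds 2500 samples
(ample for 256-sample bispectrum segments) and 10 min of signal yields 120
epochs per subject-state. Treating whole 10-min blocks as single samples
would leave too few samples for stable confusion counts.

## Problem sizes and verification

The test suite and the acceptance script size their experiments as
follows, chosen as sensible defaults for the study conditions: the
recovery and reproduction experiments use 20 subjects × 10 min per state
(4800 epochs); chance-level (null-effect) checks use 20 subjects × 1 min
per state (480 epochs, every one tested once under group k-fold, with the
chance band taken as 40–60%); structural leakage checks use 20 subjects ×
30 s per state. The quadratic-phase-coupling benchmark uses a 600 s signal
at 500 Hz containing a unit-amplitude cosine triple at (30, 40, 70) Hz in
white noise of standard deviation 7 — an SNR at which the coupled triple's
bispectral peak stands an order of magnitude above the off-peak median
while a per-segment-randomized third phase collapses it into the
background, which is exactly the contrast that separates genuine quadratic
coupling from mere spectral co-occurrence.

## Known limitations

* The generator's effect sizes are assumptions; real effect directions and
  magnitudes for road hypnosis are unknown. Results on synthetic cohorts
  bound what the *pipeline* can do, not what real data will yield.
* The 45 Hz low-pass reading of the ECG filter is an interpretation (see
  above).
* Epoch-level classification is an assumption; block-level aggregation is
  not implemented.
* No artifact rejection or baseline-wander removal is performed; the
  synthetic data do not need it and real deployments would.
* Bicoherence normalization and trispectrum features are out of scope.
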