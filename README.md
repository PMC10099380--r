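# roadhos

Recognition of **road hypnosis** — the unconscious driving state that arises
in monotonous, highly predictable environments (long highway stretches,
tunnels, the same daily commute) — from two driver physiological channels:
the electrocardiogram (ECG) and the electromyogram (EMG). A driver in road
hypnosis keeps operating the vehicle but with reduced alertness, which makes
the state dangerous precisely because it is inconspicuous. The package is
aimed at researchers in driver-state monitoring and physiological signal
processing who want a tested, reproducible reference implementation of a
bispectrum-based identification pipeline.

## The method

Ordinary second-order statistics (power spectra) discard phase relations.
Higher-order spectra keep them: the **bispectrum**

```
B(f1, f2) = E[ X(f1) X(f2) X*(f1 + f2) ]
```

(X the Fourier transform of the signal, `*` conjugation, E the expectation,
realized here by averaging over Hann-windowed, mean-removed, 50%-overlapping
segments) is non-zero exactly where three spectral components at `f1`, `f2`
and `f1 + f2` are quadratically phase-coupled — the canonical nonlinear
signature this pipeline looks for in driver physiology. Frequencies are
normalized to `[0, 1]` at Nyquist and features are summed over the
non-redundant principal region Ω = {0 ≤ f2 ≤ f1, f1 + f2 ≤ 1}:

- `S1 = Σ_Ω log |B(f1, f2)|` — total log bispectral magnitude,
- `S2 = Σ_k log |B(f_k, f_k)|` — the same sum over the diagonal,
- `S3 = Σ_k k · log |B(f_k, f_k)|` — first-order spectral moment of the
  diagonal log magnitudes.

Each 5 s epoch contributes the triple per channel after channel-specific
denoising (4th-order Butterworth low-pass at 45 Hz for ECG; 4th-order
Chebyshev type-I band-pass 20–100 Hz for EMG). The two channel triples are
concatenated, z-scored, and fused by PCA with **two retained components**;
LDA, QDA and KNN (K = 9 by default, selected over 5–10) classify the fused
scores. Performance is reported as accuracy `AC = 100·(TP+TN)/total`,
sensitivity `SE = TP/(TP+FN)` and specificity `SP = TN/(TN+FP)` with
hypnosis as the positive class, under two cross-validation schemes: repeated
stratified 70/30 shuffle-splits, and **subject-grouped k-fold** (k = 5), in
which no driver ever contributes to both the training and the test side —
the honest estimate of generalization to unseen drivers.

Real road-hypnosis recordings are private human-subject data, so the package
ships a synthetic two-state cohort generator whose classes differ in
heart-rate statistics (RR mean/spread), EMG amplitude, and the strength of a
quadratically phase-coupled harmonic pair — the statistical structure the
method is designed to detect.

## Worked example

```r
library(roadhos)
cohort   <- generate_cohort(cohort_config(n_subjects = 6, minutes_per_state = 2, seed = 42))
features <- extract_features(cohort$recordings, cohort$labels, epoch_len = 5)
model    <- hypnosis_model(features, classifier = "knn", k = 9)
print(model)
#> Road-hypnosis identification model
#>   classifier: KNN (k = 9) on 2 fused component(s)
#>   trained on 288 epochs (144 normal, 144 hypnosis)

cv <- group_kfold_cv(features, classifier = "knn", k_folds = 3, k = 9, seed = 42)
print(cv)
#> <hypno_cv> group_kfold / KNN(k=9) over 3 fold(s)
#>   pooled: AC 100.0%  SE 1.000  SP 1.000  (TP 144 TN 144 FP 0 FN 0)
```

288 epochs = 6 subjects × 2 states × 24 epochs (2 min / 5 s). The pooled
confusion counts come from testing every epoch exactly once on folds whose
training side never saw the tested subject; with the generator's default
effect sizes the two states are fully separable, so AC = 100%, SE = SP = 1.
`summary(model)` additionally prints the PCA loadings: on this cohort the
first two components carry ~95% of the standardized feature variance, with
PC1 loading on overall bispectral magnitude and PC2 contrasting the ECG
against the EMG triple.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/roadhos.R simulate --n-subjects 20 --minutes 10 --seed 1 --out out/
Rscript inst/cli/roadhos.R extract  --in out/ --features-out features.csv
Rscript inst/cli/roadhos.R evaluate --features features.csv --classifier knn \
    --cv group-kfold --folds 5 --knn-k 9 --report report.json
```

or in one step from a YAML config with `run-all` / `run_pipeline()`.

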