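# Moments, cumulants, spectra and the bispectral features.

test_that("moments match brute-force enumeration", {
  z <- signal_moments(numeric(8), 2)
  expect_equal(z$m1, 0)
  expect_true(all(z$m2 == 0) && all(z$m3 == 0))

  m <- signal_moments(c(1, 2, 3, 4), 1)
  xc <- c(1, 2, 3, 4) - 2.5
  expect_equal(m$m1, 2.5)
  expect_equal(unname(m$m2["1"]), sum(xc[1:3] * xc[2:4]) / 3)
  expect_equal(unname(m$m2["0"]), mean(xc^2))

  # third moment against explicit loops on a random vector
  set.seed(2)
  x <- rnorm(30)
  xc <- x - mean(x)
  mm <- signal_moments(x, 3)
  for (t1 in 0:3) for (t2 in 0:3) {
    k <- 1:(30 - max(t1, t2))
    expect_equal(mm$m3[t1 + 1, t2 + 1],
                 sum(xc[k] * xc[k + t1] * xc[k + t2]) / length(k))
  }
  expect_error(signal_moments(1:5, 5), "max_lag")
})

test_that("second-moment estimator is even in the lag", {
  set.seed(3)
  x <- rnorm(50)
  xc <- x - mean(x)
  for (tau in 1:5) {
    expect_equal(roadhos:::lagged_product_mean(xc, c(0L, tau)),
                 roadhos:::lagged_product_mean(xc, c(0L, -tau)))
  }
})

test_that("fourth cumulant subtracts the Gaussian part", {
  expect_equal(fourth_cumulant(numeric(20), 0, 0, 0), 0)

  # algebraic identity: m4 minus the three c2 products, via explicit loops
  set.seed(4)
  x <- rnorm(40)
  xc <- x - mean(x)
  lpm <- function(lags) {
    lo <- 1 - min(c(lags, 0)); hi <- 40 - max(c(lags, 0))
    k <- lo:hi
    acc <- rep(1, length(k))
    for (tau in lags) acc <- acc * xc[k + tau]
    mean(acc)
  }
  for (lags in list(c(0, 0, 0), c(1, 2, 3), c(2, 0, 1))) {
    expected <- lpm(c(0, lags)) -
      lpm(c(0, lags[1])) * lpm(c(0, lags[3] - lags[2])) -
      lpm(c(0, lags[2])) * lpm(c(0, lags[3] - lags[1])) -
      lpm(c(0, lags[3])) * lpm(c(0, lags[2] - lags[1]))
    expect_equal(fourth_cumulant(x, lags[1], lags[2], lags[3]), expected)
  }
  expect_error(fourth_cumulant(rnorm(10), 0, 0, 10), "out of range")
})

test_that("fourth cumulant of white Gaussian noise is null", {
  reps <- vapply(1:50, function(s) {
    set.seed(s)
    fourth_cumulant(rnorm(50000), 0, 0, 0)
  }, numeric(1))
  expect_lt(abs(mean(reps)), 5 * stats::sd(reps) / sqrt(50))
})

test_that("power spectrum satisfies Parseval and locates a sinusoid", {
  expect_true(all(power_spectrum(numeric(16))$power == 0))
  expect_error(power_spectrum(numeric(0)), "nonempty")

  set.seed(5)
  x <- rnorm(128)
  xc <- x - mean(x)
  P2 <- Mod(stats::fft(xc))^2 / 128
  expect_lt(abs(sum(P2) - 128 * mean(xc^2)) / (128 * mean(xc^2)), 1e-9)
  ps <- power_spectrum(x)
  expect_true(all(ps$power >= 0))
  expect_length(ps$power, 65)

  tone <- sin(2 * pi * 8 * (0:63) / 64)
  expect_equal(which.max(power_spectrum(tone)$power), 9)  # bin 8, 1-based
})

test_that("single-segment rectangular estimate equals the literal triple product", {
  set.seed(6)
  x <- rnorm(64)
  B <- estimate_bispectrum(x, seg_len = 64, overlap = 0, window = "rect",
                           two_sided = TRUE)
  X <- stats::fft(x - mean(x))
  L <- 64
  oracle <- matrix(0 + 0i, L, L)
  for (j in 0:(L - 1)) for (k in 0:(L - 1)) {
    oracle[j + 1, k + 1] <- X[j + 1] * X[k + 1] * Conj(X[(j + k) %% L + 1])
  }
  expect_lt(max(Mod(B$values - oracle)) / max(Mod(oracle)), 1e-10)
})

test_that("bispectrum estimator validates inputs and nulls zero signals", {
  expect_true(all(Mod(estimate_bispectrum(numeric(512))$values) == 0))
  expect_error(estimate_bispectrum(rnorm(100), seg_len = 256), "exceed")
  expect_error(estimate_bispectrum(rnorm(512), overlap = 1), "overlap")
  expect_error(estimate_bispectrum(rnorm(512), overlap = -0.1), "overlap")
})

test_that("bispectrum is exchange-symmetric and third-order homogeneous", {
  set.seed(7)
  x <- rnorm(1024)
  B <- estimate_bispectrum(x, 128, 0.5, "hann")
  expect_lt(max(Mod(B$values - t(B$values))), 1e-12)

  Ba <- estimate_bispectrum(2.5 * x, 128, 0.5, "hann")
  expect_lt(max(Mod(Ba$values - 2.5^3 * B$values)) / max(Mod(Ba$values)), 1e-9)
})

test_that("segment averaging shrinks the Gaussian-null bispectrum", {
  set.seed(8)
  x <- rnorm(64 * 256)
  mean_mag <- function(n) {
    B <- estimate_bispectrum(x[seq_len(n * 64)], 64, 0, "hann")
    mask <- roadhos:::principal_region_mask(32)
    mean(Mod(B$values)[mask])
  }
  mags <- vapply(c(4, 16, 64, 256), mean_mag, numeric(1))
  expect_true(all(diff(mags) <= 0.05 * mags[-length(mags)]))
})

test_that("features S1-S3 follow their definitions", {
  # |B| = 1 everywhere: all logs vanish
  ones <- forge_bispectrum(matrix(1 + 0i, 9, 9))
  f <- bispectral_features(ones)
  expect_equal(unlist(f), c(S1 = 0, S2 = 0, S3 = 0))

  # diagonal magnitudes (e, e^2) over a two-bin diagonal: S2 = 3, S3 = 5
  V <- matrix(1 + 0i, 3, 3)
  V[1, 1] <- exp(1); V[2, 2] <- exp(2)
  f2 <- bispectral_features(forge_bispectrum(V))
  expect_equal(f2$S2, 3)
  expect_equal(f2$S3, 5)

  # naive loop-based oracle on a random estimate
  set.seed(9)
  B <- estimate_bispectrum(rnorm(2048), 64, 0.5, "hann")
  got <- bispectral_features(B)
  h <- 32
  S1 <- S2 <- S3 <- 0; kidx <- 0
  for (k in 0:h) for (j in 0:h) {
    if (k <= j && j + k <= h) S1 <- S1 + log(max(Mod(B$values[j + 1, k + 1]), 1e-12))
  }
  for (k in 0:(h %/% 2)) {
    kidx <- kidx + 1
    lv <- log(max(Mod(B$values[k + 1, k + 1]), 1e-12))
    S2 <- S2 + lv; S3 <- S3 + kidx * lv
  }
  expect_equal(got$S1, S1, tolerance = 1e-12)
  expect_equal(got$S2, S2, tolerance = 1e-12)
  expect_equal(got$S3, S3, tolerance = 1e-12)
})

test_that("epoch feature extraction is deterministic and carries metadata", {
  set.seed(10)
  sig <- rnorm(2500)
  ep <- make_epoch(sig, rnorm(2500), subject = "S03", state = "hypnosis",
                   start_s = 20)
  r1 <- extract_epoch_features(ep)
  r2 <- extract_epoch_features(ep)
  expect_identical(r1, r2)
  expect_identical(r1$subject_id, "S03")
  expect_identical(r1$state, "hypnosis")
  expect_identical(r1$epoch_start_s, 20)

  short <- make_epoch(rnorm(100), rnorm(100))
  expect_error(extract_epoch_features(short), "seg_len")
})

test_that("phase coupling separates emg_S1 between epoch groups", {
  fs <- 500
  pc <- state_params("normal", qpc_strength = 1)
  p0 <- state_params("normal", qpc_strength = 0)
  s1_of <- function(p, seed) {
    x <- synthesize_emg(p, 5, fs, seed = seed)
    bispectral_features(estimate_bispectrum(x, 256, 0.5, "hann"))$S1
  }
  a <- vapply(1:50, function(s) s1_of(pc, s), numeric(1))
  b <- vapply(1:50, function(s) s1_of(p0, 100 + s), numeric(1))
  expect_gt(abs(stats::t.test(a, b)$statistic), 3)
})
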