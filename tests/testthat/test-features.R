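# Feature extractor: closed-form cases, analytic signals, independent
# oracle agreement on targeted blocks, and the class-separability the
# features are supposed to carry.

test_that("per-pulse morphology matches its definitions on a constructed pulse", {
  # triangle pulse: onset idx 1 value 0, peak idx 16 value 1, offset idx 61
  fs <- 75
  x <- c(seq(0, 1, length.out = 16), seq(1, 0, length.out = 46)[-1],
         rep(0, 300))
  rec <- wrap_recording(x, fs = fs)
  ps <- new_pulse_set(1L, 16L, 61L)
  pp <- per_pulse_features(rec, ps)
  expect_equal(pp$Amplitude, 1.0)
  expect_equal(pp$RiseTime, 15 / fs)   # 0.2 s
  expect_equal(pp$Width, 60 / fs)      # 0.8 s
})

test_that("two identical pulses give zero pairwise differences", {
  fs <- 75
  tpl <- make_pulse_template(0.15, 0.8, 0.1, fs)
  x <- c(tpl, tpl, rep(0, 150))
  rec <- wrap_recording(x, fs = fs)
  n <- length(tpl)
  ps <- new_pulse_set(c(1L, n + 1L), c(12L, n + 12L), c(n, 2L * n))
  pp <- per_pulse_features(rec, ps)
  expect_equal(pp$PeakHeightDiff[1], 0)
  expect_equal(pp$PeakDistance[1], 0.8)
  expect_equal(pp$TroughDiff[1], 0)
})

test_that("value-symmetric pulse has near-zero skewness", {
  fs <- 75
  # triangle pulse: sample values are symmetric about their mean
  x <- c(seq(0, 1, length.out = 31), seq(1, 0, length.out = 31)[-1],
         rep(0, 300))
  rec <- wrap_recording(x, fs = fs)
  pp <- per_pulse_features(rec, new_pulse_set(1L, 31L, 60L))
  expect_lt(abs(pp$Skewness), 1e-6)
})

test_that("window aggregation: periodic train collapses Change/Std to zero", {
  fs <- 75
  tpl <- make_pulse_template(0.15, 0.8, 0.1, fs)
  x <- rep(tpl, 20)
  rec <- wrap_recording(x, fs = fs)
  n <- length(tpl)
  onsets <- seq(1L, 19L * n + 1L, by = n)
  ps <- new_pulse_set(onsets, onsets + 11L, c(onsets[-1], 20L * n))
  pp <- per_pulse_features(rec, ps)
  agg <- aggregate_time_features(pp, rec, 0, 10)
  expect_true(all(abs(agg[9:24]) < 1e-9))
})

test_that("zero-crossing rate of a 1 Hz sinusoid is 2 per second", {
  fs <- 75
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  rec <- wrap_recording(sin(2 * pi * t + 0.1), fs = fs)
  agg <- aggregate_time_features(per_pulse_features(rec, new_pulse_set(
    integer(0), integer(0), integer(0))), rec, 2, 6)
  expect_equal(unname(agg["ZeroCrossingRate"]), 2.0)
})

test_that("alternating pulse amplitudes give the hand-computed Change and Std", {
  tbl <- data.frame(onset = c(1, 101, 201, 301), peak = c(21, 121, 221, 321),
                    offset = c(100, 200, 300, 400),
                    Amplitude = c(1, 2, 1, 2), Width = 1, PeakHeightDiff = NA,
                    PeakDistance = NA, TroughDiff = NA, RiseTime = 0.2,
                    Skewness = 0, Kurtosis = 2)
  rec <- wrap_recording(rnorm(500), fs = 75)
  agg <- aggregate_time_features(tbl, rec, 0, 6)
  expect_equal(unname(agg["ChangeAmplitude"]), 1.0)
  expect_equal(unname(agg["StdAmplitude"]), sd(c(1, 2, 1, 2)))
})

test_that("correlogram locates the period of a sinusoid and its double", {
  fs <- 75
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  rec <- wrap_recording(sin(2 * pi * t / 0.8), fs = fs)
  cf <- correlogram_features(rec, 0, 10)
  expect_lt(abs(cf["CorrelogramLag1"] - 0.8), 1.5 / fs)
  expect_gte(cf["CorrelogramPeak1"], 0.9)
  expect_lt(abs(cf["CorrelogramLag2"] - 1.6), 2.5 / fs)
})

test_that("white-noise correlogram peak is small (Monte-Carlo)", {
  fs <- 75
  vals <- vapply(1:100, function(s) {
    rec <- wrap_recording(with_seed(s, rnorm(10 * fs)), fs = fs)
    correlogram_features(rec, 0, 10)[["CorrelogramPeak1"]]
  }, numeric(1))
  expect_lt(mean(vals, na.rm = TRUE), 0.3)
})

test_that("spectrogram frame geometry and tone localization are exact", {
  fs <- 75
  t <- seq(0, 140 - 1 / fs, by = 1 / fs)
  rec <- wrap_recording(sin(2 * pi * 1 * t), fs = fs)
  spec <- compute_spectrogram(rec)
  expect_length(spec$times, 131)  # floor((140 - 10)/1) + 1
  peak_freq <- spec$freqs[apply(spec$psd_db, 2, which.max)]
  expect_true(all(abs(peak_freq - 1.0) < 1e-9))
  expect_error(compute_spectrogram(wrap_recording(rnorm(500), fs = fs)),
               class = "neckppg_too_short_error")
})

test_that("per-frame PSD integrates to the tapered time-domain power (Parseval)", {
  out <- synth_one("control", seed = 5)
  rec <- out$normalized
  spec <- compute_spectrogram(rec)
  fs <- rec$fs
  frame_len <- round(10 * fs)
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(frame_len - 1)) / (frame_len - 1))
  for (f in c(1, 60, 131)) {
    i0 <- (f - 1) * fs + 1
    seg <- rec$samples[i0:(i0 + frame_len - 1)] * win
    p_time <- mean(seg^2) / mean(win^2)
    p_freq <- sum(10^(spec$psd_db[, f] / 10)) * fs / frame_len
    expect_lt(abs(p_freq - p_time) / p_time, 0.02)
  }
})

test_that("spectral features localize a tone and saturate entropy on noise", {
  fs <- 75
  t <- seq(0, 140 - 1 / fs, by = 1 / fs)
  tone <- wrap_recording(sin(2 * pi * 1 * t), fs = fs)
  sf <- window_psd_features(compute_spectrogram(tone), 30, 10)
  expect_gte(sf["RelativePower_0.8_1.3Hz"], 0.95)
  expect_lte(sf["RelativePower_0_0.8Hz"], 0.05)
  expect_lte(sf["RelativePower_1.3_1.8Hz"], 0.05)
  # tone on a bin centre -> near-zero band entropy
  expect_lt(sf["SpectralEntropy_0_1.5Hz"], 0.35)

  ent <- vapply(1:100, function(s) {
    rec <- wrap_recording(with_seed(s, rnorm(20 * fs)), fs = fs)
    window_psd_features(compute_spectrogram(rec), 4, 10)[["SpectralEntropy_0_1.5Hz"]]
  }, numeric(1))
  expect_gte(mean(ent), 0.9)
})

test_that("relative band powers are a sub-probability over disjoint bands", {
  ft <- small_features_w6()
  s <- ft$RelativePower_0_0.8Hz + ft$RelativePower_0.8_1.3Hz +
    ft$RelativePower_1.3_1.8Hz
  expect_true(all(s[!is.nan(s)] <= 1 + 1e-12))
  expect_true(all(ft$RelativePower_0_0.8Hz[!is.nan(s)] >= 0))
})

test_that("envelope interpolates its knots exactly and tracks modulation", {
  fs <- 75
  out <- synth_one("control", seed = 9)
  rec <- out$normalized
  env <- extract_envelope(rec, 20, 10)
  w <- rec$samples[(20 * fs + 1):(30 * fs)]
  knots <- attr(env, "knots")
  expect_equal(env[knots], w[knots], tolerance = 1e-12)

  # amplitude-modulated train: envelope correlates with the modulation
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  mod <- 1 + 0.3 * sin(2 * pi * 0.25 * t)
  carrier <- abs(sin(2 * pi * 1.25 * t))^3
  rec2 <- wrap_recording(mod * carrier, fs = fs)
  env2 <- extract_envelope(rec2, 0, 30)
  expect_gte(cor(env2, mod), 0.9)

  # constant-amplitude train: flat envelope
  rec3 <- wrap_recording(carrier, fs = fs)
  env3 <- extract_envelope(rec3, 0, 30)
  expect_lte(sd(env3), 0.05 * mean(env3))
})

test_that("approximate entropy behaves per the Pincus definition", {
  expect_identical(approximate_entropy(rep(1, 100)), 0)
  # irregular > regular, seed-averaged
  diffs <- vapply(1:20, function(s) {
    x <- with_seed(s, rnorm(300))
    y <- sin(2 * pi * (1:300) / 25)
    approximate_entropy(x) - approximate_entropy(y)
  }, numeric(1))
  expect_true(all(diffs > 0))
  # production path equals the naive reference
  x <- with_seed(4, cumsum(rnorm(200)))
  expect_equal(approximate_entropy(x), oracle_apen(x), tolerance = 1e-10)
  expect_error(approximate_entropy(1:10, m = 2),
               class = "neckppg_validation_error")
})

test_that("envelope features: closed forms and band localization", {
  fs <- 75
  env <- rep(1, 6 * fs)
  ef <- envelope_features(env, fs)
  expect_equal(unname(ef["EnvelopeStd"]), 0)
  expect_equal(unname(ef["EnvelopeMax"]), 1)
  expect_equal(unname(ef["EnvelopeMin"]), 1)
  expect_equal(unname(ef["EnvelopeRange"]), 0)
  expect_equal(unname(ef["EnvelopeArea"]), (length(env) - 1) / fs,
               tolerance = 1e-12)

  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  ef2 <- envelope_features(1 + 0.3 * sin(2 * pi * 0.25 * t), fs)
  expect_gt(ef2["EnvelopeAvgPower_0.2_0.5Hz"], ef2["EnvelopeAvgPower_0_0.15Hz"])
  expect_gt(ef2["EnvelopeAvgPower_0.2_0.5Hz"], ef2["EnvelopeAvgPower_0.5_1Hz"])

  # F45 identity on random inputs
  for (s in 1:5) {
    e <- with_seed(s, abs(rnorm(300)) + 0.5)
    ef3 <- envelope_features(e, fs)
    expect_identical(unname(ef3["EnvelopeRange"]),
                     unname(ef3["EnvelopeMax"] - ef3["EnvelopeMin"]))
  }
})

test_that("full vector has 51 named entries, 10 of them envelope, and is deterministic", {
  out <- synth_one("control", seed = 13)
  rec <- out$normalized
  pulses <- detect_pulses(rec)
  spec <- compute_spectrogram(rec)
  fv1 <- extract_feature_vector(rec, pulses, 20, 6, spec)
  fv2 <- extract_feature_vector(rec, pulses, 20, 6, spec)
  expect_length(fv1, 51)
  expect_identical(names(fv1), ppg_feature_names())
  expect_identical(sum(startsWith(names(fv1), "Envelope")), 10L)
  expect_identical(fv1, fv2)
})

test_that("envelope variability separates apnea from normal; amplitude instability separates artifacts", {
  ft <- small_features_w6()
  apnea <- ft[ft$apnea_fraction >= 1 - 1e-9, "EnvelopeStd"]
  normal <- ft[ft$scenario == "breath_hold" & ft$apnea_fraction == 0,
               "EnvelopeStd"]
  n <- min(100, length(apnea), length(normal))
  p1 <- wilcox.test(apnea[seq_len(n)], normal[seq_len(n)])$p.value
  expect_lt(p1, 0.01)

  art <- ft[ft$artifact_fraction >= 1 - 1e-9, "StdAmplitude"]
  clean <- ft[ft$artifact_fraction == 0 & ft$scenario == "control",
              "StdAmplitude"]
  art <- art[!is.nan(art)]; clean <- clean[!is.nan(clean)]
  n <- min(100, length(art), length(clean))
  p2 <- wilcox.test(art[seq_len(n)], clean[seq_len(n)])$p.value
  expect_lt(p2, 0.01)
})
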