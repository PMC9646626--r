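# The 51-feature catalogue: time-domain pulse morphology (F1-F25),
# correlogram (F26-F29), spectral (F30-F41) and upper-envelope (F42-F51)
# descriptors of a PPG analysis window.

#' Canonical names of the 51 window features
#'
#' Ordered F1..F51; these names key every feature vector and feature table in
#' the package.
#'
#' @return character vector of length 51.
#' @export
ppg_feature_names <- function() {
  c("Amplitude", "Width", "PeakHeightDiff", "PeakDistance", "TroughDiff",
    "RiseTime", "Skewness", "Kurtosis",
    "ChangeAmplitude", "ChangeWidth", "ChangePeakHeightDiff",
    "ChangePeakDistance", "ChangeTroughDiff", "ChangeRiseTime",
    "ChangeSkewness", "ChangeKurtosis",
    "StdAmplitude", "StdWidth", "StdPeakHeightDiff", "StdPeakDistance",
    "StdTroughDiff", "StdRiseTime", "StdSkewness", "StdKurtosis",
    "ZeroCrossingRate",
    "CorrelogramPeak1", "CorrelogramPeak2", "CorrelogramLag1",
    "CorrelogramLag2",
    "SpectralEntropy_0_1.5Hz", "SpectralEntropy_1_4Hz",
    "SpectralKurtosis_0_1.5Hz", "SpectralKurtosis_1_4Hz",
    "RelativePower_0_0.8Hz", "RelativePower_0.8_1.3Hz",
    "RelativePower_1.3_1.8Hz",
    "AvgPower_0_0.8Hz", "AvgPower_0.8_1.3Hz", "AvgPower_1.3_1.8Hz",
    "AvgPower_2.2_2.8Hz", "AvgPower_3.2_3.8Hz",
    "EnvelopeStd", "EnvelopeMax", "EnvelopeMin", "EnvelopeRange",
    "EnvelopeApproxEntropy", "EnvelopeArea",
    "EnvelopeAvgPower_0_0.15Hz", "EnvelopeAvgPower_0.2_0.5Hz",
    "EnvelopeAvgPower_0_0.5Hz", "EnvelopeAvgPower_0.5_1Hz")
}

# population moments; MATLAB-style skewness m3/m2^1.5 and kurtosis m4/m2^2
moment_skewness <- function(x) {
  m <- mean(x); m2 <- mean((x - m)^2)
  if (m2 == 0) return(NaN)
  mean((x - m)^3) / m2^1.5
}
moment_kurtosis <- function(x) {
  m <- mean(x); m2 <- mean((x - m)^2)
  if (m2 == 0) return(NaN)
  mean((x - m)^4) / m2^2
}

#' Per-pulse morphological features (F1-F8 and pairwise F3-F5)
#'
#' One row per detected pulse. `Amplitude` is the vertical onset-to-peak
#' distance, `Width` the onset-to-offset duration, `RiseTime` the
#' onset-to-peak duration, `Skewness`/`Kurtosis` the shape moments of the
#' pulse segment. Pairwise features (`PeakHeightDiff`, `PeakDistance`,
#' `TroughDiff`) compare pulse i with pulse i+1 and are stored on row i
#' (last row `NA`).
#'
#' @param rec a `ppg_recording`.
#' @param pulses a `ppg_pulse_set` for `rec`.
#' @return data.frame with columns `onset`, `peak`, `offset`, `Amplitude`,
#'   `Width`, `PeakHeightDiff`, `PeakDistance`, `TroughDiff`, `RiseTime`,
#'   `Skewness`, `Kurtosis`.
#' @export
per_pulse_features <- function(rec, pulses) {
  x <- rec$samples
  fs <- rec$fs
  np <- length(pulses$peaks)
  if (np == 0) {
    out <- data.frame(onset = integer(0), peak = integer(0), offset = integer(0))
    for (nm in c("Amplitude", "Width", "PeakHeightDiff", "PeakDistance",
                 "TroughDiff", "RiseTime", "Skewness", "Kurtosis")) {
      out[[nm]] <- numeric(0)
    }
    return(out)
  }
  on <- pulses$onsets; pk <- pulses$peaks; off <- pulses$offsets
  skew <- numeric(np); kurt <- numeric(np)
  for (i in seq_len(np)) {
    seg <- x[on[i]:off[i]]
    skew[i] <- moment_skewness(seg)
    kurt[i] <- moment_kurtosis(seg)
  }
  data.frame(
    onset = on, peak = pk, offset = off,
    Amplitude = x[pk] - x[on],
    Width = (off - on) / fs,
    PeakHeightDiff = c(diff(x[pk]), NA_real_),
    PeakDistance = c(diff(pk) / fs, NA_real_),
    TroughDiff = c(diff(x[on]), NA_real_),
    RiseTime = (pk - on) / fs,
    Skewness = skew, Kurtosis = kurt
  )
}

# windowed raw samples; window start in seconds, half-open [start, start+W)
window_samples <- function(rec, start, W) {
  i0 <- round(start * rec$fs) + 1L
  i1 <- i0 + round(W * rec$fs) - 1L
  rec$samples[i0:min(i1, length(rec$samples))]
}

#' Window-averaged time-domain features (F1-F25)
#'
#' Restricts the per-pulse table to pulses whose systolic peaks lie in the
#' half-open window, then reports the mean of each per-pulse series (F1-F8),
#' the mean absolute consecutive difference (`Change*`, F9-F16), the sample
#' standard deviation over the window (`Std*`, F17-F24), and the
#' zero-crossing rate of the windowed signal per second (F25). Windows with
#' fewer than two in-window pulses yield `NaN` for all pulse-based features.
#'
#' @param pp per-pulse table from [per_pulse_features()].
#' @param rec the `ppg_recording`.
#' @param start window start, seconds.
#' @param W window length, seconds.
#' @return named numeric vector of the 25 time-domain features.
#' @export
aggregate_time_features <- function(pp, rec, start, W) {
  fs <- rec$fs
  nms <- ppg_feature_names()[1:25]
  out <- rep(NaN, 25)
  names(out) <- nms
  peak_t <- (pp$peak - 1) / fs
  inw <- pp[peak_t >= start & peak_t < start + W, , drop = FALSE]
  base <- c("Amplitude", "Width", "PeakHeightDiff", "PeakDistance",
            "TroughDiff", "RiseTime", "Skewness", "Kurtosis")
  if (nrow(inw) >= 2) {
    # pairwise features re-anchored so both pulses of a pair lie in-window
    x <- rec$samples
    series <- list(
      Amplitude = inw$Amplitude,
      Width = inw$Width,
      PeakHeightDiff = diff(x[inw$peak]),
      PeakDistance = diff(inw$peak) / fs,
      TroughDiff = diff(x[inw$onset]),
      RiseTime = inw$RiseTime,
      Skewness = inw$Skewness,
      Kurtosis = inw$Kurtosis
    )
    for (k in seq_along(base)) {
      v <- series[[base[k]]]
      v <- v[!is.na(v)]
      out[k] <- if (length(v)) mean(v) else NaN
      out[8 + k] <- if (length(v) >= 2) mean(abs(diff(v))) else NaN
      out[16 + k] <- if (length(v) >= 2) sd(v) else NaN
    }
  }
  w <- window_samples(rec, start, W)
  out["ZeroCrossingRate"] <- sum(w[-1] * w[-length(w)] < 0) / W
  out
}

#' Correlogram features (F26-F29)
#'
#' Biased normalized autocorrelation of the mean-removed windowed signal for
#' lags up to `min(4 s, W/2)`. F26/F28 are the value and lag (seconds) of the
#' first local maximum at lag >= 0.25 s, F27/F29 those of the second; missing
#' peaks give `NaN`.
#'
#' @inheritParams aggregate_time_features
#' @return named numeric vector of length 4.
#' @export
correlogram_features <- function(rec, start, W) {
  fs <- rec$fs
  w <- window_samples(rec, start, W)
  w <- w - mean(w)
  max_lag <- round(min(4, W / 2) * fs)
  r <- as.numeric(stats::acf(w, lag.max = max_lag, type = "correlation",
                             plot = FALSE, demean = FALSE)$acf)
  lags <- 0:max_lag
  pk <- local_maxima(r)
  pk <- pk[lags[pk] >= 0.25 * fs]
  out <- c(CorrelogramPeak1 = NaN, CorrelogramPeak2 = NaN,
           CorrelogramLag1 = NaN, CorrelogramLag2 = NaN)
  if (length(pk) >= 1) {
    out["CorrelogramPeak1"] <- r[pk[1]]
    out["CorrelogramLag1"] <- lags[pk[1]] / fs
  }
  if (length(pk) >= 2) {
    out["CorrelogramPeak2"] <- r[pk[2]]
    out["CorrelogramLag2"] <- lags[pk[2]] / fs
  }
  out
}

#' Short-time spectrogram of a recording
#'
#' Hamming-tapered one-sided modified periodogram per 10 s frame, hop 1 s
#' (90% overlap), density scaling, stored in dB/Hz with a floor at -120 dB.
#' The real part of the windowed STFT is retained for the spectral-kurtosis
#' features.
#'
#' @param rec a `ppg_recording` of at least 10 s.
#' @return object of class `ppg_spectrogram` with `freqs` (Hz), `times`
#'   (frame centers, s), `psd_db` (freq x time), `stft_re` (freq x time) and
#'   `fs`.
#' @export
compute_spectrogram <- function(rec) {
  fs <- rec$fs
  x <- rec$samples
  frame_len <- round(10 * fs)
  hop <- round(1 * fs)
  if (length(x) < frame_len) {
    stop_neckppg("recording shorter than the 10 s spectrogram frame",
                 class = "neckppg_too_short_error")
  }
  n_frames <- floor((length(x) - frame_len) / hop) + 1
  win <- signal::hamming(frame_len)
  u <- sum(win^2)
  nbins <- frame_len %/% 2 + 1
  psd <- matrix(0, nbins, n_frames)
  stft_re <- matrix(0, nbins, n_frames)
  for (f in seq_len(n_frames)) {
    i0 <- (f - 1) * hop + 1
    seg <- x[i0:(i0 + frame_len - 1)] * win
    X <- fft(seg)[1:nbins]
    p <- Mod(X)^2 / (fs * u)
    if (frame_len %% 2 == 0) {
      p[2:(nbins - 1)] <- 2 * p[2:(nbins - 1)]
    } else {
      p[2:nbins] <- 2 * p[2:nbins]
    }
    psd[, f] <- p
    stft_re[, f] <- Re(X)
  }
  psd_db <- pmax(10 * log10(pmax(psd, 1e-12)), -120)
  structure(list(
    freqs = (0:(nbins - 1)) * fs / frame_len,
    times = (seq_len(n_frames) - 1) * hop / fs + frame_len / (2 * fs),
    psd_db = psd_db, stft_re = stft_re, fs = fs
  ), class = "ppg_spectrogram")
}

band_bins <- function(freqs, lo, hi) which(freqs >= lo & freqs < hi)

#' Spectral window features (F30-F41)
#'
#' The window PSD is the mean (in the linear power domain) of the spectrogram
#' frames whose centers fall inside the window. F30/F31 are normalized
#' Shannon entropies of the band-restricted power distribution; F32/F33 the
#' band-averaged spectral kurtosis of the real STFT part over the in-window
#' frames (falling back to all frames overlapping the window when fewer than
#' four centers are inside); F34-F36 band-relative powers; F37-F41 mean band
#' powers.
#'
#' @param spec a `ppg_spectrogram`.
#' @inheritParams aggregate_time_features
#' @return named numeric vector of length 12.
#' @export
window_psd_features <- function(spec, start, W) {
  nms <- ppg_feature_names()[30:41]
  out <- rep(NaN, 12)
  names(out) <- nms
  centers <- spec$times
  inw <- which(centers >= start & centers < start + W)
  if (!length(inw)) {
    warning("no spectrogram frame center inside window [", start, ",",
            start + W, "); spectral features are NaN")
    return(out)
  }
  P <- 10^(spec$psd_db[, inw, drop = FALSE] / 10)
  P <- rowMeans(P)
  f <- spec$freqs

  spectral_entropy <- function(lo, hi) {
    b <- band_bins(f, lo, hi)
    if (length(b) < 2) return(0)
    p <- P[b] / sum(P[b])
    p <- p[p > 0]
    -sum(p * log(p)) / log(length(b))
  }
  out["SpectralEntropy_0_1.5Hz"] <- spectral_entropy(0, 1.5)
  out["SpectralEntropy_1_4Hz"] <- spectral_entropy(1, 4)

  kf <- inw
  if (length(kf) < 4) {
    kf <- which(centers + 5 > start & centers - 5 < start + W)
  }
  spectral_kurtosis <- function(lo, hi) {
    b <- band_bins(f, lo, hi)
    re <- spec$stft_re[b, kf, drop = FALSE]
    m2 <- rowMeans(re^2)
    m4 <- rowMeans(re^4)
    sk <- ifelse(m2 > 0, m4 / m2^2, NaN)
    mean(sk, na.rm = TRUE)
  }
  out["SpectralKurtosis_0_1.5Hz"] <- spectral_kurtosis(0, 1.5)
  out["SpectralKurtosis_1_4Hz"] <- spectral_kurtosis(1, 4)

  total <- sum(P)
  rel <- function(lo, hi) sum(P[band_bins(f, lo, hi)]) / total
  avg <- function(lo, hi) mean(P[band_bins(f, lo, hi)])
  out["RelativePower_0_0.8Hz"] <- rel(0, 0.8)
  out["RelativePower_0.8_1.3Hz"] <- rel(0.8, 1.3)
  out["RelativePower_1.3_1.8Hz"] <- rel(1.3, 1.8)
  out["AvgPower_0_0.8Hz"] <- avg(0, 0.8)
  out["AvgPower_0.8_1.3Hz"] <- avg(0.8, 1.3)
  out["AvgPower_1.3_1.8Hz"] <- avg(1.3, 1.8)
  out["AvgPower_2.2_2.8Hz"] <- avg(2.2, 2.8)
  out["AvgPower_3.2_3.8Hz"] <- avg(3.2, 3.8)
  out
}

#' Upper envelope of a window
#'
#' Cubic-spline interpolation through local maxima separated by at least 50
#' samples, evaluated at every window sample, with constant extrapolation
#' beyond the first/last knot. With fewer than two maxima the envelope is
#' constant at the available maximum (flagged via attribute `degenerate`).
#'
#' @inheritParams aggregate_time_features
#' @return numeric vector (one value per window sample) with attribute
#'   `knots` (sample indices within the window).
#' @export
extract_envelope <- function(rec, start, W) {
  w <- window_samples(rec, start, W)
  n <- length(w)
  mx <- local_maxima(w)
  mx <- enforce_min_separation(mx, w[mx], 50L)
  if (length(mx) < 2) {
    env <- rep(if (length(mx)) w[mx] else max(w), n)
    attr(env, "knots") <- mx
    attr(env, "degenerate") <- TRUE
    return(env)
  }
  sf <- splinefun(mx, w[mx], method = "fmm")
  env <- numeric(n)
  i <- seq_len(n)
  inside <- i >= mx[1] & i <= mx[length(mx)]
  env[inside] <- sf(i[inside])
  env[i < mx[1]] <- w[mx[1]]
  env[i > mx[length(mx)]] <- w[mx[length(mx)]]
  attr(env, "knots") <- mx
  attr(env, "degenerate") <- FALSE
  env
}

#' Approximate entropy
#'
#' ApEn(m, r) = Phi_m(r) - Phi_(m+1)(r) with Phi_m the mean log of
#' Chebyshev-distance neighbour fractions, self-matches included (the
#' standard Pincus convention). Defaults m = 2, r = 0.2 * sd(x); a constant
#' input (r = 0) returns 0 by convention.
#'
#' @param x numeric sequence.
#' @param m embedding dimension.
#' @param r tolerance radius.
#' @return ApEn value (scalar).
#' @export
approximate_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  x <- as.numeric(x)
  if (!is.finite(r) || r <= 0) return(0)
  if (length(x) < 10 * m) {
    stop_neckppg("approximate_entropy needs length(x) >= 10*m",
                 class = "neckppg_validation_error")
  }
  apen_cpp(x, as.integer(m), r)
}

#' Envelope features (F42-F51)
#'
#' Standard deviation, extrema, range, approximate entropy, trapezoidal area
#' of the absolute envelope, and mean one-sided periodogram power of the
#' mean-removed envelope in four sub-hertz bands.
#'
#' @param env envelope from [extract_envelope()].
#' @param fs sampling rate, Hz.
#' @return named numeric vector of length 10.
#' @export
envelope_features <- function(env, fs) {
  n <- length(env)
  out <- numeric(10)
  names(out) <- ppg_feature_names()[42:51]
  out["EnvelopeStd"] <- sd(env)
  out["EnvelopeMax"] <- max(env)
  out["EnvelopeMin"] <- min(env)
  out["EnvelopeRange"] <- out["EnvelopeMax"] - out["EnvelopeMin"]
  out["EnvelopeApproxEntropy"] <- approximate_entropy(env)
  a <- abs(env)
  out["EnvelopeArea"] <- sum((a[-1] + a[-n]) / 2) / fs
  e <- env - mean(env)
  X <- fft(e)
  nbins <- n %/% 2 + 1
  p <- Mod(X[1:nbins])^2 / (fs * n)
  if (n %% 2 == 0) {
    p[2:(nbins - 1)] <- 2 * p[2:(nbins - 1)]
  } else if (nbins > 1) {
    p[2:nbins] <- 2 * p[2:nbins]
  }
  f <- (0:(nbins - 1)) * fs / n
  avg <- function(lo, hi) {
    b <- band_bins(f, lo, hi)
    if (!length(b)) return(0)
    mean(p[b])
  }
  out["EnvelopeAvgPower_0_0.15Hz"] <- avg(0, 0.15)
  out["EnvelopeAvgPower_0.2_0.5Hz"] <- avg(0.2, 0.5)
  out["EnvelopeAvgPower_0_0.5Hz"] <- avg(0, 0.5)
  out["EnvelopeAvgPower_0.5_1Hz"] <- avg(0.5, 1)
  out
}

#' Assemble the full 51-feature vector for one window
#'
#' Delegates to [aggregate_time_features()], [correlogram_features()],
#' [window_psd_features()] and [envelope_features()]; values that cannot be
#' computed (too few pulses, no in-window spectrogram frame) are `NaN`.
#'
#' @param rec a normalized `ppg_recording`.
#' @param pulses `ppg_pulse_set` for `rec` (from [detect_pulses()]).
#' @param start window start, seconds.
#' @param W window length, seconds.
#' @param spec spectrogram from [compute_spectrogram()].
#' @param pp optional precomputed [per_pulse_features()] table.
#' @return named numeric vector of length 51.
#' @export
extract_feature_vector <- function(rec, pulses, start, W, spec,
                                   pp = per_pulse_features(rec, pulses)) {
  env <- extract_envelope(rec, start, W)
  out <- c(
    aggregate_time_features(pp, rec, start, W),
    correlogram_features(rec, start, W),
    window_psd_features(spec, start, W),
    envelope_features(env, rec$fs)
  )
  stopifnot(identical(names(out), ppg_feature_names()))
  out
}
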