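# Independent naive re-implementations of the 51 window features, written
# from the feature definitions with explicit loops. These back the oracle-
# equivalence tests and deliberately share no code with the package paths
# (library primitives fft/splinefun excepted).

oracle_skew <- function(v) {
  mu <- sum(v) / length(v)
  m2 <- sum((v - mu)^2) / length(v)
  if (m2 == 0) return(NaN)
  (sum((v - mu)^3) / length(v)) / m2^1.5
}
oracle_kurt <- function(v) {
  mu <- sum(v) / length(v)
  m2 <- sum((v - mu)^2) / length(v)
  if (m2 == 0) return(NaN)
  (sum((v - mu)^4) / length(v)) / m2^2
}
oracle_sd <- function(v) sqrt(sum((v - mean(v))^2) / (length(v) - 1))

# F1-F25 from raw pulse indices
oracle_time_features <- function(x, fs, pulses, start, W) {
  out <- rep(NaN, 25)
  names(out) <- ppg_feature_names()[1:25]
  keep <- which((pulses$peaks - 1) / fs >= start &
                  (pulses$peaks - 1) / fs < start + W)
  if (length(keep) >= 2) {
    on <- pulses$onsets[keep]; pk <- pulses$peaks[keep]
    off <- pulses$offsets[keep]
    series <- list(
      Amplitude = x[pk] - x[on],
      Width = (off - on) / fs,
      PeakHeightDiff = if (length(keep) >= 2) x[pk[-1]] - x[pk[-length(pk)]] else numeric(0),
      PeakDistance = if (length(keep) >= 2) (pk[-1] - pk[-length(pk)]) / fs else numeric(0),
      TroughDiff = if (length(keep) >= 2) x[on[-1]] - x[on[-length(on)]] else numeric(0),
      RiseTime = (pk - on) / fs,
      Skewness = vapply(seq_along(keep), function(i) oracle_skew(x[on[i]:off[i]]), numeric(1)),
      Kurtosis = vapply(seq_along(keep), function(i) oracle_kurt(x[on[i]:off[i]]), numeric(1))
    )
    for (k in seq_along(series)) {
      v <- series[[k]]
      out[k] <- if (length(v)) mean(v) else NaN
      d <- if (length(v) >= 2) abs(v[-1] - v[-length(v)]) else numeric(0)
      out[8 + k] <- if (length(d)) mean(d) else NaN
      out[16 + k] <- if (length(v) >= 2) oracle_sd(v) else NaN
    }
  }
  w <- x[(round(start * fs) + 1):(round(start * fs) + round(W * fs))]
  cross <- 0
  for (i in seq_len(length(w) - 1)) {
    if (w[i] * w[i + 1] < 0) cross <- cross + 1
  }
  out["ZeroCrossingRate"] <- cross / W
  out
}

oracle_correlogram <- function(x, fs, start, W) {
  w <- x[(round(start * fs) + 1):(round(start * fs) + round(W * fs))]
  w <- w - mean(w)
  n <- length(w)
  max_lag <- round(min(4, W / 2) * fs)
  r <- numeric(max_lag + 1)
  denom <- sum(w^2)
  for (k in 0:max_lag) {
    r[k + 1] <- sum(w[seq_len(n - k)] * w[(k + 1):n]) / denom
  }
  peaks <- integer(0)
  for (i in 2:max_lag) {
    if (r[i] > r[i - 1] && r[i] > r[i + 1]) peaks <- c(peaks, i)
  }
  lags <- (peaks - 1) / fs
  peaks <- peaks[lags >= 0.25]
  out <- c(CorrelogramPeak1 = NaN, CorrelogramPeak2 = NaN,
           CorrelogramLag1 = NaN, CorrelogramLag2 = NaN)
  if (length(peaks) >= 1) {
    out[1] <- r[peaks[1]]; out[3] <- (peaks[1] - 1) / fs
  }
  if (length(peaks) >= 2) {
    out[2] <- r[peaks[2]]; out[4] <- (peaks[2] - 1) / fs
  }
  out
}

# window PSD features recomputed from the raw samples (frames, Hamming
# taper, dB floor and band rules restated independently)
oracle_psd_features <- function(x, fs, start, W) {
  out <- rep(NaN, 12)
  names(out) <- ppg_feature_names()[30:41]
  frame_len <- round(10 * fs); hop <- round(fs)
  n_frames <- floor((length(x) - frame_len) / hop) + 1
  centers <- ((seq_len(n_frames) - 1) * hop + frame_len / 2) / fs
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(frame_len - 1)) / (frame_len - 1))
  nbins <- frame_len %/% 2 + 1
  freqs <- (0:(nbins - 1)) * fs / frame_len
  frame_psd <- function(fidx) {
    i0 <- (fidx - 1) * hop + 1
    X <- fft(x[i0:(i0 + frame_len - 1)] * ham)[1:nbins]
    p <- (Mod(X)^2) / (fs * sum(ham^2))
    p[2:(nbins - 1)] <- 2 * p[2:(nbins - 1)]
    db <- 10 * log10(pmax(p, 1e-12))
    db[db < -120] <- -120
    10^(db / 10)
  }
  inw <- which(centers >= start & centers < start + W)
  if (!length(inw)) return(out)
  P <- rowMeans(vapply(inw, frame_psd, numeric(nbins)))

  ent <- function(lo, hi) {
    b <- which(freqs >= lo & freqs < hi)
    p <- P[b] / sum(P[b])
    h <- 0
    for (q in p) if (q > 0) h <- h - q * log(q)
    h / log(length(b))
  }
  out["SpectralEntropy_0_1.5Hz"] <- ent(0, 1.5)
  out["SpectralEntropy_1_4Hz"] <- ent(1, 4)

  kf <- inw
  if (length(kf) < 4) kf <- which(centers + 5 > start & centers - 5 < start + W)
  re_frame <- function(fidx) {
    i0 <- (fidx - 1) * hop + 1
    Re(fft(x[i0:(i0 + frame_len - 1)] * ham)[1:nbins])
  }
  RE <- vapply(kf, re_frame, numeric(nbins))
  sk_band <- function(lo, hi) {
    b <- which(freqs >= lo & freqs < hi)
    vals <- numeric(0)
    for (bin in b) {
      m2 <- mean(RE[bin, ]^2); m4 <- mean(RE[bin, ]^4)
      if (m2 > 0) vals <- c(vals, m4 / m2^2)
    }
    mean(vals)
  }
  out["SpectralKurtosis_0_1.5Hz"] <- sk_band(0, 1.5)
  out["SpectralKurtosis_1_4Hz"] <- sk_band(1, 4)

  bandsum <- function(lo, hi) sum(P[freqs >= lo & freqs < hi])
  bandmean <- function(lo, hi) mean(P[freqs >= lo & freqs < hi])
  out["RelativePower_0_0.8Hz"] <- bandsum(0, 0.8) / sum(P)
  out["RelativePower_0.8_1.3Hz"] <- bandsum(0.8, 1.3) / sum(P)
  out["RelativePower_1.3_1.8Hz"] <- bandsum(1.3, 1.8) / sum(P)
  out["AvgPower_0_0.8Hz"] <- bandmean(0, 0.8)
  out["AvgPower_0.8_1.3Hz"] <- bandmean(0.8, 1.3)
  out["AvgPower_1.3_1.8Hz"] <- bandmean(1.3, 1.8)
  out["AvgPower_2.2_2.8Hz"] <- bandmean(2.2, 2.8)
  out["AvgPower_3.2_3.8Hz"] <- bandmean(3.2, 3.8)
  out
}

# envelope by explicit local-maximum scan + greedy separation, spline fill
oracle_envelope <- function(x, fs, start, W) {
  w <- x[(round(start * fs) + 1):(round(start * fs) + round(W * fs))]
  n <- length(w)
  mx <- integer(0)
  for (i in 2:(n - 1)) {
    if (w[i] > w[i - 1] && w[i] > w[i + 1]) mx <- c(mx, i)
  }
  ord <- order(-w[mx], mx)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(mx[i] - kept) >= 50)) kept <- c(kept, mx[i])
  }
  kept <- sort(kept)
  if (length(kept) < 2) {
    return(rep(if (length(kept)) w[kept] else max(w), n))
  }
  sf <- splinefun(kept, w[kept], method = "fmm")
  env <- numeric(n)
  for (i in seq_len(n)) {
    env[i] <- if (i < kept[1]) {
      w[kept[1]]
    } else if (i > kept[length(kept)]) {
      w[kept[length(kept)]]
    } else {
      sf(i)
    }
  }
  env
}

# vectorized-over-j naive ApEn (Pincus convention, self-matches included)
oracle_apen <- function(x, m = 2, r = 0.2 * oracle_sd(x)) {
  if (!is.finite(r) || r <= 0) return(0)
  phi <- function(mm) {
    N <- length(x) - mm + 1
    emb <- sapply(seq_len(mm), function(k) x[k:(k + N - 1)])
    cnt <- numeric(N)
    for (i in seq_len(N)) {
      d <- abs(emb - matrix(emb[i, ], N, mm, byrow = TRUE))
      cnt[i] <- sum(apply(d, 1, max) <= r)
    }
    mean(log(cnt / N))
  }
  phi(m) - phi(m + 1)
}

oracle_envelope_features <- function(env, fs) {
  n <- length(env)
  out <- numeric(10)
  names(out) <- ppg_feature_names()[42:51]
  out["EnvelopeStd"] <- oracle_sd(env)
  out["EnvelopeMax"] <- max(env)
  out["EnvelopeMin"] <- min(env)
  out["EnvelopeRange"] <- max(env) - min(env)
  out["EnvelopeApproxEntropy"] <- oracle_apen(env)
  area <- 0
  for (i in seq_len(n - 1)) area <- area + (abs(env[i]) + abs(env[i + 1])) / 2
  out["EnvelopeArea"] <- area / fs
  e <- env - mean(env)
  nbins <- n %/% 2 + 1
  X <- fft(e)[1:nbins]
  p <- Mod(X)^2 / (fs * n)
  if (n %% 2 == 0) p[2:(nbins - 1)] <- 2 * p[2:(nbins - 1)] else p[2:nbins] <- 2 * p[2:nbins]
  freqs <- (0:(nbins - 1)) * fs / n
  bm <- function(lo, hi) {
    b <- which(freqs >= lo & freqs < hi)
    if (!length(b)) return(0)
    mean(p[b])
  }
  out["EnvelopeAvgPower_0_0.15Hz"] <- bm(0, 0.15)
  out["EnvelopeAvgPower_0.2_0.5Hz"] <- bm(0.2, 0.5)
  out["EnvelopeAvgPower_0_0.5Hz"] <- bm(0, 0.5)
  out["EnvelopeAvgPower_0.5_1Hz"] <- bm(0.5, 1)
  out
}

oracle_feature_vector <- function(rec, pulses, start, W) {
  x <- rec$samples; fs <- rec$fs
  env <- oracle_envelope(x, fs, start, W)
  c(oracle_time_features(x, fs, pulses, start, W),
    oracle_correlogram(x, fs, start, W),
    oracle_psd_features(x, fs, start, W),
    oracle_envelope_features(env, fs))
}

# brute-force corruption fraction by sample-level counting
oracle_corrupt_fraction <- function(start, W, segs, fs) {
  ts <- start + (seq_len(round(W * fs)) - 0.5) / fs
  if (nrow(segs) == 0) return(0)
  inside <- rep(FALSE, length(ts))
  for (k in seq_len(nrow(segs))) {
    inside <- inside | (ts >= segs$onset[k] & ts < segs$offset[k])
  }
  sum(inside) / length(ts)
}

expect_feature_equal <- function(a, b, tol) {
  both_nan <- is.nan(a) & is.nan(b)
  expect_equal(a[!both_nan], b[!both_nan], tolerance = tol)
}
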