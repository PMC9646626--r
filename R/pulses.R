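# Pulse segmentation: onsets, systolic peaks and offsets anchoring the
# time-domain morphological features.

#' Construct a pulse set
#'
#' Sample indices (1-based, referring to the raw recording) of pulse onsets,
#' systolic peaks and offsets. The offset of pulse i coincides with (or
#' precedes) the onset of pulse i+1.
#'
#' @param onsets,peaks,offsets integer vectors of equal length.
#' @return an object of class `ppg_pulse_set`.
#' @export
new_pulse_set <- function(onsets, peaks, offsets) {
  stopifnot(length(onsets) == length(peaks), length(peaks) == length(offsets))
  if (length(onsets)) {
    ok <- onsets < peaks & peaks <= offsets
    if (!all(ok)) {
      stop_neckppg("pulse %d violates onset < peak <= offset", which(!ok)[1],
                   class = "neckppg_validation_error")
    }
    if (any(diff(onsets) <= 0) || any(diff(peaks) <= 0) ||
        any(diff(offsets) <= 0)) {
      stop_neckppg("pulse indices must be strictly increasing",
                   class = "neckppg_validation_error")
    }
    if (length(onsets) > 1 && any(offsets[-length(offsets)] > onsets[-1])) {
      stop_neckppg("pulse offsets must not pass the next onset",
                   class = "neckppg_validation_error")
    }
  }
  structure(list(onsets = as.integer(onsets), peaks = as.integer(peaks),
                 offsets = as.integer(offsets)),
            class = "ppg_pulse_set")
}

#' @export
print.ppg_pulse_set <- function(x, ...) {
  cat(sprintf("<ppg_pulse_set: %d pulses>\n", length(x$peaks)))
  invisible(x)
}

#' Detect pulses in a normalized recording
#'
#' Systolic peaks are prominence-gated local maxima of a zero-phase 0.5-8 Hz
#' band-passed copy of the signal with an enforced minimum separation of
#' `60 / max_rate` seconds; each onset is the minimum of the raw signal
#' between the previous peak (or the recording start) and the current peak;
#' the offset of each pulse is the next pulse's onset, and the last offset is
#' the last local minimum after the last peak (the final pulse is dropped if
#' none exists). All indices refer to the raw signal.
#'
#' @param rec a normalized `ppg_recording`.
#' @param min_rate,max_rate admissible heart-rate range in bpm.
#' @return a `ppg_pulse_set` (possibly empty when no peaks survive gating).
#' @export
detect_pulses <- function(rec, min_rate = 40, max_rate = 180) {
  stopifnot(inherits(rec, "ppg_recording"))
  if (!rec$normalized) {
    stop_neckppg("detect_pulses requires a normalized recording",
                 class = "neckppg_precondition_error")
  }
  fs <- rec$fs
  x <- rec$samples
  if (length(x) < 2 * (60 / min_rate) * fs) {
    stop_neckppg("recording shorter than two beats at %g bpm", min_rate,
                 class = "neckppg_too_short_error")
  }
  bf <- signal::butter(2, c(0.5, 8) / (fs / 2), type = "pass")
  filt <- as.numeric(signal::filtfilt(bf, x))

  cand <- local_maxima(filt)
  if (!length(cand)) return(new_pulse_set(integer(0), integer(0), integer(0)))
  prom <- peak_prominence(filt, cand)
  # adaptive gate: robust scale of the band-passed signal; clean pulsatile
  # segments dominate the MAD even when bursts corrupt part of the recording
  thr <- 1.0 * stats::mad(filt)
  keep <- cand[prom >= thr]
  if (!length(keep)) return(new_pulse_set(integer(0), integer(0), integer(0)))
  min_sep <- round(60 / max_rate * fs)
  peaks <- enforce_min_separation(keep, filt[keep], min_sep)

  # onsets: raw-signal minima between consecutive peaks
  onsets <- integer(length(peaks))
  prev <- 1L
  for (i in seq_along(peaks)) {
    lo <- prev
    hi <- peaks[i] - 1L
    if (hi < lo) { onsets[i] <- NA_integer_ } else {
      onsets[i] <- lo + which.min(x[lo:hi]) - 1L
    }
    prev <- peaks[i] + 1L
  }
  ok <- !is.na(onsets) & onsets < peaks
  peaks <- peaks[ok]; onsets <- onsets[ok]
  if (!length(peaks)) return(new_pulse_set(integer(0), integer(0), integer(0)))

  offsets <- c(onsets[-1], NA_integer_)
  last_peak <- peaks[length(peaks)]
  if (last_peak < length(x) - 1) {
    tail_min <- local_minima_after(x, last_peak)
    if (!is.na(tail_min)) offsets[length(offsets)] <- tail_min
  }
  ok <- !is.na(offsets) & offsets >= peaks
  new_pulse_set(onsets[ok], peaks[ok], offsets[ok])
}

# last local minimum of x after index p (NA if none)
local_minima_after <- function(x, p) {
  seg <- x[(p + 1L):length(x)]
  mins <- local_maxima(-seg)
  if (!length(mins)) return(NA_integer_)
  p + mins[length(mins)]
}

#' Write detected pulses to CSV
#' @param pulses a `ppg_pulse_set`.
#' @param path destination CSV (`onset,peak,offset`, 1-based indices).
#' @return `path`, invisibly.
#' @export
save_pulses <- function(pulses, path) {
  df <- data.frame(onset = pulses$onsets, peak = pulses$peaks,
                   offset = pulses$offsets)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
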