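# Synthetic neck-PPG cohort generator.
#
# Emulates the experimental protocol the classifiers target: per subject, one
# control recording, one slow-breathing recording, one breath-hold (apnea)
# recording and ten artifact recordings of 140 s at 75 Hz, with exact
# generator-truth annotations. The generative model is a test harness, not a
# physiological claim: it is designed so that the discriminative features of
# the pipeline (envelope variability, spectral entropy, pulse-height
# differences) separate the classes.

#' Configuration for the synthetic cohort generator
#'
#' @param n_subjects number of subjects (>= 2; default 12).
#' @param fs sampling rate in Hz (default 75).
#' @param duration recording duration in seconds (default 140).
#' @param heart_rate_range per-subject heart-rate interval in bpm.
#' @param resp_rate_range per-subject respiratory-rate interval in Hz.
#' @param resp_mod_depth fractional respiratory amplitude modulation of the
#'   pulse train during spontaneous breathing.
#' @param apnea_mod_depth residual modulation depth during breath-hold
#'   episodes (must be < `resp_mod_depth`).
#' @param artifact_snr_db artifact-to-pulse power ratio in dB added during
#'   artifact bursts.
#' @param noise_std baseline white sensor-noise standard deviation.
#' @param seed RNG seed controlling the whole cohort.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 12, fs = 75, duration = 140,
                         heart_rate_range = c(55, 90),
                         resp_rate_range = c(0.15, 0.35),
                         resp_mod_depth = 0.3, apnea_mod_depth = 0.02,
                         artifact_snr_db = 6, noise_std = 0.02, seed = 1) {
  stopifnot(fs > 0, duration > 0)
  if (n_subjects < 2) {
    stop_neckppg("n_subjects must be >= 2", class = "neckppg_validation_error")
  }
  if (diff(heart_rate_range) <= 0 || diff(resp_rate_range) <= 0) {
    stop_neckppg("parameter ranges must be non-degenerate",
                 class = "neckppg_validation_error")
  }
  if (apnea_mod_depth >= resp_mod_depth) {
    stop_neckppg("apnea_mod_depth must be below resp_mod_depth",
                 class = "neckppg_validation_error")
  }
  structure(list(n_subjects = n_subjects, fs = fs, duration = duration,
                 heart_rate_range = heart_rate_range,
                 resp_rate_range = resp_rate_range,
                 resp_mod_depth = resp_mod_depth,
                 apnea_mod_depth = apnea_mod_depth,
                 artifact_snr_db = artifact_snr_db,
                 noise_std = noise_std, seed = seed),
            class = "synth_config")
}

#' Single-pulse waveform template
#'
#' Builds one PPG pulse: a raised-cosine upstroke from 0 to the systolic peak
#' (value 1) at sample `round(rise_time * fs)` (0-based), followed by a
#' squared-cosine decay back towards 0 carrying a Gaussian dicrotic bump of
#' relative height `notch_depth`.
#'
#' @param rise_time time from onset to systolic peak, seconds.
#' @param width total pulse duration, seconds (`rise_time < width`).
#' @param notch_depth dicrotic bump height as a fraction of the local
#'   peak-to-baseline gap, in `[0, 1)`.
#' @param fs sampling rate, Hz.
#' @return numeric vector of length `round(width * fs)`.
#' @export
make_pulse_template <- function(rise_time, width, notch_depth, fs) {
  if (rise_time <= 0 || rise_time >= width) {
    stop_neckppg("need 0 < rise_time < width", class = "neckppg_validation_error")
  }
  if (notch_depth < 0 || notch_depth >= 1) {
    stop_neckppg("notch_depth must be in [0, 1)", class = "neckppg_validation_error")
  }
  n <- round(width * fs)
  p <- round(rise_time * fs)         # 0-based peak index
  if (p < 1 || p > n - 2) {
    stop_neckppg("pulse too short for the requested rise time",
                 class = "neckppg_validation_error")
  }
  i <- 0:(n - 1)
  y <- numeric(n)
  rise <- i <= p
  y[rise] <- 0.5 * (1 - cos(pi * i[rise] / p))
  u <- (i[!rise] - p) / (n - 1 - p)
  base <- cos(pi / 2 * u)^2
  bump <- notch_depth * exp(-0.5 * ((u - 0.45) / 0.05)^2) * (1 - base)
  y[!rise] <- base + bump
  y / max(y)
}

# Piecewise-constant lookup of episode membership for a vector of times.
in_segments <- function(t, segs) {
  if (is.null(segs) || nrow(segs) == 0) return(rep(FALSE, length(t)))
  hit <- rep(FALSE, length(t))
  for (k in seq_len(nrow(segs))) {
    hit <- hit | (t >= segs$onset[k] & t < segs$offset[k])
  }
  hit
}

# Draw three non-overlapping 20-30 s episodes separated by >= 8 s gaps.
draw_episodes <- function(duration, label) {
  durs <- runif(3, 20, 30)
  slack <- duration - sum(durs) - 4 * 8
  gaps <- 8 + slack * {
    g <- runif(4)
    g / sum(g)
  }
  onsets <- cumsum(gaps)[1:3] + cumsum(c(0, durs[-3]))
  data.frame(onset = onsets, offset = onsets + durs, label = label,
             stringsAsFactors = FALSE)
}

# Subtype-specific corruption waveform, unit power.
artifact_wave <- function(subtype, n, fs) {
  t <- (0:(n - 1)) / fs
  w <- switch(subtype,
    talking = , coughing = , fast_breathing = , sensor_rubbing = {
      bf <- signal::butter(2, c(1, 10) / (fs / 2), type = "pass")
      as.numeric(signal::filtfilt(bf, rnorm(n + 2 * fs)))[(fs + 1):(fs + n)]
    },
    swallowing = , yawning = {
      # step/ramp excursion: up-ramp, plateau, down-ramp
      k <- sort(runif(2, 0.2, 0.8)) * n
      ramp <- approx(c(0, k[1], mean(k), k[2], n - 1),
                     c(0, 1, runif(1, 0.6, 1.4), 1, 0), xout = 0:(n - 1))$y
      ramp + 0.1 * rnorm(n)
    },
    head_movement = , body_movement = {
      f <- runif(1, 0.3, 0.8)
      sin(2 * pi * f * t + runif(1, 0, 2 * pi)) +
        0.5 * sin(2 * pi * 2 * f * t + runif(1, 0, 2 * pi))
    },
    stop_neckppg("unknown artifact subtype '%s'", subtype,
                 class = "neckppg_validation_error")
  )
  w / sqrt(mean(w^2))
}

#' Synthesize one annotated recording
#'
#' Builds a 140 s pulse train by concatenating per-beat templates at jittered
#' beat intervals, amplitude-modulated by the respiratory waveform, with slow
#' baseline wander and white sensor noise. Scenario-specific events (apnea
#' episodes, slow-breathing episodes, 20 s artifact bursts) are injected and
#' annotated exactly.
#'
#' @param cfg a [synth_config()].
#' @param subject list of subject-level parameters as drawn by
#'   [synth_cohort()] (`subject_id`, `hr_bpm`, `resp_hz`, `rise_time`,
#'   `notch_depth`, `amp`).
#' @param scenario one of the scenario tags (see [new_recording()]).
#' @param recording_id identifier for the new recording.
#' @return list with elements `recording` (`ppg_recording`, unnormalized),
#'   `annotations` (data.frame) and `truth` (beat onset/peak times in seconds
#'   plus the episode table).
#' @export
synth_recording <- function(cfg, subject, scenario, recording_id = "R1") {
  if (!scenario %in% SCENARIOS) {
    stop_neckppg("unknown scenario '%s'", scenario,
                 class = "neckppg_validation_error")
  }
  fs <- cfg$fs
  n <- round(cfg$duration * fs)
  t <- (0:(n - 1)) / fs

  episodes <- NULL
  if (scenario == "breath_hold") {
    episodes <- draw_episodes(cfg$duration, "apnea")
  } else if (scenario == "slow_breathing") {
    episodes <- draw_episodes(cfg$duration, "slow_breathing")
  } else if (startsWith(scenario, "artifact_")) {
    episodes <- data.frame(onset = c(20, 60, 100), offset = c(40, 80, 120),
                           label = sub("^artifact_", "", scenario),
                           stringsAsFactors = FALSE)
    episodes$label <- paste0("artifact_", episodes$label)
  }

  in_ep <- in_segments(t, episodes)

  # respiratory modulation with phase-continuous instantaneous frequency
  f_resp <- rep(subject$resp_hz, n)
  depth <- rep(cfg$resp_mod_depth, n)
  if (scenario == "slow_breathing") f_resp[in_ep] <- subject$resp_hz / 2
  if (scenario == "breath_hold") depth[in_ep] <- cfg$apnea_mod_depth
  phase <- 2 * pi * cumsum(f_resp) / fs
  modulation <- 1 + depth * sin(phase)

  # beat train
  base_ibi <- 60 / subject$hr_bpm
  x <- numeric(n)
  beat_onset <- numeric(0)
  beat_peak <- numeric(0)
  t0 <- runif(1, 0, base_ibi)
  while (TRUE) {
    cv <- if (scenario == "breath_hold" &&
              any(in_segments(t0, episodes))) 0.01 else 0.03
    ibi <- base_ibi * exp(rnorm(1, 0, cv))
    if (t0 + ibi > cfg$duration) break
    tpl <- make_pulse_template(subject$rise_time, ibi, subject$notch_depth, fs)
    i0 <- round(t0 * fs) + 1L
    i1 <- min(n, i0 + length(tpl) - 1L)
    amp <- subject$amp * modulation[i0]
    x[i0:i1] <- x[i0:i1] + amp * tpl[seq_len(i1 - i0 + 1L)]
    beat_onset <- c(beat_onset, t0)
    beat_peak <- c(beat_peak, t0 + round(subject$rise_time * fs) / fs)
    t0 <- t0 + ibi
  }

  # baseline wander + sensor noise
  x <- x + 0.08 * sin(2 * pi * 0.05 * t + runif(1, 0, 2 * pi)) +
    rnorm(n, 0, cfg$noise_std)

  # artifact bursts scaled to the configured artifact-to-pulse power ratio
  if (startsWith(scenario, "artifact_")) {
    subtype <- sub("^artifact_", "", scenario)
    for (k in seq_len(nrow(episodes))) {
      idx <- which(t >= episodes$onset[k] & t < episodes$offset[k])
      pulse_power <- mean(x[idx]^2)
      wave <- artifact_wave(subtype, length(idx), fs)
      x[idx] <- x[idx] + sqrt(pulse_power * 10^(cfg$artifact_snr_db / 10)) * wave
    }
  }

  ann <- if (is.null(episodes)) {
    data.frame(onset = numeric(0), offset = numeric(0), label = character(0),
               stringsAsFactors = FALSE)
  } else if (startsWith(scenario, "artifact_")) {
    # spontaneous-breathing gaps annotated explicitly
    gaps <- data.frame(onset = c(0, episodes$offset),
                       offset = c(episodes$onset, cfg$duration),
                       label = "normal", stringsAsFactors = FALSE)
    gaps <- gaps[gaps$offset > gaps$onset, , drop = FALSE]
    rbind(episodes, gaps)
  } else {
    episodes
  }

  rec <- new_recording(x, fs = fs, subject_id = subject$subject_id,
                       recording_id = recording_id, scenario = scenario)
  list(recording = rec, annotations = validate_annotations(ann, cfg$duration),
       truth = list(beat_onsets = beat_onset, beat_peaks = beat_peak,
                    episodes = ann))
}

#' Synthesize a full annotated cohort
#'
#' Per subject: one control, one slow-breathing, one breath-hold and ten
#' artifact recordings (cycling through the eight artifact subtypes).
#' Subject-level heart rate, respiratory rate and pulse morphology are drawn
#' once per subject so leave-one-subject-out validation sees realistic
#' between-subject variance. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return a `ppg_cohort`; generator truth for each recording is attached as
#'   `cohort$truth[[recording_id]]`.
#' @export
synth_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    recordings <- list()
    annotations <- list()
    truth <- list()
    subtypes <- ARTIFACT_SUBTYPES[(0:9 %% length(ARTIFACT_SUBTYPES)) + 1L]
    for (s in seq_len(cfg$n_subjects)) {
      subject <- list(
        subject_id = sprintf("sub%02d", s),
        hr_bpm = runif(1, cfg$heart_rate_range[1], cfg$heart_rate_range[2]),
        resp_hz = runif(1, cfg$resp_rate_range[1], cfg$resp_rate_range[2]),
        rise_time = runif(1, 0.12, 0.18),
        notch_depth = runif(1, 0.08, 0.25),
        amp = runif(1, 0.8, 1.2)
      )
      scen <- c("control", "slow_breathing", "breath_hold",
                paste0("artifact_", subtypes))
      for (r in seq_along(scen)) {
        rid <- sprintf("%s_r%02d_%s", subject$subject_id, r, scen[r])
        out <- synth_recording(cfg, subject, scen[r], recording_id = rid)
        recordings[[rid]] <- out$recording
        annotations[[rid]] <- out$annotations
        truth[[rid]] <- out$truth
      }
    }
    cohort <- new_cohort(recordings, annotations)
    cohort$truth <- truth
    cohort
  })
}
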