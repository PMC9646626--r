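# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# 4-subject cohort at the generator's default signal parameters
small_cohort <- function() {
  fixture("small_cohort", function() {
    synth_cohort(synth_config(n_subjects = 4, seed = 42))
  })
}

# features of the small cohort at W = 6 (all scenarios)
small_features_w6 <- function() {
  fixture("small_features_w6", function() {
    extract_cohort_features(small_cohort(), 6)
  })
}

# features of the small cohort's breath-hold recordings at W = 10
small_features_apnea_w10 <- function() {
  fixture("small_features_apnea_w10", function() {
    extract_cohort_features(small_cohort(), 10, scenarios = "breath_hold")
  })
}

default_subject <- function(subject_id = "s1") {
  list(subject_id = subject_id, hr_bpm = 75, resp_hz = 0.25,
       rise_time = 0.15, notch_depth = 0.15, amp = 1)
}

# one deterministic synthetic recording (+ truth), normalized
synth_one <- function(scenario = "control", seed = 3, cfg = synth_config()) {
  out <- with_seed(seed, synth_recording(cfg, default_subject(), scenario,
                                         recording_id = scenario))
  out$normalized <- normalize_recording(out$recording)
  out
}

# a recording wrapping an arbitrary sample vector
wrap_recording <- function(x, fs = 75, normalized = FALSE, ...) {
  new_recording(x, fs = fs, normalized = normalized, ...)
}

# random feature table with 51 named noise columns, a label and subjects;
# individual columns can then be overwritten with informative signals
noise_table <- function(n = 200, n_subjects = 4, seed = 1) {
  with_seed(seed, {
    X <- matrix(rnorm(n * 51), n, 51, dimnames = list(NULL, ppg_feature_names()))
    data.frame(
      subject = rep(sprintf("sub%02d", seq_len(n_subjects)), length.out = n),
      recording = "r1", window_start = seq_len(n) * 2,
      label = rep(c(-1, 1), length.out = n),
      as.data.frame(X), check.names = FALSE
    )
  })
}
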