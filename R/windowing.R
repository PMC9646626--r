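# Sliding-window segmentation, corruption-threshold labelling and balanced
# feature-table assembly for the two classification tasks.

WINDOW_LENGTHS <- c(4, 5, 6, 7, 8, 10)
CORRUPTION_THRESHOLDS <- c(0.20, 0.30, 0.40, 0.50)

#' Sliding windows over a recording
#'
#' Half-open `[start, start + W)` windows starting at 0, 2, 4, ... seconds
#' while the window still fits; count = `floor((duration - W)/shift) + 1`.
#'
#' @param rec a `ppg_recording`.
#' @param W window length, seconds.
#' @param shift shift between consecutive windows, seconds (default 2).
#' @return data.frame with `recording_id`, `start`, `W`, `index`.
#' @export
segment_windows <- function(rec, W, shift = 2) {
  duration <- recording_duration(rec)
  if (W > duration) {
    stop_neckppg("window length %g s exceeds recording duration %g s",
                 W, duration, class = "neckppg_validation_error")
  }
  n <- floor((duration - W) / shift) + 1
  starts <- (seq_len(n) - 1) * shift
  data.frame(recording_id = rec$recording_id, start = starts, W = W,
             index = seq_len(n), stringsAsFactors = FALSE)
}

# total overlap (seconds) of [start, start+W) with the labelled segments
overlap_seconds <- function(start, W, segs) {
  if (is.null(segs) || nrow(segs) == 0) return(rep(0, length(start)))
  out <- numeric(length(start))
  for (k in seq_len(nrow(segs))) {
    out <- out + pmax(0, pmin(start + W, segs$offset[k]) -
                        pmax(start, segs$onset[k]))
  }
  out
}

task_positive_labels <- function(task) {
  switch(task,
    artifacts = paste0("artifact_", ARTIFACT_SUBTYPES),
    apnea = "apnea",
    stop_neckppg("unknown task '%s'", task, class = "neckppg_validation_error")
  )
}

#' Label one window by corruption threshold
#'
#' The corrupt fraction is the total overlap of positive-class segments with
#' the half-open window divided by `W`; the window is positive when the
#' fraction reaches `Thd`. For the apnea task, windows overlapping any
#' artifact segment are excluded (label `NA`): apnea detection operates on
#' the clean-PPG universe.
#'
#' @param start window start, seconds.
#' @param W window length, seconds.
#' @param annotations annotation data.frame of the recording.
#' @param task `"artifacts"` or `"apnea"`.
#' @param Thd corruption threshold, fraction in (0, 1].
#' @return list with `label` (+1/-1, or `NA` for excluded windows) and
#'   `corrupt_fraction`.
#' @export
label_window <- function(start, W, annotations, task, Thd) {
  pos <- task_positive_labels(task)
  segs <- annotations[annotations$label %in% pos, , drop = FALSE]
  frac <- overlap_seconds(start, W, segs) / W
  label <- ifelse(frac >= Thd, 1, -1)
  if (task == "apnea") {
    art <- annotations[startsWith(annotations$label, "artifact_"), , drop = FALSE]
    excl <- overlap_seconds(start, W, art) > 0
    label[excl] <- NA
  }
  list(label = label, corrupt_fraction = frac)
}

#' Extract features for all windows of one recording
#'
#' Normalizes the recording if needed, detects pulses, computes the
#' spectrogram once, then assembles the 51-feature vector per sliding window.
#'
#' @param rec a `ppg_recording`.
#' @param W window length, seconds.
#' @param shift window shift, seconds.
#' @return data.frame: `subject`, `recording`, `scenario`, `window_start`,
#'   `W`, `index` plus the 51 feature columns.
#' @export
extract_recording_features <- function(rec, W, shift = 2) {
  if (!rec$normalized) rec <- normalize_recording(rec)
  pulses <- detect_pulses(rec)
  pp <- per_pulse_features(rec, pulses)
  spec <- compute_spectrogram(rec)
  wins <- segment_windows(rec, W, shift)
  feats <- matrix(NA_real_, nrow(wins), 51,
                  dimnames = list(NULL, ppg_feature_names()))
  for (i in seq_len(nrow(wins))) {
    feats[i, ] <- suppressWarnings(
      extract_feature_vector(rec, pulses, wins$start[i], W, spec, pp = pp)
    )
  }
  cbind(
    data.frame(subject = rec$subject_id, recording = rec$recording_id,
               scenario = rec$scenario, window_start = wins$start, W = W,
               index = wins$index, stringsAsFactors = FALSE),
    as.data.frame(feats)
  )
}

#' Extract features and corruption fractions for a whole cohort
#'
#' One row per sliding window, with per-task corruption fractions and an
#' artifact-overlap flag, ready for [build_feature_table()] to label and
#' balance at any threshold without re-extracting.
#'
#' @param cohort a `ppg_cohort`.
#' @param W window length, seconds.
#' @param scenarios optional scenario subset to restrict extraction to.
#' @param shift window shift, seconds.
#' @return data.frame of window metadata, fractions and the 51 features.
#' @export
extract_cohort_features <- function(cohort, W, scenarios = NULL, shift = 2) {
  stopifnot(inherits(cohort, "ppg_cohort"))
  rows <- list()
  for (id in names(cohort$recordings)) {
    rec <- cohort$recordings[[id]]
    if (!is.null(scenarios) && !rec$scenario %in% scenarios) next
    ft <- extract_recording_features(rec, W, shift)
    ann <- cohort$annotations[[id]]
    art <- ann[startsWith(ann$label, "artifact_"), , drop = FALSE]
    apn <- ann[ann$label == "apnea", , drop = FALSE]
    ft$artifact_fraction <- overlap_seconds(ft$window_start, W, art) / W
    ft$apnea_fraction <- overlap_seconds(ft$window_start, W, apn) / W
    rows[[id]] <- ft
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Build a balanced, labelled feature table
#'
#' Labels every extracted window for the requested task and threshold, drops
#' rows with unavailable (NaN) features, and downsamples the majority class
#' uniformly at random (seeded) so the table is exactly balanced. For the
#' apnea task the universe is restricted to breath-hold recordings (the
#' interleaved apnea / spontaneous-breathing protocol), and balancing is done
#' within each subject's three duration-equal recording segments so the
#' thirds partition stays balanced; windows straddling a segment border are
#' dropped.
#'
#' @param cohort a `ppg_cohort`.
#' @param task `"artifacts"` or `"apnea"`.
#' @param W window length, seconds.
#' @param Thd corruption threshold, fraction.
#' @param seed RNG seed for the balancing subsample.
#' @param features optional precomputed [extract_cohort_features()] table
#'   (for the right `W` and, for apnea, restricted to clean scenarios).
#' @param max_per_class cap on the per-class size of the balanced table
#'   (seeded downsampling; `Inf` disables the cap).
#' @return data.frame with metadata, `label` (+1/-1), `corrupt_fraction`,
#'   `segment` (apnea task) and the 51 features; attribute `n_dropped_nan`
#'   records rows lost to the NaN policy.
#' @export
build_feature_table <- function(cohort, task, W, Thd, seed = 1,
                                features = NULL, max_per_class = 300) {
  task <- match.arg(task, c("artifacts", "apnea"))
  if (is.null(features)) {
    scen <- if (task == "apnea") "breath_hold" else NULL
    features <- extract_cohort_features(cohort, W, scenarios = scen)
  }
  if (task == "apnea") {
    features <- features[features$scenario == "breath_hold", , drop = FALSE]
  }
  stopifnot(all(features$W == W))

  # label from precomputed fractions
  frac <- if (task == "artifacts") features$artifact_fraction else features$apnea_fraction
  features$corrupt_fraction <- frac
  features$label <- ifelse(frac >= Thd, 1, -1)
  if (task == "apnea") {
    features$label[features$artifact_fraction > 0] <- NA
  }
  features <- features[!is.na(features$label), , drop = FALSE]

  fcols <- ppg_feature_names()
  nan_row <- !stats::complete.cases(features[, fcols])
  n_dropped <- sum(nan_row)
  features <- features[!nan_row, , drop = FALSE]

  if (task == "apnea") {
    # duration-equal thirds per recording; drop border-straddling windows
    dur <- vapply(features$recording, function(id) {
      recording_duration(cohort$recordings[[id]])
    }, numeric(1))
    b1 <- dur / 3; b2 <- 2 * dur / 3
    s <- features$window_start; e <- s + W
    seg <- rep(NA_integer_, nrow(features))
    seg[e <= b1 + 1e-9] <- 1L
    seg[s >= b1 - 1e-9 & e <= b2 + 1e-9] <- 2L
    seg[s >= b2 - 1e-9] <- 3L
    features$segment <- seg
    features <- features[!is.na(features$segment), , drop = FALSE]
  }

  pos <- features$label == 1
  if (!any(pos) || all(pos)) {
    stop_neckppg("class absent after labelling (task=%s, W=%g, Thd=%g)",
                 task, W, Thd, class = "neckppg_empty_class_error")
  }

  balanced <- with_seed(seed, {
    if (task == "apnea") {
      groups <- split(seq_len(nrow(features)),
                      list(features$subject, features$segment), drop = TRUE)
    } else {
      groups <- list(seq_len(nrow(features)))
    }
    keep <- integer(0)
    for (g in groups) {
      p <- g[features$label[g] == 1]
      n <- g[features$label[g] == -1]
      m <- min(length(p), length(n))
      if (is.finite(max_per_class)) {
        m <- min(m, ceiling(max_per_class / length(groups)))
      }
      if (m == 0) next
      keep <- c(keep, p[sample.int(length(p), m)], n[sample.int(length(n), m)])
    }
    sort(keep)
  })
  out <- features[balanced, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_nan") <- n_dropped
  attr(out, "task") <- task
  attr(out, "Thd") <- Thd
  out
}

#' Write a labelled feature table to CSV
#' @param table a feature table.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
save_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
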