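#' @useDynLib neckppg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd fft splinefun rnorm runif quantile chisq.test
#' @importFrom utils read.csv write.csv
NULL

ARTIFACT_SUBTYPES <- c(
  "fast_breathing", "talking", "head_movement", "body_movement",
  "swallowing", "coughing", "yawning", "sensor_rubbing"
)

SCENARIOS <- c("control", "slow_breathing", "breath_hold",
               paste0("artifact_", ARTIFACT_SUBTYPES))

ANNOTATION_LABELS <- c("normal", "slow_breathing", "apnea",
                       paste0("artifact_", ARTIFACT_SUBTYPES))

#' Construct a PPG recording
#'
#' A recording is one subject's single-channel PPG trace with its sampling
#' rate, scenario tag and normalization state.
#'
#' @param samples numeric vector of PPG amplitudes (arbitrary units).
#' @param fs sampling rate in Hz (default 75).
#' @param subject_id,recording_id identifier strings.
#' @param scenario one of `"control"`, `"slow_breathing"`, `"breath_hold"` or
#'   `"artifact_<subtype>"`.
#' @param normalized logical; `TRUE` once [normalize_recording()] has been
#'   applied.
#' @return an object of class `ppg_recording`.
#' @export
new_recording <- function(samples, fs = 75, subject_id = "S1",
                          recording_id = "R1", scenario = "control",
                          normalized = FALSE) {
  fs <- as.numeric(fs)
  if (!is.numeric(fs) || length(fs) != 1 || is.na(fs) || fs <= 0) {
    stop_neckppg("fs must be a positive scalar, got %s", fs,
                 class = "neckppg_validation_error")
  }
  samples <- as.numeric(samples)
  if (anyNA(samples)) {
    stop_neckppg("recording samples contain NA", class = "neckppg_validation_error")
  }
  if (length(samples) < 2 * fs) {
    stop_neckppg("recording must span at least 2 s (%d samples at %g Hz)",
                 ceiling(2 * fs), fs, class = "neckppg_validation_error")
  }
  if (!scenario %in% SCENARIOS) {
    stop_neckppg("unknown scenario '%s'", scenario,
                 class = "neckppg_validation_error")
  }
  if (normalized) {
    if (abs(mean(samples)) > 1e-9 || abs(sd(samples) - 1) > 1e-9) {
      stop_neckppg("normalized recording must have mean 0 and sd 1",
                   class = "neckppg_validation_error")
    }
  }
  structure(
    list(subject_id = subject_id, recording_id = recording_id,
         scenario = scenario, fs = fs, samples = samples,
         normalized = isTRUE(normalized)),
    class = "ppg_recording"
  )
}

#' @export
print.ppg_recording <- function(x, ...) {
  cat(sprintf("<ppg_recording %s/%s [%s] %.1f s @ %g Hz%s>\n",
              x$subject_id, x$recording_id, x$scenario,
              length(x$samples) / x$fs, x$fs,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a `ppg_recording`.
#' @return duration in seconds.
#' @export
recording_duration <- function(rec) length(rec$samples) / rec$fs

#' Z-score normalize a recording
#'
#' Each recording is normalized independently: the mean is subtracted and the
#' result divided by the sample standard deviation, making amplitudes
#' comparable across subjects and sensors and centring the trace so the
#' zero-crossing rate is meaningful.
#'
#' @param rec a `ppg_recording` that has not been normalized yet.
#' @return a normalized copy of `rec`.
#' @export
normalize_recording <- function(rec) {
  stopifnot(inherits(rec, "ppg_recording"))
  if (rec$normalized) {
    stop_neckppg("recording %s is already normalized", rec$recording_id,
                 class = "neckppg_precondition_error")
  }
  s <- sd(rec$samples)
  if (!is.finite(s) || s == 0) {
    stop_neckppg("degenerate (constant) signal in recording %s",
                 rec$recording_id, class = "neckppg_degenerate_signal_error")
  }
  rec$samples <- (rec$samples - mean(rec$samples)) / s
  rec$normalized <- TRUE
  rec
}

#' Read a recording from CSV + JSON sidecar
#'
#' The CSV holds either a single `ppg` column or `t,ppg`; the sidecar
#' `<path-without-.csv>.json` carries `subject_id`, `recording_id`,
#' `scenario`, `fs` and `normalized`.
#'
#' @param path path to the recording CSV.
#' @return a `ppg_recording`.
#' @export
load_recording <- function(path) {
  if (!file.exists(path)) {
    stop_neckppg("recording file not found: %s", path, class = "neckppg_io_error")
  }
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  if (!"ppg" %in% names(df)) {
    stop_neckppg("recording CSV %s lacks a 'ppg' column", path,
                 class = "neckppg_parse_error")
  }
  raw <- df[["ppg"]]
  samples <- suppressWarnings(as.numeric(raw))
  if (anyNA(samples)) {
    bad <- which(is.na(samples))[1]
    stop_neckppg("non-numeric sample '%s' at row %d of %s", raw[bad], bad, path,
                 class = "neckppg_parse_error")
  }
  meta_path <- sidecar_path(path)
  meta <- list()
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  }
  fs <- meta$fs
  if (is.null(fs)) {
    message("no fs in sidecar for ", path, "; defaulting to 75 Hz")
    fs <- 75
  }
  if (fs <= 0) {
    stop_neckppg("fs must be positive, sidecar of %s has %g", path, fs,
                 class = "neckppg_validation_error")
  }
  new_recording(samples, fs = fs,
                subject_id = meta$subject_id %||% "S1",
                recording_id = meta$recording_id %||% basename(path),
                scenario = meta$scenario %||% "control",
                normalized = isTRUE(meta$normalized))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write a recording to CSV + JSON sidecar
#'
#' Samples are serialized at full double precision so that
#' [load_recording()] inverts [save_recording()] bit-for-bit.
#'
#' @param rec a `ppg_recording`.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
save_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ppg_recording"))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop_neckppg("directory does not exist: %s", dir, class = "neckppg_io_error")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("ppg", con)
  writeLines(formatC(rec$samples, format = "g", digits = 17), con)
  jsonlite::write_json(
    list(subject_id = rec$subject_id, recording_id = rec$recording_id,
         scenario = rec$scenario, fs = rec$fs, normalized = rec$normalized),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read an annotation table
#'
#' Annotations are half-open `[onset, offset)` intervals in seconds with a
#' class label; gaps between segments are implicitly `normal`.
#'
#' @param path CSV with header `onset,offset,label`.
#' @return a `data.frame` with columns `onset`, `offset`, `label`, sorted by
#'   onset.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) {
    stop_neckppg("annotation file not found: %s", path, class = "neckppg_io_error")
  }
  df <- read.csv(path, colClasses = c("numeric", "numeric", "character"))
  validate_annotations(df)
}

#' Validate and sort an annotation table
#'
#' @param df data.frame with `onset`, `offset`, `label`.
#' @param duration optional recording duration (s) to bound offsets.
#' @return the validated, onset-sorted data.frame.
#' @export
validate_annotations <- function(df, duration = NULL) {
  stopifnot(all(c("onset", "offset", "label") %in% names(df)))
  if (nrow(df) == 0) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  }
  if (any(df$offset <= df$onset)) {
    i <- which(df$offset <= df$onset)[1]
    stop_neckppg("segment %d has offset <= onset (%g <= %g)", i,
                 df$offset[i], df$onset[i], class = "neckppg_validation_error")
  }
  if (any(df$onset < 0)) {
    stop_neckppg("negative onset", class = "neckppg_validation_error")
  }
  if (!is.null(duration) && any(df$offset > duration + 1e-9)) {
    stop_neckppg("segment offset exceeds recording duration %g s", duration,
                 class = "neckppg_validation_error")
  }
  bad <- !df$label %in% ANNOTATION_LABELS
  if (any(bad)) {
    stop_neckppg("unknown annotation label '%s'", df$label[which(bad)[1]],
                 class = "neckppg_validation_error")
  }
  df <- df[order(df$onset), , drop = FALSE]
  if (nrow(df) > 1) {
    overlap <- which(df$onset[-1] < df$offset[-nrow(df)] - 1e-9)
    if (length(overlap)) {
      i <- overlap[1]
      stop_neckppg("segments %d and %d overlap ([%g,%g) vs [%g,%g))",
                   i, i + 1, df$onset[i], df$offset[i],
                   df$onset[i + 1], df$offset[i + 1],
                   class = "neckppg_validation_error")
    }
  }
  rownames(df) <- NULL
  df
}

#' Write an annotation table
#' @param ann annotation data.frame (`onset,offset,label`).
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
save_annotations <- function(ann, path) {
  ann <- validate_annotations(ann)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("onset,offset,label", con)
  if (nrow(ann)) {
    writeLines(sprintf("%s,%s,%s",
                       formatC(ann$onset, format = "g", digits = 17),
                       formatC(ann$offset, format = "g", digits = 17),
                       ann$label), con)
  }
  invisible(path)
}

#' Assemble a cohort
#'
#' @param recordings list of `ppg_recording` objects.
#' @param annotations named list: `recording_id` -> annotation data.frame.
#' @return an object of class `ppg_cohort` with elements `recordings`
#'   (named by recording_id), `annotations` and `subjects`.
#' @export
new_cohort <- function(recordings, annotations) {
  ids <- vapply(recordings, `[[`, character(1), "recording_id")
  names(recordings) <- ids
  missing <- setdiff(ids, names(annotations))
  if (length(missing)) {
    stop_neckppg("recordings without annotations: %s",
                 paste(missing, collapse = ", "),
                 class = "neckppg_validation_error")
  }
  subjects <- unique(vapply(recordings, `[[`, character(1), "subject_id"))
  structure(list(recordings = recordings,
                 annotations = annotations[ids],
                 subjects = subjects),
            class = "ppg_cohort")
}

#' @export
print.ppg_cohort <- function(x, ...) {
  cat(sprintf("<ppg_cohort: %d subjects, %d recordings>\n",
              length(x$subjects), length(x$recordings)))
  invisible(x)
}

#' Write a cohort to a directory
#'
#' One `<recording_id>.csv` + `.json` sidecar and one
#' `<recording_id>_annotations.csv` per recording.
#'
#' @param cohort a `ppg_cohort`.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$recordings)) {
    save_recording(cohort$recordings[[id]], file.path(dir, paste0(id, ".csv")))
    save_annotations(cohort$annotations[[id]],
                     file.path(dir, paste0(id, "_annotations.csv")))
  }
  invisible(dir)
}

#' Read a cohort written by [save_cohort()]
#' @param dir directory containing recording CSVs and sidecars.
#' @return a `ppg_cohort`.
#' @export
load_cohort <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  rec_files <- files[!grepl("_annotations\\.csv$", files)]
  recordings <- lapply(rec_files, load_recording)
  ids <- vapply(recordings, `[[`, character(1), "recording_id")
  annotations <- lapply(seq_along(rec_files), function(i) {
    load_annotations(sub("\\.csv$", "_annotations.csv", rec_files[i]))
  })
  names(annotations) <- ids
  new_cohort(recordings, annotations)
}
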