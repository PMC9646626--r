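# Confusion-matrix metrics, the repeated-randomization experiment driver,
# best-model selection and the feature selection-frequency report.

#' Metrics from confusion counts
#'
#' ACC, sensitivity, specificity, precision and F1 (all in %) from the four
#' confusion counts; zero-denominator metrics are `NaN` with a warning.
#' Counts may be non-integer means over repetitions.
#'
#' @param TP,TN,FP,FN confusion counts.
#' @return list with the counts and `ACC`, `SE`, `SP`, `precision`, `F1`.
#' @export
metrics_from_counts <- function(TP, TN, FP, FN) {
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NaN)
    }
    100 * num / den
  }
  ACC <- ratio(TP + TN, TP + TN + FP + FN, "ACC")
  SE <- ratio(TP, TP + FN, "SE")
  SP <- ratio(TN, TN + FP, "SP")
  precision <- ratio(TP, TP + FP, "precision")
  F1 <- if (is.nan(SE) || is.nan(precision) || SE + precision == 0) {
    warning("F1 undefined")
    NaN
  } else {
    2 * precision * SE / (precision + SE)
  }
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       ACC = ACC, SE = SE, SP = SP, precision = precision, F1 = F1)
}

#' Classification metrics from labels
#'
#' @param y_true,y_pred -1/+1 label vectors of equal length.
#' @return list as in [metrics_from_counts()].
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop_neckppg("y_true and y_pred lengths differ (%d vs %d)",
                 length(y_true), length(y_pred),
                 class = "neckppg_validation_error")
  }
  stopifnot(all(y_true %in% c(-1, 1)), all(y_pred %in% c(-1, 1)))
  metrics_from_counts(
    TP = sum(y_true == 1 & y_pred == 1),
    TN = sum(y_true == -1 & y_pred == -1),
    FP = sum(y_true == -1 & y_pred == 1),
    FN = sum(y_true == 1 & y_pred == -1)
  )
}

# one repetition: build table -> partition -> fit pipeline -> test metrics
run_single_repetition <- function(cohort, task, W, Thd, rep, seed,
                                  features, max_per_class) {
  table_seed <- derive_seed(seed, W, round(100 * Thd), rep, 1)
  tbl <- build_feature_table(cohort, task, W, Thd, seed = table_seed,
                             features = features,
                             max_per_class = max_per_class)
  if (task == "artifacts") {
    part_seed <- derive_seed(seed, W, round(100 * Thd), rep, 2)
    plan <- partition_leave_30pct_subjects(unique(tbl$subject), part_seed)
    train <- tbl[tbl$subject %in% plan$train_subjects, , drop = FALSE]
    test <- tbl[tbl$subject %in% plan$test_subjects, , drop = FALSE]
  } else {
    plan <- partition_recording_thirds(tbl, rep - 1)
    train <- tbl[plan$train_idx, , drop = FALSE]
    test <- tbl[plan$test_idx, , drop = FALSE]
  }
  fitted <- fit_pipeline(train, task)
  pred <- predict(fitted$model, test[, fitted$selected, drop = FALSE])
  metrics <- compute_metrics(test$label, pred)
  list(metrics = metrics, selected = fitted$selected,
       config = fitted$config, n_train = nrow(train), n_test = nrow(test))
}

#' Repeated-randomization experiment
#'
#' For every combination of window length and corruption threshold, runs
#' `n_reps` repetitions of: balanced table assembly, task-appropriate
#' subject-safe partition, chi-square ranking + grid search + forward
#' selection + final fit on the training side, and evaluation on the test
#' side. Aggregates mean and standard deviation per metric and accumulates
#' per-feature selection counts. Repetitions failing with an empty class are
#' recorded and skipped; more than 20% failures aborts the experiment.
#'
#' @param cohort a `ppg_cohort`.
#' @param task `"artifacts"` or `"apnea"`.
#' @param W_list window lengths (subset of 4, 5, 6, 7, 8, 10 s).
#' @param Thd_list corruption thresholds (subset of 0.2, 0.3, 0.4, 0.5).
#' @param n_reps repetitions per combination (30 in the full protocol).
#' @param seed master seed; every source of randomness derives from it.
#' @param max_per_class per-class cap of the balanced tables (see
#'   [build_feature_table()]).
#' @return object of class `ppg_experiment`: `per_rep` (one row per
#'   repetition and metric set), `summary` (mean/sd per combination),
#'   `selection_counts`, `best` (best W/Thd by the task's criterion),
#'   `failures`.
#' @export
run_repeated_experiment <- function(cohort, task = c("artifacts", "apnea"),
                                    W_list = WINDOW_LENGTHS,
                                    Thd_list = CORRUPTION_THRESHOLDS,
                                    n_reps = 30, seed = 1,
                                    max_per_class = 300) {
  task <- match.arg(task)
  stopifnot(all(W_list %in% WINDOW_LENGTHS),
            all(Thd_list %in% CORRUPTION_THRESHOLDS))
  per_rep <- list()
  sel_counts <- list()
  failures <- list()
  for (W in W_list) {
    scen <- if (task == "apnea") "breath_hold" else NULL
    features <- extract_cohort_features(cohort, W, scenarios = scen)
    for (Thd in Thd_list) {
      key <- sprintf("W%g_Thd%g", W, 100 * Thd)
      counts <- setNames(numeric(51), ppg_feature_names())
      n_ok <- 0
      for (rep in seq_len(n_reps)) {
        res <- tryCatch(
          run_single_repetition(cohort, task, W, Thd, rep, seed,
                                features, max_per_class),
          neckppg_empty_class_error = function(e) e,
          neckppg_partition_error = function(e) e
        )
        if (inherits(res, "condition")) {
          failures[[length(failures) + 1]] <-
            data.frame(task = task, W = W, Thd = Thd, rep = rep,
                       message = conditionMessage(res),
                       stringsAsFactors = FALSE)
          next
        }
        n_ok <- n_ok + 1
        m <- res$metrics
        per_rep[[length(per_rep) + 1]] <- data.frame(
          task = task, W = W, Thd = Thd, rep = rep,
          TP = m$TP, TN = m$TN, FP = m$FP, FN = m$FN,
          ACC = m$ACC, SE = m$SE, SP = m$SP, precision = m$precision,
          F1 = m$F1, C = res$config$C, gamma = res$config$gamma,
          n_selected = length(res$selected),
          n_train = res$n_train, n_test = res$n_test,
          stringsAsFactors = FALSE)
        counts[res$selected] <- counts[res$selected] + 1
      }
      if (n_ok < 0.8 * n_reps) {
        stop_neckppg("more than 20%% of repetitions failed for %s", key,
                     class = "neckppg_experiment_error")
      }
      sel_counts[[key]] <- counts / n_ok * 100
    }
  }
  per_rep <- do.call(rbind, per_rep)
  failures <- if (length(failures)) do.call(rbind, failures) else NULL
  summary <- aggregate_experiment(per_rep)
  crit <- if (task == "artifacts") "ACC" else "F1"
  best_row <- summary[which.max(summary[[paste0("mean_", crit)]]), ]
  structure(list(task = task, per_rep = per_rep, summary = summary,
                 selection_counts = sel_counts,
                 best = list(W = best_row$W, Thd = best_row$Thd,
                             criterion = crit,
                             value = best_row[[paste0("mean_", crit)]]),
                 failures = failures, seed = seed),
            class = "ppg_experiment")
}

# mean/sd aggregation per (W, Thd); undefined (NaN) metrics are excluded
# from aggregation with their count reported
aggregate_experiment <- function(per_rep) {
  metrics <- c("TP", "TN", "FP", "FN", "ACC", "SE", "SP", "precision", "F1")
  combos <- unique(per_rep[, c("task", "W", "Thd")])
  out <- NULL
  for (i in seq_len(nrow(combos))) {
    d <- per_rep[per_rep$W == combos$W[i] & per_rep$Thd == combos$Thd[i], ]
    row <- combos[i, ]
    row$n_effective <- nrow(d)
    for (m in metrics) {
      v <- d[[m]]
      row[[paste0("mean_", m)]] <- mean(v[!is.nan(v)])
      row[[paste0("sd_", m)]] <- sd(v[!is.nan(v)])
      row[[paste0("n_undefined_", m)]] <- sum(is.nan(v))
    }
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}

#' @export
print.ppg_experiment <- function(x, ...) {
  cat(sprintf("<ppg_experiment: %s task, %d repetitions x %d combinations>\n",
              x$task, max(x$per_rep$rep), nrow(x$summary)))
  cat(sprintf("best model: W=%g s, Thd=%g%% (%s=%.2f%%)\n",
              x$best$W, 100 * x$best$Thd, x$best$criterion, x$best$value))
  invisible(x)
}

#' Feature selection-frequency report
#'
#' Percentage of repetitions in which each of the 51 features entered the
#' final model for the experiment's best W/Thd combination, sorted
#' descending.
#'
#' @param result a `ppg_experiment`.
#' @param W,Thd combination to report (defaults to the best model).
#' @return 51-row data.frame `feature`, `frequency_pct`.
#' @export
selection_frequency_report <- function(result, W = result$best$W,
                                       Thd = result$best$Thd) {
  key <- sprintf("W%g_Thd%g", W, 100 * Thd)
  counts <- result$selection_counts[[key]]
  if (is.null(counts)) {
    stop_neckppg("no selection counts for %s", key,
                 class = "neckppg_validation_error")
  }
  df <- data.frame(feature = names(counts), frequency_pct = unname(counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$frequency_pct, match(df$feature, ppg_feature_names())), ]
  rownames(df) <- NULL
  df
}

#' Write experiment outputs to a directory
#'
#' `metrics_by_model.csv` (per-repetition rows), `summary_by_model.csv`,
#' `selection_frequency.csv` and `best_models.json`.
#'
#' @param result a `ppg_experiment`.
#' @param dir destination directory.
#' @return `dir`, invisibly.
#' @export
save_experiment <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$per_rep, file.path(dir, "metrics_by_model.csv"),
            row.names = FALSE)
  write.csv(result$summary, file.path(dir, "summary_by_model.csv"),
            row.names = FALSE)
  write.csv(selection_frequency_report(result),
            file.path(dir, "selection_frequency.csv"), row.names = FALSE)
  jsonlite::write_json(result$best, file.path(dir, "best_models.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
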