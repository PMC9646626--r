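# RBF-SVM training, LOSO grid search over the printed hyperparameter
# ladders, and the two subject-safe data partitions.

#' SVM hyperparameter configuration
#'
#' @param C soft-margin cost (> 0).
#' @param gamma RBF kernel width parameter (> 0).
#' @param task `"artifacts"` or `"apnea"` (drives the grid and the
#'   grid-search selection criterion).
#' @return object of class `svm_config`.
#' @export
svm_config <- function(C, gamma, task = c("artifacts", "apnea")) {
  task <- match.arg(task)
  stopifnot(C > 0, gamma > 0)
  structure(list(C = C, gamma = gamma, task = task), class = "svm_config")
}

#' Hyperparameter grid for a task
#'
#' The cost ladder differs per classifier; the kernel-width ladder
#' `2^-15, 2^-13, ..., 2^-1, 2^1, 2^3` is shared.
#'
#' @param task `"artifacts"` or `"apnea"`.
#' @return data.frame of 100 `(C, gamma)` rows ordered by ascending C then
#'   gamma (the tie-break order).
#' @export
svm_grid <- function(task = c("artifacts", "apnea")) {
  task <- match.arg(task)
  C <- switch(task,
    artifacts = c(0.5, 1, 4, 6, 8, 16, 32, 64, 80, 128),
    apnea = c(0.125, 0.75, 1, 2, 3, 4, 5, 6, 8, 32)
  )
  gamma <- 2^c(seq(-15, -1, by = 2), 1, 3)
  grid <- expand.grid(gamma = gamma, C = C)[, c("C", "gamma")]
  grid[order(grid$C, grid$gamma), , drop = FALSE]
}

canonical_order <- function(table) {
  table[order(table$subject, table$recording, table$window_start), ,
        drop = FALSE]
}

#' Train a soft-margin RBF-SVM
#'
#' Features are z-scored with training-set statistics (stored in the model so
#' test data reuses them), then passed to the libsvm solver with a Gaussian
#' kernel; the decision threshold is 0.
#'
#' @param X numeric data.frame/matrix of features (columns named).
#' @param y labels in -1/+1.
#' @param cfg an [svm_config()].
#' @return object of class `ppg_svm`.
#' @export
train_svm_rbf <- function(X, y, cfg) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) {
    stop_neckppg("non-finite feature values in training matrix",
                 class = "neckppg_validation_error")
  }
  if (length(unique(y)) < 2) {
    stop_neckppg("training labels contain a single class",
                 class = "neckppg_validation_error")
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  fit <- e1071::svm(Xs, factor(y, levels = c(-1, 1)),
                    type = "C-classification", kernel = "radial",
                    cost = cfg$C, gamma = cfg$gamma, scale = FALSE)
  structure(list(fit = fit, center = ctr, scale = scl,
                 features = colnames(X), config = cfg),
            class = "ppg_svm")
}

#' Predict labels with a trained RBF-SVM
#'
#' Columns are matched by name (input column order is irrelevant), the stored
#' training standardization is applied, and -1/+1 labels are returned.
#'
#' @param object a `ppg_svm`.
#' @param newdata data.frame/matrix containing the model's feature columns.
#' @param ... unused.
#' @return integer vector of -1/+1 labels.
#' @export
predict.ppg_svm <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing)) {
    stop_neckppg("missing feature column(s): %s",
                 paste(missing, collapse = ", "),
                 class = "neckppg_schema_error")
  }
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  if (any(!is.finite(X))) {
    stop_neckppg("non-finite feature values in prediction input",
                 class = "neckppg_validation_error")
  }
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  as.integer(as.character(predict(object$fit, Xs)))
}

#' LOSO grid search over the task's hyperparameter grid
#'
#' Evaluates every `(C, gamma)` combination by leave-one-subject-out
#' cross-validation on the training table. The artifacts classifier selects
#' the configuration maximizing the fold-mean accuracy; the apnea classifier
#' the one maximizing the F1-score of the pooled LOSO predictions. Ties are
#' broken towards smaller C, then smaller gamma.
#'
#' @param table balanced training feature table.
#' @param task `"artifacts"` or `"apnea"`.
#' @param feats feature subset to train on (default the full 51).
#' @return the winning [svm_config()] with attributes `score` and `scores`
#'   (per-config results).
#' @export
loso_grid_search <- function(table, task = c("artifacts", "apnea"),
                             feats = ppg_feature_names()) {
  task <- match.arg(task)
  grid <- svm_grid(task)
  table <- canonical_order(table)
  subjects <- sort(unique(table$subject))
  if (length(subjects) < 2) {
    stop_neckppg("grid search needs >= 2 training subjects",
                 class = "neckppg_validation_error")
  }
  best <- NULL
  best_score <- -Inf
  scores <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- svm_config(grid$C[i], grid$gamma[i], task)
    preds <- loso_predictions(table, feats, cfg)
    score <- if (task == "artifacts") {
      mean(vapply(split(preds, preds$fold),
                  function(d) mean(d$pred == d$truth), numeric(1)))
    } else {
      # degenerate configs may predict one class only; score them 0 rather
      # than warn 100 times per search
      m <- suppressWarnings(compute_metrics(preds$truth, preds$pred))
      if (is.nan(m$F1)) 0 else m$F1
    }
    scores[i] <- score
    if (score > best_score) {
      best_score <- score
      best <- cfg
    }
  }
  if (is.null(best)) {
    stop_neckppg("grid search failed on all configurations",
                 class = "neckppg_search_error")
  }
  attr(best, "score") <- best_score
  attr(best, "scores") <- cbind(grid, score = scores)
  best
}

#' Leave-30%-of-subjects-out partition
#'
#' `round(0.30 * n)` subjects are drawn uniformly at random (seeded) for the
#' test side; all recordings of a subject travel together.
#'
#' @param subjects character vector of subject ids.
#' @param seed RNG seed.
#' @return list with `train_subjects`, `test_subjects`, `seed`.
#' @export
partition_leave_30pct_subjects <- function(subjects, seed) {
  subjects <- sort(unique(subjects))
  n <- length(subjects)
  if (n < 4) {
    stop_neckppg("need >= 4 subjects for a 70/30 subject split",
                 class = "neckppg_validation_error")
  }
  n_test <- round(0.30 * n)
  if (n_test < 1 || n_test >= n) {
    stop_neckppg("cannot leave %d of %d subjects out", n_test, n,
                 class = "neckppg_validation_error")
  }
  test <- with_seed(seed, sort(sample(subjects, n_test)))
  list(train_subjects = setdiff(subjects, test), test_subjects = test,
       seed = seed)
}

#' Leave-one-third-of-recording-out partition (apnea task)
#'
#' Each subject's breath-hold recording is split into three duration-equal
#' segments (assigned in [build_feature_table()], which also drops windows
#' straddling segment borders and balances classes within each segment);
#' repetition r assigns segment `(r mod 3) + 1` to the test side for every
#' subject.
#'
#' A subject whose held-out segment lacks a class (a breath-hold recording
#' whose episode geometry saturated one third) is dropped from both sides of
#' that repetition, leakage-safe, and reported in `dropped_subjects`; the
#' partition errors only when fewer than two subjects survive.
#'
#' @param table apnea feature table carrying a `segment` column.
#' @param repetition non-negative repetition index.
#' @return list with `train_idx`, `test_idx` (row indices into `table`),
#'   `test_segment`, `dropped_subjects`.
#' @export
partition_recording_thirds <- function(table, repetition) {
  stopifnot("segment" %in% names(table))
  test_segment <- (repetition %% 3) + 1
  dropped <- character(0)
  for (s in unique(table$subject)) {
    te <- table[table$subject == s & table$segment == test_segment, ,
                drop = FALSE]
    if (nrow(te) == 0 || length(unique(te$label)) < 2) dropped <- c(dropped, s)
  }
  keep <- !table$subject %in% dropped
  if (length(unique(table$subject[keep])) < 2) {
    stop_neckppg("test segment %d leaves fewer than 2 usable subjects (dropped: %s)",
                 test_segment, paste(dropped, collapse = ", "),
                 class = "neckppg_partition_error")
  }
  test_idx <- which(keep & table$segment == test_segment)
  train_idx <- which(keep & table$segment != test_segment)
  list(train_idx = train_idx, test_idx = test_idx,
       test_segment = test_segment, dropped_subjects = dropped)
}

#' Fit the full training pipeline on one training table
#'
#' Order of operations per repetition: (1) chi-square ranking on the training
#' data, (2) LOSO grid search at the top-30 base set, (3) forward sequential
#' selection at the chosen hyperparameters, (4) final re-fit on the whole
#' training table with the selected features.
#'
#' @param train_table balanced training feature table.
#' @param task `"artifacts"` or `"apnea"`.
#' @return list with `model` (`ppg_svm`), `config`, `selected` (feature
#'   names), `ranking`, `selection` (forward-selection audit).
#' @export
fit_pipeline <- function(train_table, task = c("artifacts", "apnea")) {
  task <- match.arg(task)
  ranking <- chi2_rank(train_table)
  base <- ranking$feature[1:30]
  cfg <- loso_grid_search(train_table, task, feats = base)
  sel <- forward_select(ranking, train_table, cfg)
  model <- train_svm_rbf(train_table[, sel$features, drop = FALSE],
                         train_table$label, cfg)
  list(model = model, config = cfg, selected = sel$features,
       ranking = ranking, selection = sel)
}

#' Serialize a trained model to JSON
#'
#' Stores the hyperparameters, selected features, standardization statistics
#' and support-vector data sufficient to reconstruct the decision function.
#'
#' @param bundle result of [fit_pipeline()] (or a list with `model`).
#' @param path destination JSON path.
#' @return `path`, invisibly.
#' @export
save_model_json <- function(bundle, path) {
  model <- bundle$model
  fit <- model$fit
  payload <- list(
    config = unclass(model$config),
    features = model$features,
    center = as.list(model$center),
    scale = as.list(model$scale),
    support = list(
      SV = apply(fit$SV, 1, as.numeric, simplify = FALSE),
      coefs = as.numeric(fit$coefs),
      rho = as.numeric(fit$rho),
      labels = as.integer(as.character(fit$levels))
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
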