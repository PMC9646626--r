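# Chi-square feature ranking and forward sequential selection, run on
# training folds only inside leave-one-subject-out cross-validation.

#' Chi-square ranking of the 51 features
#'
#' Each feature is discretized into (up to) 10 equal-frequency bins on the
#' training data; a chi-square test of independence between bin membership
#' and the binary label yields a p-value per feature. Features are ranked by
#' ascending p-value, ties broken by ascending feature index. A feature with
#' a single distinct value is uninformative and assigned p = 1.
#'
#' @param table balanced feature table from [build_feature_table()].
#' @return data.frame `feature`, `p_value`, `rank` (rank order, all 51 rows).
#' @export
chi2_rank <- function(table) {
  fcols <- ppg_feature_names()
  stopifnot(all(fcols %in% names(table)), "label" %in% names(table))
  y <- table$label
  p_values <- vapply(fcols, function(f) {
    x <- table[[f]]
    br <- unique(quantile(x, probs = seq(0, 1, length.out = 11), names = FALSE))
    if (length(br) < 3) return(1)
    bins <- cut(x, breaks = br, include.lowest = TRUE)
    tab <- table(bins, y)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) return(1)
    suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }, numeric(1))
  ord <- order(p_values, seq_along(fcols))
  data.frame(feature = fcols[ord], p_value = unname(p_values[ord]),
             rank = seq_along(fcols), stringsAsFactors = FALSE)
}

# LOSO misclassification error (1 - accuracy on concatenated predictions)
loso_error <- function(table, feats, cfg) {
  preds <- loso_predictions(table, feats, cfg)
  mean(preds$pred != preds$truth)
}

# concatenated LOSO predictions over subjects of `table`
loso_predictions <- function(table, feats, cfg) {
  subjects <- sort(unique(table$subject))
  if (length(subjects) < 2) {
    stop_neckppg("LOSO needs at least 2 subjects",
                 class = "neckppg_validation_error")
  }
  table <- canonical_order(table)
  pred <- integer(0); truth <- integer(0); fold <- character(0)
  for (s in subjects) {
    tr <- table[table$subject != s, , drop = FALSE]
    te <- table[table$subject == s, , drop = FALSE]
    if (length(unique(tr$label)) < 2 || nrow(te) == 0) next
    model <- train_svm_rbf(tr[, feats, drop = FALSE], tr$label, cfg)
    p <- predict(model, te[, feats, drop = FALSE])
    pred <- c(pred, p)
    truth <- c(truth, te$label)
    fold <- c(fold, rep(s, nrow(te)))
  }
  data.frame(pred = pred, truth = truth, fold = fold,
             stringsAsFactors = FALSE)
}

#' Forward sequential feature selection
#'
#' Starts from the top-30 chi-square-ranked features and considers the
#' remaining features in rank order, adding the next candidate and
#' recomputing the mean LOSO misclassification error at the supplied SVM
#' hyperparameters; the search stops at the first candidate whose relative
#' error decrease is below `tol`.
#'
#' @param ranking ranking from [chi2_rank()].
#' @param table balanced training feature table.
#' @param cfg [svm_config()] hyperparameters held fixed during the search.
#' @param base_size size of the ranked base set (default 30).
#' @param tol relative error-decrease tolerance (default 1e-6).
#' @return list with `features` (selected names, in rank order), `cv_error`
#'   (LOSO error of the accepted set) and `audit` (per-step log).
#' @export
forward_select <- function(ranking, table, cfg, base_size = 30, tol = 1e-6) {
  stopifnot(nrow(ranking) == 51)
  base <- ranking$feature[seq_len(min(base_size, nrow(ranking)))]
  candidates <- ranking$feature[-seq_len(min(base_size, nrow(ranking)))]
  current <- base
  err <- loso_error(table, current, cfg)
  audit <- data.frame(step = 0L, candidate = NA_character_,
                      cv_error_before = NA_real_, cv_error_after = err,
                      accepted = TRUE, stringsAsFactors = FALSE)
  step <- 0L
  for (cand in candidates) {
    step <- step + 1L
    err_new <- loso_error(table, c(current, cand), cfg)
    rel_dec <- if (err > 0) (err - err_new) / err else 0
    accept <- rel_dec >= tol
    audit <- rbind(audit, data.frame(
      step = step, candidate = cand, cv_error_before = err,
      cv_error_after = err_new, accepted = accept, stringsAsFactors = FALSE))
    if (!accept) break
    current <- c(current, cand)
    err <- err_new
  }
  list(features = current, cv_error = err, audit = audit)
}
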