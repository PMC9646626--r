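# RBF-SVM wrapper, LOSO grid search and the subject-safe partitions.

blob_data <- function(n = 100, sep = 6, seed = 1) {
  with_seed(seed, {
    X <- rbind(matrix(rnorm(n, 0, 1), n / 2, 2),
               matrix(rnorm(n, sep, 1), n / 2, 2))
    colnames(X) <- c("Amplitude", "Width")
    list(X = as.data.frame(X), y = rep(c(-1, 1), each = n / 2))
  })
}

test_that("separable blobs are fit perfectly and predictions are schema-aligned", {
  d <- blob_data()
  model <- train_svm_rbf(d$X, d$y, svm_config(1, 0.5, "artifacts"))
  expect_identical(predict(model, d$X), as.integer(d$y))
  # column order irrelevant
  expect_identical(predict(model, d$X[, c("Width", "Amplitude")]),
                   as.integer(d$y))
  expect_error(predict(model, d$X["Amplitude"]), class = "neckppg_schema_error")
  bad <- d$X; bad$Width[1] <- NaN
  expect_error(predict(model, bad), class = "neckppg_validation_error")
  expect_error(train_svm_rbf(d$X, rep(1, nrow(d$X)),
                             svm_config(1, 0.5, "artifacts")),
               class = "neckppg_validation_error")
})

test_that("RBF kernel solves XOR where a linear kernel cannot", {
  with_seed(2, {
    centers <- matrix(c(0, 0, 4, 4, 0, 4, 4, 0), 4, 2, byrow = TRUE)
    X <- centers[rep(1:4, each = 30), ] + matrix(rnorm(240, 0, 0.3), 120, 2)
  })
  colnames(X) <- c("Amplitude", "Width")
  y <- rep(c(-1, -1, 1, 1), each = 30)
  model <- train_svm_rbf(as.data.frame(X), y, svm_config(1, 2, "artifacts"))
  expect_identical(predict(model, as.data.frame(X)), as.integer(y))
  # independent baseline: linear kernel on the same standardized data
  Xs <- scale(X)
  lin <- e1071::svm(Xs, factor(y), type = "C-classification",
                    kernel = "linear", cost = 1, scale = FALSE)
  lin_acc <- mean(as.integer(as.character(predict(lin, Xs))) == y)
  expect_lt(lin_acc, 1)
})

test_that("duplicating the training set leaves the decision function unchanged", {
  d <- blob_data(n = 80, sep = 6, seed = 3)
  cfg <- svm_config(1, 0.5, "artifacts")
  m1 <- train_svm_rbf(d$X, d$y, cfg)
  m2 <- train_svm_rbf(rbind(d$X, d$X), c(d$y, d$y), cfg)
  probe <- expand.grid(Amplitude = seq(-2, 8, length.out = 15),
                       Width = seq(-2, 8, length.out = 15))
  # labels identical everywhere; decision values agree up to the small
  # standardization shift induced by the n-1 sd denominator on 2n points
  expect_identical(predict(m1, probe), predict(m2, probe))
  p1 <- sweep(sweep(as.matrix(probe), 2, m1$center), 2, m1$scale, "/")
  p2 <- sweep(sweep(as.matrix(probe), 2, m2$center), 2, m2$scale, "/")
  d1 <- attr(predict(m1$fit, p1, decision.values = TRUE), "decision.values")
  d2 <- attr(predict(m2$fit, p2, decision.values = TRUE), "decision.values")
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 0.05)
})

test_that("hyperparameter grids match the printed ladders", {
  ga <- svm_grid("artifacts")
  gp <- svm_grid("apnea")
  expect_identical(nrow(ga), 100L)
  expect_identical(nrow(gp), 100L)
  expect_setequal(unique(ga$C), c(0.5, 1, 4, 6, 8, 16, 32, 64, 80, 128))
  expect_setequal(unique(gp$C), c(0.125, 0.75, 1, 2, 3, 4, 5, 6, 8, 32))
  expect_setequal(unique(ga$gamma), 2^c(-15, -13, -11, -9, -7, -5, -3, -1, 1, 3))
})

test_that("grid search returns the first argmax in (C, gamma) order", {
  tbl <- noise_table(n = 160, n_subjects = 4, seed = 9)
  tbl$Amplitude <- tbl$label + with_seed(10, rnorm(160, 0, 0.5))
  cfg <- loso_grid_search(tbl, "artifacts", feats = c("Amplitude", "Width"))
  sc <- attr(cfg, "scores")
  best <- max(sc$score)
  expect_equal(attr(cfg, "score"), best)
  first <- sc[sc$score == best, ][1, ]
  expect_identical(cfg$C, first$C)
  expect_identical(cfg$gamma, first$gamma)
})

test_that("grid-search result is invariant to row order of the training table", {
  tbl <- noise_table(n = 120, n_subjects = 4, seed = 11)
  tbl$Amplitude <- tbl$label + with_seed(12, rnorm(120, 0, 0.5))
  cfg1 <- loso_grid_search(tbl, "artifacts", feats = c("Amplitude", "Width"))
  shuffled <- tbl[with_seed(13, sample(nrow(tbl))), ]
  cfg2 <- loso_grid_search(shuffled, "artifacts", feats = c("Amplitude", "Width"))
  expect_identical(cfg1$C, cfg2$C)
  expect_identical(cfg1$gamma, cfg2$gamma)
})

test_that("gamma ladder spans the underfit-to-interpolate kernel regimes", {
  d <- blob_data(n = 60, sep = 2.0, seed = 14)
  accs <- vapply(2^c(-15, -13, -11, -9, -7, -5, -3, -1, 1, 3), function(g) {
    m <- train_svm_rbf(d$X, d$y, svm_config(8, g, "artifacts"))
    mean(predict(m, d$X) == d$y)
  }, numeric(1))
  # flexibility grows along the ladder: the widest kernel fits worst,
  # the narrowest fits (near-)perfectly
  expect_gte(accs[10], max(accs[1:5]))
  expect_gte(accs[10], 0.95)
  # near-flat-kernel limit: the decision surface loses contrast, so the
  # widest kernel cannot beat the training fit of the narrowest
  expect_lte(accs[1], accs[10])
})

test_that("leave-30%-of-subjects-out: size, determinism, coverage", {
  subjects <- sprintf("sub%02d", 1:19)
  plan <- partition_leave_30pct_subjects(subjects, 1)
  expect_length(plan$test_subjects, 6)   # round(0.30 * 19)
  expect_length(plan$train_subjects, 13)
  expect_length(intersect(plan$train_subjects, plan$test_subjects), 0)
  expect_identical(plan, partition_leave_30pct_subjects(subjects, 1))

  seen <- character(0)
  for (s in 1:30) {
    seen <- c(seen, partition_leave_30pct_subjects(subjects, s)$test_subjects)
  }
  expect_setequal(unique(seen), subjects)  # everyone tested at least once
  expect_error(partition_leave_30pct_subjects(sprintf("s%d", 1:3), 1),
               class = "neckppg_validation_error")
})

test_that("thirds partition is leak-free, border-free and covers each segment once", {
  co <- small_cohort()
  ta <- build_feature_table(co, "apnea", 10, 0.5, seed = 3,
                            features = small_features_apnea_w10())
  segs_seen <- integer(0)
  for (r in 0:2) {
    plan <- partition_recording_thirds(ta, r)
    expect_length(intersect(plan$train_idx, plan$test_idx), 0)
    expect_identical(sort(c(plan$train_idx, plan$test_idx)),
                     seq_len(nrow(ta)))
    segs_seen <- c(segs_seen, plan$test_segment)
  }
  expect_setequal(segs_seen, 1:3)
  # no window straddles a third border (they were dropped at assembly)
  dur <- 140
  s <- ta$window_start; e <- s + 10
  crosses <- (s < dur / 3 & e > dur / 3) | (s < 2 * dur / 3 & e > 2 * dur / 3)
  expect_false(any(crosses))
})
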