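test_that("confusion-derived metrics match hand-computed values", {
  cm <- confusion(c(TRUE, TRUE, TRUE, TRUE, TRUE),
                  c(TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_identical(sensitivity(cm), 1)

  cm2 <- confusion(rep(c(TRUE, FALSE), c(4, 5)),
                   c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE,
                     FALSE))
  expect_identical(cm2$tp, 3L); expect_identical(cm2$fn, 1L)
  expect_identical(cm2$tn, 4L); expect_identical(cm2$fp, 1L)
  expect_identical(sensitivity(cm2), 0.75)
  expect_identical(specificity(cm2), 0.8)
  # F from precision 3/4 and recall 3/4
  expect_identical(f_measure(cm2), 0.75)

  # constant-negative predictions: sensitivity 0, specificity 1
  cm3 <- confusion(c(TRUE, TRUE, FALSE), c(FALSE, FALSE, FALSE))
  expect_identical(sensitivity(cm3), 0)
  expect_identical(specificity(cm3), 1)
  expect_error(f_measure(cm3), "precision")
  expect_error(sensitivity(confusion(logical(3), logical(3))),
               "no positive")
  expect_error(specificity(confusion(!logical(3), !logical(3))),
               "no negative")
  expect_error(confusion(c(TRUE, FALSE), TRUE), "length")
})

test_that("AUC equals the exhaustive pair-counting oracle with ties at 1/2", {
  y <- c(TRUE, TRUE, FALSE, FALSE)
  s <- c(0.9, 0.8, 0.8, 0.3)
  expect_identical(brute_auc(y, s), 0.875)
  expect_equal(roc_curve(y, s)$auc, 0.875, tolerance = 1e-15)
  expect_identical(roc_curve(c(TRUE, TRUE, FALSE), c(3, 2, 1))$auc, 1)
  set.seed(67)
  for (i in 1:100) {
    n <- sample(6:40, 1)
    yy <- c(TRUE, FALSE, stats::runif(n - 2) < 0.5)
    ss <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # many ties
    expect_equal(roc_curve(yy, ss)$auc, brute_auc(yy, ss),
                 tolerance = 1e-12)
  }
  expect_error(roc_curve(c(TRUE, TRUE), c(1, 2)), "both classes")
})

test_that("the ROC curve is monotone with unit endpoints and matches pROC", {
  set.seed(68)
  y <- stats::runif(80) < 0.4
  y[1:2] <- c(TRUE, FALSE)
  s <- stats::rnorm(80) + y
  roc <- roc_curve(y, s)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_identical(roc$points$fpr[1], 0)
  expect_identical(roc$points$tpr[1], 0)
  expect_identical(roc$points$fpr[nrow(roc$points)], 1)
  expect_identical(roc$points$tpr[nrow(roc$points)], 1)
  # independent implementation agreement
  proc_auc <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                             quiet = TRUE,
                                             direction = "<")))
  expect_equal(roc$auc, proc_auc, tolerance = 1e-12)
})

test_that("trapezoidal integration of the curve equals the pair statistic", {
  set.seed(70)
  for (i in 1:100) {
    n <- sample(8:60, 1)
    y <- c(TRUE, FALSE, stats::runif(n - 2) < 0.5)
    s <- round(stats::rnorm(n), sample(0:2, 1))  # induce ties
    roc <- roc_curve(y, s)
    trap <- sum(diff(roc$points$fpr) *
                  (utils::head(roc$points$tpr, -1) +
                     utils::tail(roc$points$tpr, -1)) / 2)
    expect_equal(trap, roc$auc, tolerance = 1e-12)
  }
})

test_that("AUC is complementary under score negation and rank-invariant", {
  set.seed(71)
  y <- stats::runif(50) < 0.5
  y[1:2] <- c(TRUE, FALSE)
  s <- stats::rnorm(50)  # continuous: tie-free almost surely
  expect_equal(roc_curve(y, s)$auc + roc_curve(y, -s)$auc, 1,
               tolerance = 1e-12)
  expect_equal(roc_curve(y, exp(2 * s))$auc, roc_curve(y, s)$auc,
               tolerance = 1e-12)
})

test_that("label-independent scores give AUC near one half", {
  set.seed(72)
  aucs <- replicate(2000, {
    y <- c(TRUE, FALSE, stats::runif(18) < 0.5)
    .s <- stats::runif(20)
    roc_curve(y, .s)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("the learner benchmark is paired, deterministic and sane", {
  tab <- generate_feature_table(160, 2, 2, imbalance = 0.5,
                                effect_size = 4, seed = 14)
  bench <- benchmark_learners(tab$X, tab$y, folds = 4, seed = 5)
  expect_setequal(bench$family, c("knn", "svm", "mlp", "random_forest",
                                  "gradient_boosting"))
  expect_true(all(bench$mean_auc > 0.9))
  # shuffled labels: no learner should beat chance by much
  set.seed(15)
  y_shuf <- sample(tab$y)
  bench_null <- benchmark_learners(tab$X, y_shuf, folds = 4, seed = 5)
  expect_true(all(abs(bench_null$mean_auc - 0.5) < 0.2))
  bench2 <- benchmark_learners(tab$X, tab$y, folds = 4, seed = 5)
  expect_identical(bench, bench2)
  expect_error(benchmark_learners(tab$X, tab$y,
                                  families = "deep_transformer"),
               "arg")
})

test_that("model evaluation reports per-target metrics with gated scoring", {
  sc <- generate_corpus(generator_spec(n = 200, seed = 51))
  sp <- split_corpus(sc$corpus, 0.7, seed = 1)
  train_labels <- sc$labels[sc$labels$message_id %in% sp$train$id, ]
  fit <- hrqol_train(sp$train, train_labels, fixture_lexicons(),
                     hrqol_control(grid = list(learning_rate = 0.3,
                                               n_rounds = 50L,
                                               n_trees_max_depth = 3L),
                                   max_features = 4L),
                     seed = 7)
  ev <- evaluate_model(fit, sp$validation, sc$labels)
  expect_setequal(names(ev), c("impact", qol_dimensions()))
  for (t in names(ev)) {
    e <- ev[[t]]
    n_eval <- e$cm$tp + e$cm$fp + e$cm$tn + e$cm$fn
    expect_identical(n_eval, nrow(sp$validation))
    if (!is.na(e$sensitivity)) {
      expect_true(e$sensitivity >= 0 && e$sensitivity <= 1)
    }
    if (!is.na(e$specificity)) {
      expect_true(e$specificity >= 0 && e$specificity <= 1)
    }
  }
  expect_gte(ev$impact$roc$auc, 0.85)
  # report files
  dir <- withr::local_tempdir()
  write_evaluation(ev, dir)
  metrics <- utils::read.csv(file.path(dir, "metrics.csv"))
  expect_identical(nrow(metrics), 6L)
  expect_true(file.exists(file.path(dir, "roc_impact.csv")))
  expect_error(evaluate_model(fit, tiny_corpus("hors sujet"), sc$labels),
               "no overlap")
})
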