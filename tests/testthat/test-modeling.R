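test_that("SMOTE balances classes while preserving originals verbatim", {
  set.seed(2)
  X <- matrix(stats::runif(12 * 3), 12, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- c(rep(1, 3), rep(0, 9))
  out <- smote_oversample(X, y, k = 2, seed = 5)
  expect_identical(sum(out$y == 1), sum(out$y == 0))
  expect_identical(sum(out$y == 0), 9L)
  expect_identical(out$X[1:12, ], X)
  expect_identical(out$y[1:12], as.integer(y))
  expect_identical(which(out$synthetic), 13:18)
  # determinism
  out2 <- smote_oversample(X, y, k = 2, seed = 5)
  expect_identical(out$X, out2$X)
})

test_that("SMOTE leaves balanced data unchanged and rejects singletons", {
  X <- matrix(stats::rnorm(8), 4, 2)
  y <- c(0, 0, 1, 1)
  out <- smote_oversample(X, y, seed = 1)
  expect_identical(out$X, X)
  expect_false(any(out$synthetic))
  expect_error(smote_oversample(matrix(0, 4, 2), c(1, 0, 0, 0), seed = 1),
               "at least 2")
  expect_warning(smote_oversample(matrix(stats::rnorm(12), 6, 2),
                                  c(1, 1, 0, 0, 0, 0), k = 5, seed = 1),
                 "reduced")
})

test_that("every synthetic point lies on a minority-pair segment", {
  # 5-point minority in 2D, checked against all 10 pairwise segments
  set.seed(9)
  Xmin <- matrix(stats::runif(10), 5, 2)
  Xmaj <- matrix(stats::runif(30) + 3, 15, 2)
  X <- rbind(Xmin, Xmaj)
  y <- c(rep(1, 5), rep(0, 15))
  out <- smote_oversample(X, y, k = 3, seed = 11)
  synth <- out$X[out$synthetic, , drop = FALSE]
  on_some_segment <- function(p) {
    for (i in 1:4) for (j in (i + 1):5) {
      a <- Xmin[i, ]; b <- Xmin[j, ]
      d <- b - a
      if (sum(d^2) < 1e-300) next
      t <- sum((p - a) * d) / sum(d^2)
      if (t >= -1e-9 && t <= 1 + 1e-9 &&
          sqrt(sum((p - (a + t * d))^2)) < 1e-9) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(synth, 1, on_some_segment)))
})

test_that("SFFS finds a perfectly separating feature first", {
  set.seed(3)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  X <- matrix(stats::rnorm(n * 6), n, 6)
  colnames(X) <- c(paste0("noise", 1:5), "signal")
  X[, "signal"] <- y + stats::runif(n, 0, 0.2)  # separates perfectly
  # oracle: the signal feature is the unique single-feature AUC maximizer
  single_aucs <- vapply(colnames(X), function(f) brute_auc(y, X[, f]),
                        numeric(1))
  expect_identical(names(which.max(single_aucs)), "signal")
  sel <- sffs_select(X, y, folds = 5, seed = 1)
  expect_identical(sel$trajectory$feature[1], "signal")
  expect_true("signal" %in% sel$selected)
})

test_that("SFFS trajectories are non-decreasing and handle edge cases", {
  tab <- generate_feature_table(150, 1, 4, imbalance = 0.4,
                                effect_size = 2, seed = 8)
  sel <- sffs_select(tab$X, tab$y, folds = 5, seed = 2)
  expect_true(all(diff(sel$trajectory$score) >= 0))
  expect_true(all(sel$selected %in% colnames(tab$X)))
  # a single candidate feature is simply returned
  one <- sffs_select(tab$X[, 1, drop = FALSE], tab$y, folds = 5, seed = 2)
  expect_identical(one$selected, "inf1")
  expect_error(sffs_select(tab$X, rep(1, nrow(tab$X)), seed = 1),
               "single class|degenerate")
})

test_that("SFFS ignores appended zero-variance features", {
  tab <- generate_feature_table(150, 2, 3, imbalance = 0.5,
                                effect_size = 2, seed = 12)
  sel_base <- sffs_select(tab$X, tab$y, folds = 5, seed = 4)
  Xplus <- cbind(tab$X, const1 = 0, const2 = 1)
  sel_plus <- sffs_select(Xplus, tab$y, folds = 5, seed = 4)
  expect_identical(sel_plus$selected, sel_base$selected)
})

test_that("grid search is exhaustive, tie-broken by order, deterministic", {
  tab <- generate_feature_table(120, 2, 1, imbalance = 0.5,
                                effect_size = 3, seed = 6)
  single <- grid_search(tab$X, tab$y,
                        grid = list(learning_rate = 0.1, n_rounds = 30L),
                        folds = 4, seed = 3)
  expect_identical(single$best$learning_rate, 0.1)
  expect_identical(nrow(single$cv_table), 1L)

  g <- grid_search(tab$X, tab$y,
                   grid = list(n_rounds = c(10L, 40L),
                               n_trees_max_depth = c(2L, 3L)),
                   folds = 4, seed = 3)
  expect_identical(nrow(g$cv_table), 4L)
  expect_identical(g$best_score, max(g$cv_table$mean_auc))
  g2 <- grid_search(tab$X, tab$y,
                    grid = list(n_rounds = c(10L, 40L),
                                n_trees_max_depth = c(2L, 3L)),
                    folds = 4, seed = 3)
  expect_identical(g$cv_table, g2$cv_table)
  expect_error(grid_search(tab$X, tab$y, grid = list(bogus = 1), seed = 1),
               "unknown hyperparameter")
})

small_control <- function() {
  hrqol_control(grid = list(learning_rate = 0.3, n_rounds = 50L,
                            n_trees_max_depth = c(2L, 3L)),
                max_features = 4L)
}

test_that("hierarchical training selects each dimension's lexical feature", {
  sc <- generate_corpus(generator_spec(n = 220, seed = 41))
  fit <- hrqol_train(sc$corpus, sc$labels, fixture_lexicons(),
                     small_control(), seed = 6)
  for (d in qol_dimensions()) {
    st <- fit$dimensions[[d]]
    expect_false(isTRUE(st$untrainable))
    expect_true(paste0("lex_", d) %in% st$features)
  }
  expect_gte(fit$impact$tuning$best_score, 0.9)
})

test_that("a dimension without positive labels degrades to fixed-false", {
  sc <- generate_corpus(generator_spec(n = 120, seed = 43))
  labels <- sc$labels
  labels$financial <- FALSE
  expect_warning(
    fit <- hrqol_train(sc$corpus, labels, fixture_lexicons(),
                       small_control(), seed = 2),
    "financial")
  expect_true(fit$dimensions$financial$untrainable)
  expect_false(fit$dimensions$physical$untrainable)
  preds <- predict(fit, sc$corpus)
  expect_false(any(preds$financial_flag))
  expect_true(all(is.na(preds$financial_prob)))
})

test_that("predictions honor the gating invariant and empty corpora", {
  sc <- generate_corpus(generator_spec(n = 150, seed = 45))
  fit <- hrqol_train(sc$corpus, sc$labels, fixture_lexicons(),
                     small_control(), seed = 3)
  preds <- predict(fit, sc$corpus)
  dims_flag <- as.matrix(preds[paste0(qol_dimensions(), "_flag")])
  dims_prob <- as.matrix(preds[paste0(qol_dimensions(), "_prob")])
  gated <- !preds$impact_flag
  expect_false(any(dims_flag[gated, ]))
  expect_true(all(is.na(dims_prob[gated, ])))
  expect_true(all(preds$impact_prob >= 0 & preds$impact_prob <= 1))
  # high-signal message packed with physical vocabulary is caught
  packed <- tiny_corpus(paste("je vis avec douleur et mal au dos.",
                              "fatigue intense et douleur encore."))
  pp <- predict(fit, packed)
  expect_true(pp$impact_flag)
  expect_true(pp$physical_flag)
  empty <- tiny_corpus(character(0))
  expect_identical(nrow(predict(fit, empty)), 0L)
})

test_that("training and prediction are deterministic given the seed", {
  sc <- generate_corpus(generator_spec(n = 120, seed = 47))
  f1 <- hrqol_train(sc$corpus, sc$labels, fixture_lexicons(),
                    small_control(), seed = 9)
  f2 <- hrqol_train(sc$corpus, sc$labels, fixture_lexicons(),
                    small_control(), seed = 9)
  expect_identical(f1$impact$features, f2$impact$features)
  expect_identical(f1$impact$tuning$best, f2$impact$tuning$best)
  p1 <- predict(f1, sc$corpus)
  p2 <- predict(f2, sc$corpus)
  expect_identical(p1, p2)
})

test_that("models round-trip through directory serialization", {
  sc <- generate_corpus(generator_spec(n = 100, seed = 49))
  fit <- hrqol_train(sc$corpus, sc$labels, fixture_lexicons(),
                     small_control(), seed = 4)
  dir <- withr::local_tempdir()
  save_hrqol_model(fit, dir)
  expect_true(file.exists(file.path(dir, "model.json")))
  meta <- jsonlite::fromJSON(file.path(dir, "model.json"))
  expect_identical(meta$feature_inventory, feature_inventory())
  loaded <- load_hrqol_model(dir)
  expect_identical(predict(loaded, sc$corpus), predict(fit, sc$corpus))
})
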