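#' Specify a learner
#'
#' The five learner families compared by the pipeline. Hyperparameter names
#' for `gradient_boosting` follow the boosting vocabulary:
#' `learning_rate`, `n_rounds`, `n_trees_max_depth`, `min_child_weight`,
#' `min_split_loss`, `l1_regularization`.
#'
#' @param family one of `"knn"`, `"svm"`, `"mlp"`, `"random_forest"`,
#'   `"gradient_boosting"`.
#' @param ... hyperparameters (name = value).
#' @return An object of class `qol_learner_spec`.
#' @export
learner_spec <- function(family = c("gradient_boosting", "knn", "svm", "mlp",
                                    "random_forest"), ...) {
  family <- match.arg(family)
  hp <- list(...)
  known <- .learner_hyperparameters(family)
  bad <- setdiff(names(hp), known)
  if (length(bad)) {
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(family = family, hyperparameters = hp),
            class = "qol_learner_spec")
}

.learner_hyperparameters <- function(family) {
  switch(family,
    knn = c("k"),
    svm = c("cost", "gamma", "kernel"),
    mlp = c("size", "decay", "maxit"),
    random_forest = c("n_trees", "mtry"),
    gradient_boosting = c("learning_rate", "n_rounds", "n_trees_max_depth",
                          "min_child_weight", "min_split_loss",
                          "l1_regularization"))
}

#' @export
print.qol_learner_spec <- function(x, ...) {
  hp <- if (length(x$hyperparameters)) {
    paste(names(x$hyperparameters), unlist(x$hyperparameters), sep = "=",
          collapse = ", ")
  } else "defaults"
  cat(sprintf("<qol_learner_spec> %s (%s)\n", x$family, hp))
  invisible(x)
}

# Fit one learner on a numeric matrix. All stochastic learners are seeded
# locally so a fit is a pure function of (X, y, spec, seed).
.fit_learner <- function(spec, X, y, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  hp <- spec$hyperparameters
  get <- function(nm, default) if (!is.null(hp[[nm]])) hp[[nm]] else default
  fit <- switch(spec$family,
    knn = list(train_x = X, train_y = y, k = get("k", 5L)),
    svm = {
      set.seed(seed)
      e1071::svm(X, factor(y, levels = c(0, 1)),
                 kernel = get("kernel", "radial"),
                 cost = get("cost", 1), gamma = get("gamma", 1 / ncol(X)),
                 probability = TRUE, scale = FALSE)
    },
    mlp = {
      set.seed(seed)
      nnet::nnet(X, y, size = get("size", 5L), decay = get("decay", 1e-3),
                 maxit = get("maxit", 200L), entropy = TRUE, trace = FALSE)
    },
    random_forest = {
      set.seed(seed)
      randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                 ntree = get("n_trees", 300L),
                                 mtry = get("mtry",
                                            max(1, floor(sqrt(ncol(X))))))
    },
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      params <- list(objective = "binary:logistic",
                     eta = get("learning_rate", 0.1),
                     max_depth = get("n_trees_max_depth", 4L),
                     min_child_weight = get("min_child_weight", 1),
                     gamma = get("min_split_loss", 0),
                     alpha = get("l1_regularization", 0),
                     nthread = 1, seed = seed)
      xgboost::xgb.train(params = params, data = dtrain,
                         nrounds = get("n_rounds", 100L), verbose = 0)
    })
  structure(list(family = spec$family, fit = fit, spec = spec,
                 features = colnames(X)),
            class = "qol_fitted_learner")
}

# Positive-class probability for new rows.
.predict_learner <- function(model, X) {
  X <- as.matrix(X)
  switch(model$family,
    knn = {
      k <- model$fit$k
      pred <- class::knn(model$fit$train_x, X,
                         factor(model$fit$train_y, levels = c(0, 1)),
                         k = k, prob = TRUE, use.all = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    },
    svm = {
      p <- attr(stats::predict(model$fit, X, probability = TRUE),
                "probabilities")
      as.numeric(p[, "1"])
    },
    mlp = as.numeric(stats::predict(model$fit, X)),
    random_forest = as.numeric(
      stats::predict(model$fit, X, type = "prob")[, "1"]),
    gradient_boosting = as.numeric(
      stats::predict(model$fit, xgboost::xgb.DMatrix(X))))
}
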