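#' The documented default boosting hyperparameter grid
#'
#' The grid swept by the per-model grid search: learning rate, number of
#' boosting rounds, maximum tree depth, minimum child weight, minimum
#' split loss and L1 regularization.
#'
#' @return Named list of value vectors.
#' @export
default_boosting_grid <- function() {
  list(learning_rate = c(0.05, 0.1, 0.3),
       n_rounds = c(50L, 100L, 200L),
       n_trees_max_depth = c(2L, 4L, 6L),
       min_child_weight = c(1, 5),
       min_split_loss = c(0, 1),
       l1_regularization = c(0, 0.5))
}

#' Training configuration for the hierarchical model
#'
#' @param learner_family family used for the final models (and, unless
#'   overridden, for SFFS scoring); boosting by default.
#' @param grid hyperparameter grid for the per-model grid search.
#' @param folds number of stratified CV folds used everywhere.
#' @param smote_dimensions dimensions whose training data is rebalanced
#'   with SMOTE (inside CV training folds and before the final fit);
#'   default the three rare dimensions: activity, relational, financial.
#' @param smote_k SMOTE neighbor count (reduced automatically when the
#'   minority is tiny).
#' @param max_features cap on the SFFS selected-set size per model.
#' @param threshold decision threshold turning the stage-1 impact
#'   probability into a flag, in (0, 1).
#' @param stage2_on_impacted train each dimension model on the
#'   impact-labeled training messages only (matching the prediction-time
#'   gating), rather than on all training messages.
#' @param sffs_learner learner used to score SFFS candidates (a fast
#'   boosting configuration by default).
#' @return A list of class `hrqol_control`.
#' @export
hrqol_control <- function(learner_family = "gradient_boosting",
                          grid = default_boosting_grid(),
                          folds = 5L,
                          smote_dimensions = c("activity", "relational",
                                               "financial"),
                          smote_k = 5L,
                          max_features = 10L,
                          threshold = 0.5,
                          stage2_on_impacted = TRUE,
                          sffs_learner = learner_spec("gradient_boosting",
                                                      n_rounds = 60L,
                                                      n_trees_max_depth = 3L,
                                                      learning_rate = 0.3)) {
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly in (0, 1)", call. = FALSE)
  }
  stopifnot(all(smote_dimensions %in% qol_dimensions()))
  structure(list(learner_family = learner_family, grid = grid,
                 folds = as.integer(folds),
                 smote_dimensions = smote_dimensions,
                 smote_k = as.integer(smote_k),
                 max_features = max_features, threshold = threshold,
                 stage2_on_impacted = stage2_on_impacted,
                 sffs_learner = sffs_learner),
            class = "hrqol_control")
}

# Select features, tune and fit one binary model. Returns NULL-free list or
# the marker list(untrainable = TRUE) when y has no positive example.
.train_stage <- function(Xn, y, control, seed, smote, label) {
  if (sum(y) == 0 || sum(!y) == 0) {
    warning("model `", label, "` is untrainable (single-class labels); ",
            "its predictions are fixed to FALSE", call. = FALSE)
    return(list(untrainable = TRUE, label = label))
  }
  sel <- sffs_select(Xn, y, learner = control$sffs_learner,
                     folds = control$folds, seed = seed,
                     max_features = control$max_features,
                     smote = smote, smote_k = control$smote_k)
  gs <- grid_search(Xn[, sel$selected, drop = FALSE], y,
                    family = control$learner_family, grid = control$grid,
                    folds = control$folds, seed = seed,
                    smote = smote, smote_k = control$smote_k)
  Xfit <- as.matrix(Xn[, sel$selected, drop = FALSE])
  yfit <- as.integer(y)
  if (smote) {
    n_min <- min(sum(yfit == 1), sum(yfit == 0))
    if (n_min >= 2) {
      bal <- smote_oversample(Xfit, yfit,
                              k = max(1L, min(control$smote_k, n_min - 1L)),
                              seed = seed)
      Xfit <- bal$X; yfit <- bal$y
    }
  }
  spec <- do.call(learner_spec,
                  c(list(family = control$learner_family), gs$best))
  fit <- .fit_learner(spec, Xfit, yfit, seed = seed)
  list(untrainable = FALSE, label = label, fit = fit,
       features = sel$selected, selection = sel, tuning = gs,
       smote = smote)
}

#' Train the hierarchical HRQoL impact model
#'
#' The full modeling pipeline on a training corpus: feature extraction,
#' normalization fitting (training rows only), then for the stage-1 impact
#' model and each of the five stage-2 dimension models: SFFS feature
#' selection scored by stratified cross-validated AUC, grid-search
#' hyperparameter tuning, and a final fit. SMOTE rebalancing is applied to
#' the configured rare dimensions, inside CV training folds only and on the
#' final training set. Stage-2 models train, by default, on the
#' impact-labeled subset of the training messages, matching the
#' prediction-time gating. Fully deterministic given
#' `(corpus, labels, lexicons, control, seed)`.
#'
#' @param corpus training [qol_corpus] (normalized texts).
#' @param labels gold label table covering the corpus (see
#'   [read_labels()]).
#' @param lexicons complete [lexicon_set].
#' @param control a [hrqol_control].
#' @param tagger morphology tagger, default [french_tagger()].
#' @param seed integer seed driving every stochastic step.
#' @return An object of class `hrqol_model`.
#' @export
hrqol_train <- function(corpus, labels, lexicons,
                        control = hrqol_control(),
                        tagger = french_tagger(), seed = 1L) {
  seed <- as.integer(seed)
  check <- validate_labels(labels, corpus)
  if (!check$ok) {
    stop("label table fails validation (", check$n_violations,
         " violations); see validate_labels()", call. = FALSE)
  }
  labels <- labels[match(corpus$id, labels$message_id), , drop = FALSE]
  if (anyNA(labels$message_id)) {
    stop("labels missing for some corpus messages", call. = FALSE)
  }
  feats <- extract_features(corpus, lexicons, tagger)
  norm <- fit_normalization(feats)
  Xn <- apply_normalization(feats, norm)
  Xmat <- as.matrix(Xn[, feature_inventory(), drop = FALSE])
  impact <- .train_stage(Xmat, labels$impact, control, seed,
                         smote = FALSE, label = "impact")
  sub <- if (control$stage2_on_impacted) which(labels$impact) else
    seq_len(nrow(labels))
  dim_models <- lapply(qol_dimensions(), function(d) {
    .train_stage(Xmat[sub, , drop = FALSE], labels[[d]][sub], control,
                 seed = seed + match(d, qol_dimensions()),
                 smote = d %in% control$smote_dimensions, label = d)
  })
  names(dim_models) <- qol_dimensions()
  structure(list(impact = impact, dimensions = dim_models,
                 normalization = norm, threshold = control$threshold,
                 control = control, lexicons = lexicons, tagger = tagger,
                 feature_inventory = feature_inventory(), seed = seed,
                 n_train = nrow(corpus)),
            class = "hrqol_model")
}

#' @export
print.hrqol_model <- function(x, ...) {
  cat(sprintf("<hrqol_model> two-stage gated classifier (%s), %d training messages, seed %d\n",
              x$control$learner_family, x$n_train, x$seed))
  stage_line <- function(st) {
    if (isTRUE(st$untrainable)) {
      sprintf("  %-10s untrainable (no positive labels)\n", st$label)
    } else {
      sprintf("  %-10s %2d features, CV AUC %.3f%s\n", st$label,
              length(st$features), st$tuning$best_score,
              if (isTRUE(st$smote)) " (SMOTE)" else "")
    }
  }
  cat(stage_line(x$impact))
  for (d in qol_dimensions()) cat(stage_line(x$dimensions[[d]]))
  cat(sprintf("  decision threshold %.2f\n", x$threshold))
  invisible(x)
}

#' @export
summary.hrqol_model <- function(object, ...) {
  rows <- lapply(c(list(object$impact), object$dimensions), function(st) {
    if (isTRUE(st$untrainable)) {
      data.frame(target = st$label, trainable = FALSE, n_features = 0L,
                 cv_auc = NA_real_, features = "",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(target = st$label, trainable = TRUE,
                 n_features = length(st$features),
                 cv_auc = st$tuning$best_score,
                 features = paste(st$features, collapse = ", "),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.hrqol_model", "data.frame")
  out
}

#' @export
print.summary.hrqol_model <- function(x, ...) {
  cat("Hierarchical HRQoL model summary\n")
  for (i in seq_len(nrow(x))) {
    if (!x$trainable[i]) {
      cat(sprintf("  %-10s untrainable\n", x$target[i]))
    } else {
      cat(sprintf("  %-10s CV AUC %.3f | %s\n", x$target[i], x$cv_auc[i],
                  x$features[i]))
    }
  }
  invisible(x)
}

#' Predict HRQoL impacts for a corpus
#'
#' Stage 1 scores every message for the presence of an impact; messages at
#' or above the decision threshold are flagged and passed to the five
#' stage-2 dimension models. Unflagged messages carry no dimension
#' probability (`NA`) and all-false dimension flags (the gating
#' invariant).
#'
#' @param object a fitted [hrqol_train()] model.
#' @param corpus a [qol_corpus] with normalized texts.
#' @param ... unused.
#' @return A data frame of class `hrqol_predictions`: `message_id`,
#'   `impact_prob`, `impact_flag`, then `<dimension>_prob` and
#'   `<dimension>_flag` for the five dimensions.
#' @export
predict.hrqol_model <- function(object, corpus, ...) {
  dims <- qol_dimensions()
  if (nrow(corpus) == 0) {
    out <- data.frame(message_id = character(0), impact_prob = numeric(0),
                      impact_flag = logical(0), stringsAsFactors = FALSE)
    for (d in dims) {
      out[[paste0(d, "_prob")]] <- numeric(0)
      out[[paste0(d, "_flag")]] <- logical(0)
    }
    class(out) <- c("hrqol_predictions", "data.frame")
    return(out)
  }
  feats <- extract_features(corpus, object$lexicons, object$tagger)
  if (!identical(setdiff(names(feats), "message_id"),
                 object$feature_inventory)) {
    stop("feature inventory mismatch between model and extractor",
         call. = FALSE)
  }
  Xn <- apply_normalization(feats, object$normalization)
  Xmat <- as.matrix(Xn[, object$feature_inventory, drop = FALSE])
  p_imp <- .predict_learner(object$impact$fit,
                            Xmat[, object$impact$features, drop = FALSE])
  flag <- p_imp >= object$threshold
  out <- data.frame(message_id = corpus$id, impact_prob = p_imp,
                    impact_flag = flag, stringsAsFactors = FALSE)
  for (d in dims) {
    st <- object$dimensions[[d]]
    prob <- rep(NA_real_, nrow(corpus))
    dflag <- rep(FALSE, nrow(corpus))
    if (!isTRUE(st$untrainable) && any(flag)) {
      p <- .predict_learner(st$fit,
                            Xmat[flag, st$features, drop = FALSE])
      prob[flag] <- p
      dflag[flag] <- p >= object$threshold
    }
    out[[paste0(d, "_prob")]] <- prob
    out[[paste0(d, "_flag")]] <- dflag
  }
  rownames(out) <- NULL
  class(out) <- c("hrqol_predictions", "data.frame")
  out
}

#' Write predictions to CSV
#'
#' Probabilities are serialized with full precision; gated-out dimension
#' probabilities are empty fields.
#'
#' @param predictions an `hrqol_predictions` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  out <- as.data.frame(predictions)
  for (cl in names(out)) {
    if (is.numeric(out[[cl]])) out[[cl]] <- sprintf("%.12g", out[[cl]])
    if (is.logical(out[[cl]])) out[[cl]] <- as.integer(out[[cl]])
  }
  for (cl in grep("_prob$", names(out), value = TRUE)) {
    out[[cl]][out[[cl]] == "NA"] <- ""
  }
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
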