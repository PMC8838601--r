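#' Confusion matrix of a binary prediction
#'
#' @param y_true,y_pred logical vectors of equal length.
#' @return An object of class `qol_confusion`: list with `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- as.logical(y_true); y_pred <- as.logical(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have the same length", call. = FALSE)
  }
  structure(list(tp = sum(y_true & y_pred), fp = sum(!y_true & y_pred),
                 tn = sum(!y_true & !y_pred), fn = sum(y_true & !y_pred)),
            class = "qol_confusion")
}

#' @export
print.qol_confusion <- function(x, ...) {
  cat(sprintf("<qol_confusion> tp=%d fp=%d tn=%d fn=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Sensitivity (true positive rate)
#'
#' `tp / (tp + fn)`: the probability of flagging a message that truly
#' mentions an impact.
#'
#' @param cm a [confusion] matrix.
#' @return Sensitivity in \[0, 1\].
#' @export
sensitivity <- function(cm) {
  if (cm$tp + cm$fn == 0) {
    stop("sensitivity undefined: no positive examples", call. = FALSE)
  }
  cm$tp / (cm$tp + cm$fn)
}

#' Specificity (true negative rate)
#'
#' `tn / (tn + fp)`: the probability of clearing a message that truly
#' mentions no impact.
#'
#' @param cm a [confusion] matrix.
#' @return Specificity in \[0, 1\].
#' @export
specificity <- function(cm) {
  if (cm$tn + cm$fp == 0) {
    stop("specificity undefined: no negative examples", call. = FALSE)
  }
  cm$tn / (cm$tn + cm$fp)
}

#' F-measure
#'
#' Harmonic mean of precision (`tp / (tp + fp)`) and recall
#' (`tp / (tp + fn)`).
#'
#' @param cm a [confusion] matrix.
#' @return F-measure in \[0, 1\].
#' @export
f_measure <- function(cm) {
  if (cm$tp + cm$fp == 0) {
    stop("f_measure undefined: precision has a zero denominator",
         call. = FALSE)
  }
  if (cm$tp + cm$fn == 0) {
    stop("f_measure undefined: recall has a zero denominator",
         call. = FALSE)
  }
  precision <- cm$tp / (cm$tp + cm$fp)
  recall <- cm$tp / (cm$tp + cm$fn)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the distinct scores and records
#' (false positive rate, true positive rate) at each; the curve starts at
#' (0, 0) and ends at (1, 1). The AUC equals the Mann-Whitney pair
#' statistic — the probability that a random positive scores above a
#' random negative, ties counted 1/2 — and the trapezoidal integral of the
#' curve agrees with it.
#'
#' @param y_true logical labels (both classes must be present).
#' @param scores numeric scores, higher meaning more likely positive.
#' @return An object of class `qol_roc`: list with `points` (data frame
#'   `fpr`, `tpr`, `threshold`, sorted by increasing fpr/tpr) and `auc`.
#' @export
roc_curve <- function(y_true, scores) {
  y_true <- as.logical(y_true)
  if (length(y_true) != length(scores)) {
    stop("`y_true` and `scores` must have the same length", call. = FALSE)
  }
  n1 <- sum(y_true); n0 <- sum(!y_true)
  if (n1 == 0 || n0 == 0) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(y_true & scores >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(!y_true & scores >= t) / n0, numeric(1))
  points <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                       threshold = c(Inf, thr))
  if (points$fpr[nrow(points)] < 1 || points$tpr[nrow(points)] < 1) {
    points <- rbind(points, data.frame(fpr = 1, tpr = 1, threshold = -Inf))
  }
  structure(list(points = points, auc = .auc(y_true, scores)),
            class = "qol_roc")
}

#' @export
print.qol_roc <- function(x, ...) {
  cat(sprintf("<qol_roc> AUC %.4f (%d points)\n", x$auc, nrow(x$points)))
  invisible(x)
}

#' @export
plot.qol_roc <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "False positive rate (1 - specificity)",
                 ylab = "True positive rate (sensitivity)",
                 main = sprintf("ROC curve (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Compare the five learner families by cross-validated AUC
#'
#' Evaluates every family with the same stratified folds (a paired
#' comparison) and default hyperparameters unless a full [learner_spec()]
#' is given.
#'
#' @param X numeric matrix or data frame of features.
#' @param y binary labels.
#' @param families character vector of family names, or a list of
#'   [learner_spec()] objects.
#' @param folds number of stratified CV folds.
#' @param seed integer seed.
#' @return A data frame of class `qol_benchmark`: one row per family with
#'   the per-fold and mean AUC.
#' @export
benchmark_learners <- function(X, y,
                               families = c("knn", "svm", "mlp",
                                            "random_forest",
                                            "gradient_boosting"),
                               folds = 5L, seed = 1L) {
  specs <- if (is.character(families)) {
    lapply(families, learner_spec)
  } else families
  fold_id <- make_stratified_folds(y, folds, seed)
  rows <- lapply(specs, function(spec) {
    cv <- .cv_auc(X, y, spec, fold_id, seed = seed)
    data.frame(family = spec$family, mean_auc = cv$mean,
               t(stats::setNames(cv$folds,
                                 paste0("fold", seq_along(cv$folds)))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("qol_benchmark", "data.frame")
  out
}

#' Evaluate a hierarchical model against gold labels
#'
#' Computes, for the overall impact and each of the five dimensions, the
#' confusion matrix, sensitivity, specificity, F-measure and ROC/AUC over
#' all labeled messages. Messages gated out by stage 1 count as negative
#' dimension predictions with score 0, reflecting end-to-end behavior.
#' Metrics whose denominator is zero (e.g. a dimension with no positive
#' validation labels) are reported as `NA`.
#'
#' @param model a fitted [hrqol_train()] model.
#' @param corpus evaluation [qol_corpus].
#' @param labels gold label table covering the corpus.
#' @return An object of class `hrqol_evaluation`: a named list (impact +
#'   dimensions) of per-target lists with `cm`, `sensitivity`,
#'   `specificity`, `f_measure`, `roc`, plus the predictions as an
#'   attribute.
#' @export
evaluate_model <- function(model, corpus, labels) {
  common <- intersect(corpus$id, labels$message_id)
  if (length(common) == 0) {
    stop("no overlap between corpus and label message ids", call. = FALSE)
  }
  corpus <- corpus[corpus$id %in% common, , drop = FALSE]
  class(corpus) <- c("qol_corpus", "data.frame")
  labels <- labels[match(corpus$id, labels$message_id), , drop = FALSE]
  preds <- predict(model, corpus)
  targets <- c("impact", qol_dimensions())
  safe <- function(f, cm) tryCatch(f(cm), error = function(e) NA_real_)
  out <- lapply(targets, function(t) {
    y_true <- as.logical(labels[[t]])
    if (t == "impact") {
      y_pred <- preds$impact_flag
      scores <- preds$impact_prob
    } else {
      y_pred <- preds[[paste0(t, "_flag")]]
      scores <- preds[[paste0(t, "_prob")]]
      scores[is.na(scores)] <- 0  # gated-out messages score 0
    }
    cm <- confusion(y_true, y_pred)
    roc <- tryCatch(roc_curve(y_true, scores), error = function(e) NULL)
    list(target = t, cm = cm,
         sensitivity = safe(sensitivity, cm),
         specificity = safe(specificity, cm),
         f_measure = safe(f_measure, cm),
         roc = roc)
  })
  names(out) <- targets
  structure(out, predictions = preds, class = "hrqol_evaluation")
}

#' @export
print.hrqol_evaluation <- function(x, ...) {
  cat("Evaluation (impact + five dimensions)\n")
  for (t in names(x)) {
    e <- x[[t]]
    auc <- if (is.null(e$roc)) NA_real_ else e$roc$auc
    cat(sprintf("  %-10s sens %5s  spec %5s  F %5s  AUC %5s\n", t,
                ifelse(is.na(e$sensitivity), "-",
                       sprintf("%.3f", e$sensitivity)),
                ifelse(is.na(e$specificity), "-",
                       sprintf("%.3f", e$specificity)),
                ifelse(is.na(e$f_measure), "-",
                       sprintf("%.3f", e$f_measure)),
                ifelse(is.na(auc), "-", sprintf("%.3f", auc))))
  }
  invisible(x)
}

#' Write an evaluation report to a directory
#'
#' Writes `metrics.csv` (one row per target: confusion counts, sensitivity,
#' specificity, F-measure, AUC) and one `roc_<target>.csv` per target with
#' the curve points.
#'
#' @param evaluation an [evaluate_model()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(evaluation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(evaluation), function(t) {
    e <- evaluation[[t]]
    data.frame(target = t, tp = e$cm$tp, fp = e$cm$fp, tn = e$cm$tn,
               fn = e$cm$fn, sensitivity = e$sensitivity,
               specificity = e$specificity, f_measure = e$f_measure,
               auc = if (is.null(e$roc)) NA_real_ else e$roc$auc,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  for (t in names(evaluation)) {
    if (!is.null(evaluation[[t]]$roc)) {
      utils::write.csv(evaluation[[t]]$roc$points,
                       file.path(dir, paste0("roc_", t, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(dir)
}
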