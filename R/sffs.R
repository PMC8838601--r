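#' Sequential forward floating selection scored by cross-validated AUC
#'
#' Classic SFFS: repeatedly add the feature whose inclusion maximizes the
#' mean cross-validated AUC; after each addition, conditionally remove any
#' already-selected feature whose removal strictly improves the score
#' (the "floating" step). Stops when no addition improves the score or
#' `max_features` is reached. Ties are broken by feature-inventory
#' (column) order. Folds are created once and reused for every candidate,
#' so all comparisons are paired; the whole search is deterministic given
#' the seed.
#'
#' @param X numeric matrix or data frame of candidate features (named
#'   columns).
#' @param y binary labels.
#' @param learner a [learner_spec] used for scoring (default: gradient
#'   boosting).
#' @param folds number of stratified CV folds.
#' @param seed integer seed.
#' @param max_features optional cap on the selected-set size.
#' @param smote apply SMOTE inside training folds while scoring.
#' @param smote_k SMOTE neighbor count.
#' @param min_improve minimal score improvement for a step to be accepted.
#' @return An object of class `qol_sffs`: list with `selected` (ordered
#'   feature names), `cv_score` (mean AUC of the final set), and
#'   `trajectory` (data frame `step`, `action`, `feature`, `score` of the
#'   accepted steps; scores are non-decreasing).
#' @export
sffs_select <- function(X, y, learner = learner_spec("gradient_boosting",
                                                     n_rounds = 60L,
                                                     n_trees_max_depth = 3L,
                                                     learning_rate = 0.3),
                        folds = 5L, seed = 1L, max_features = NULL,
                        smote = FALSE, smote_k = 5L, min_improve = 1e-6) {
  X <- as.matrix(X)
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2) {
    stop("labels are degenerate (a single class)", call. = FALSE)
  }
  if (ncol(X) < 1) stop("no candidate features", call. = FALSE)
  all_features <- colnames(X)
  if (is.null(all_features)) {
    all_features <- paste0("f", seq_len(ncol(X)))
    colnames(X) <- all_features
  }
  fold_id <- make_stratified_folds(y, folds, seed)
  score_set <- function(set) {
    if (length(set) == 0) return(-Inf)
    .cv_auc(X[, set, drop = FALSE], y, learner, fold_id, seed = seed,
            smote = smote, smote_k = smote_k)$mean
  }
  selected <- character(0)
  best_score <- -Inf
  trajectory <- list()
  step <- 0L
  repeat {
    if (!is.null(max_features) && length(selected) >= max_features) break
    remaining <- setdiff(all_features, selected)
    if (length(remaining) == 0) break
    add_scores <- vapply(remaining, function(f) score_set(c(selected, f)),
                         numeric(1))
    best_add <- remaining[which.max(add_scores)]  # ties: first in order
    if (max(add_scores) <= best_score + min_improve &&
        length(selected) > 0) break
    selected <- c(selected, best_add)
    best_score <- max(add_scores)
    step <- step + 1L
    trajectory[[length(trajectory) + 1]] <- data.frame(
      step = step, action = "add", feature = best_add, score = best_score,
      stringsAsFactors = FALSE)
    # floating step: drop any feature whose removal strictly helps
    repeat {
      if (length(selected) <= 2) break
      drop_scores <- vapply(selected, function(f) {
        score_set(setdiff(selected, f))
      }, numeric(1))
      # never undo the feature just added
      drop_scores[length(drop_scores)] <- -Inf
      if (max(drop_scores) > best_score + min_improve) {
        worst <- selected[which.max(drop_scores)]
        selected <- setdiff(selected, worst)
        best_score <- max(drop_scores)
        step <- step + 1L
        trajectory[[length(trajectory) + 1]] <- data.frame(
          step = step, action = "remove", feature = worst,
          score = best_score, stringsAsFactors = FALSE)
      } else break
    }
  }
  structure(list(selected = selected, cv_score = best_score,
                 trajectory = do.call(rbind, trajectory)),
            class = "qol_sffs")
}

#' @export
print.qol_sffs <- function(x, ...) {
  cat(sprintf("<qol_sffs> %d features selected, CV AUC %.4f\n",
              length(x$selected), x$cv_score))
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive 5-fold grid search scored by cross-validated AUC
#'
#' Evaluates every hyperparameter combination of the grid with the same
#' stratified folds; the best setting is the one with maximal mean AUC,
#' ties resolved by grid iteration order (rows of `expand.grid` over the
#' supplied value lists).
#'
#' @param X numeric matrix or data frame (the selected features).
#' @param y binary labels.
#' @param family learner family name (see [learner_spec()]).
#' @param grid named list mapping hyperparameter names to value vectors.
#' @param folds number of stratified CV folds.
#' @param seed integer seed.
#' @param smote apply SMOTE inside training folds while scoring.
#' @param smote_k SMOTE neighbor count.
#' @return An object of class `qol_grid_search`: list with `best`
#'   (hyperparameter list), `best_score`, and `cv_table` (one row per
#'   combination with its per-fold and mean AUC).
#' @export
grid_search <- function(X, y, family = "gradient_boosting", grid,
                        folds = 5L, seed = 1L, smote = FALSE, smote_k = 5L) {
  if (length(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  known <- .learner_hyperparameters(family)
  bad <- setdiff(names(grid), known)
  if (length(bad)) {
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  fold_id <- make_stratified_folds(y, folds, seed)
  results <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    hp <- as.list(combos[i, , drop = FALSE])
    names(hp) <- names(combos)
    spec <- do.call(learner_spec, c(list(family = family), hp))
    cv <- .cv_auc(X, y, spec, fold_id, seed = seed, smote = smote,
                  smote_k = smote_k)
    results[[i]] <- c(mean_auc = cv$mean,
                      stats::setNames(cv$folds,
                                      paste0("fold", seq_along(cv$folds))))
  }
  cv_table <- cbind(combos, do.call(rbind, results))
  best_i <- which.max(cv_table$mean_auc)  # ties: first in grid order
  best <- as.list(combos[best_i, , drop = FALSE])
  names(best) <- names(combos)
  structure(list(best = best, best_score = cv_table$mean_auc[best_i],
                 cv_table = cv_table),
            class = "qol_grid_search")
}

#' @export
print.qol_grid_search <- function(x, ...) {
  cat(sprintf("<qol_grid_search> %d combinations, best mean AUC %.4f\n",
              nrow(x$cv_table), x$best_score))
  cat("  best:", paste(names(x$best), unlist(x$best), sep = "=",
                       collapse = ", "), "\n")
  invisible(x)
}
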