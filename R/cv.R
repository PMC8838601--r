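# Cross-validation plumbing shared by feature selection, grid search and
# the learner benchmark: stratified fold assignment, a fast rank-based AUC,
# and a single-fold evaluation loop with optional in-fold SMOTE.

# Rank-based AUC (Mann-Whitney statistic, ties counted 1/2).
.auc <- function(y, scores) {
  y <- as.integer(as.logical(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified cross-validation folds
#'
#' Deterministic given `(y, k, seed)`: within each class, indices are
#' shuffled and dealt round-robin so every fold holds both classes whenever
#' each class has at least `k` members.
#'
#' @param y binary labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold assignments in `1..k`.
#' @export
make_stratified_folds <- function(y, k = 5L, seed = 1L) {
  y <- as.integer(as.logical(y))
  folds <- integer(length(y))
  set.seed(as.integer(seed))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    if (length(idx) == 0) next
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Mean cross-validated AUC of one learner on (X, y) under a fixed fold
# assignment. SMOTE, when requested, is applied to the training folds only,
# never to the held-out fold.
.cv_auc <- function(X, y, spec, folds, seed = 1L, smote = FALSE,
                    smote_k = 5L) {
  X <- as.matrix(X)
  y <- as.integer(as.logical(y))
  k <- max(folds)
  fold_auc <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- folds == f
    if (!any(te) || length(unique(y[tr])) < 2 ||
        length(unique(y[te])) < 2) next
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (smote) {
      n_min <- min(sum(ytr == 1), sum(ytr == 0))
      if (n_min >= 2) {
        bal <- smote_oversample(Xtr, ytr,
                                k = max(1L, min(smote_k, n_min - 1L)),
                                seed = seed + f)
        Xtr <- bal$X; ytr <- bal$y
      }
    }
    model <- .fit_learner(spec, Xtr, ytr, seed = seed + f)
    scores <- .predict_learner(model, X[te, , drop = FALSE])
    fold_auc[f] <- .auc(y[te], scores)
  }
  list(mean = mean(fold_auc, na.rm = TRUE), folds = fold_auc)
}
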