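#' SMOTE oversampling of the minority class
#'
#' Synthetic minority oversampling: each synthetic row is a convex
#' combination \eqn{x + u (x_{nn} - x)} with \eqn{u \sim U(0,1)}, where
#' \eqn{x} is a minority row and \eqn{x_{nn}} one of its `k` nearest
#' minority neighbors (Euclidean distance on the normalized features).
#' Enough synthetic rows are created to raise the minority count to the
#' majority count. Original rows are preserved verbatim (synthetic rows are
#' appended). `k` is reduced to `minority size - 1` when the minority is
#' too small, with a warning.
#'
#' @param X numeric matrix or data frame of features (normalized).
#' @param y binary labels (logical or 0/1), length `nrow(X)`.
#' @param k number of nearest minority neighbors to interpolate toward.
#' @param seed integer seed; the output is deterministic given it.
#' @return A list with `X` (original rows first, synthetic rows appended),
#'   `y`, and `synthetic` (logical vector marking appended rows).
#' @export
smote_oversample <- function(X, y, k = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(as.logical(y))
  stopifnot(nrow(X) == length(y), k >= 1)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == n0) {
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  }
  minority <- if (n1 < n0) 1L else 0L
  min_idx <- which(y == minority)
  n_min <- length(min_idx); n_maj <- nrow(X) - n_min
  if (n_min < 2) {
    stop("SMOTE needs at least 2 samples in the minority class (class ",
         minority, " has ", n_min, ")", call. = FALSE)
  }
  if (k > n_min - 1) {
    warning("SMOTE k reduced from ", k, " to ", n_min - 1,
            " (minority size ", n_min, ")", call. = FALSE)
    k <- n_min - 1L
  }
  Xm <- X[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  # k nearest minority neighbors per minority row (ties: lowest index)
  nn <- do.call(rbind, lapply(seq_len(n_min),
                              function(i) order(d[i, ])[seq_len(k)]))
  n_new <- n_maj - n_min
  set.seed(as.integer(seed))
  base <- sample(n_min, n_new, replace = TRUE)
  pick <- sample.int(k, n_new, replace = TRUE)
  u <- stats::runif(n_new)
  synth <- Xm[base, , drop = FALSE] +
    u * (Xm[nn[cbind(base, pick)], , drop = FALSE] - Xm[base, , drop = FALSE])
  rownames(synth) <- NULL
  list(X = rbind(X, synth),
       y = c(y, rep(minority, n_new)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_new)))
}
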