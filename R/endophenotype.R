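# Behavioral endophenotyping: PCA of standardized behavioral metrics, and
# prediction of response vigor from tensor unit loadings.

#' PCA endophenotype decomposition of a behavior matrix
#'
#' Metrics have heterogeneous units (prices, rewards, elasticities), so the
#' decomposition is an eigendecomposition of the correlation matrix:
#' columns are standardized to mean 0 / sd 1, loadings are the orthonormal
#' eigenvectors, scores are the standardized data projected on them, and
#' variance fractions come from the eigenvalues. The sign convention fixes
#' the largest-magnitude loading of each component to be positive, so the
#' output is deterministic.
#'
#' @param behavior numeric matrix or data.frame, subjects x metrics.
#' @param n_components number of components to keep (default all).
#' @return list of class "EndophenotypeResult": `loadings` (metrics x
#'   components, orthonormal), `scores` (subjects x components),
#'   `variance_explained` (fraction per component, non-increasing).
#' @export
pcaEndophenotype <- function(behavior, n_components = NULL) {
  X <- as.matrix(behavior)
  if (nrow(X) < 3L || ncol(X) < 2L) stop("need >= 3 subjects and >= 2 metrics")
  if (anyNA(X)) {
    keep <- stats::complete.cases(X)
    X <- X[keep, , drop = FALSE]       # listwise deletion
    if (nrow(X) < 3L) stop("fewer than 3 complete subjects after deletion")
  }
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant metric column(s): %s",
                 paste(colnames(X)[sds == 0], collapse = ", ")))
  }
  Z <- scale(X)
  e <- eigen(stats::cor(X), symmetric = TRUE)
  m <- ncol(X)
  nc <- if (is.null(n_components)) m else min(n_components, m)
  V <- e$vectors[, seq_len(nc), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(nc)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(X)
  colnames(V) <- paste0("PC", seq_len(nc))
  scores <- Z %*% V
  structure(list(loadings = V, scores = scores,
                 variance_explained = e$values[seq_len(nc)] / sum(e$values),
                 eigenvalues = e$values),
            class = "EndophenotypeResult")
}

#' @export
print.EndophenotypeResult <- function(x, ...) {
  cat("EndophenotypeResult:", ncol(x$loadings), "components\n")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' Predict behavioral latency from CP unit loadings
#'
#' Harness for the response-vigor prediction: a seeded train/test split of
#' the units (80% training by default), a configurable regression strategy
#' fitted on the training unit loadings, and the held-out Pearson
#' correlation between predicted and true latencies. The regressor is an
#' injected strategy — a list with `fit(X, y)` returning an object and
#' `predict(obj, X)` — defaulting to least squares on the loadings; any
#' compliant regressor (e.g. boosted trees) can be supplied.
#'
#' @param W unit-loading matrix (units x components).
#' @param latency positive numeric target per unit (e.g. latency to the
#'   eighth reward of the unit's session).
#' @param split training fraction in (0.5, 0.95) (default 0.8).
#' @param regressor strategy list with `fit` and `predict`, or NULL for the
#'   linear default.
#' @param seed integer seed for the split.
#' @return list with `pearson_r` (held-out), `predictions`, `truth`,
#'   `test_idx`.
#' @export
predictLatencyFromLoadings <- function(W, latency, split = 0.8,
                                       regressor = NULL, seed = 1L) {
  W <- as.matrix(W)
  if (nrow(W) < 20L) stop("need at least 20 samples")
  if (length(latency) != nrow(W)) stop("latency length must match rows of W")
  if (split <= 0.5 || split >= 0.95) stop("split must lie in (0.5, 0.95)")
  if (stats::sd(latency) == 0) stop("constant target: correlation undefined")
  if (is.null(regressor)) {
    regressor <- list(
      fit = function(X, y) stats::lm.fit(cbind(1, X), y)$coefficients,
      predict = function(obj, X) drop(cbind(1, X) %*% obj)
    )
  }
  n <- nrow(W)
  idx <- withSeed(seed, sample(n, size = floor(split * n)))
  test <- setdiff(seq_len(n), idx)
  fit <- regressor$fit(W[idx, , drop = FALSE], latency[idx])
  pred <- regressor$predict(fit, W[test, , drop = FALSE])
  list(pearson_r = stats::cor(pred, latency[test]),
       predictions = pred, truth = latency[test], test_idx = test)
}
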