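# Canonical polyadic (CP) tensor decomposition by alternating least squares,
# cross-run rank selection, and group comparison of unit loadings.

#' Build a trial tensor from per-subject unit PSTHs, truncated to the first
#' n trials
#'
#' All subjects contribute their units along the first mode; only the first
#' `n` trials (the lowest reward count completed by every subject) are kept
#' so all arrays share the same trial dimension.
#'
#' @param psth_sets list of per-subject lists of "UnitPSTH" objects (from
#'   \code{\link{buildUnitPSTHs}}); or a single such list.
#' @param n number of leading trials to keep (default 8).
#' @param groups optional character vector of group labels, one per subject.
#' @return a \linkS4class{TrialTensor} of dimension (total units) x n x bins.
#' @export
truncateToFirstTrials <- function(psth_sets, n = 8L, groups = NULL) {
  if (length(psth_sets) && !is.null(psth_sets[[1]]$z)) {
    psth_sets <- list(psth_sets)        # single subject
  }
  if (!length(psth_sets)) stop("no PSTH sets supplied")
  short <- vapply(psth_sets, function(s) nrow(s[[1]]$z) < n, logical(1))
  if (any(short)) {
    stop(sprintf("subject(s) %s have fewer than %d trials",
                 paste(which(short), collapse = ", "), n))
  }
  time <- psth_sets[[1]][[1]]$time
  slabs <- list(); ids <- character(); grp <- character()
  for (s in seq_along(psth_sets)) {
    for (u in psth_sets[[s]]) {
      slabs[[length(slabs) + 1L]] <- u$z[seq_len(n), , drop = FALSE]
      ids <- c(ids, u$unit_id)
      grp <- c(grp, if (is.null(groups)) NA_character_ else groups[s])
    }
  }
  X <- array(0, dim = c(length(slabs), n, length(time)))
  for (u in seq_along(slabs)) X[u, , ] <- slabs[[u]]
  info <- data.frame(unit_id = ids)
  if (!is.null(groups)) info$group <- grp
  new("TrialTensor", data = X, unitInfo = info, timeAxis = time)
}

.cpSweepFit <- function(X, r, init, tol, max_iter) {
  d <- dim(X)
  U <- d[1]; Tt <- d[2]; P <- d[3]
  X1 <- matrix(X, U, Tt * P)                       # columns: (t, p), t fastest
  X2 <- matrix(aperm(X, c(2, 1, 3)), Tt, U * P)    # columns: (u, p), u fastest
  X3 <- matrix(aperm(X, c(3, 1, 2)), P, U * Tt)    # columns: (u, t), u fastest
  W <- init$W; B <- init$B; A <- init$A
  normX2 <- sum(X^2)
  obj <- numeric()
  solveLS <- function(Y, KR) {
    G <- crossprod(KR)
    # ridge jitter guards against transient rank deficiency
    Y %*% KR %*% solve(G + diag(1e-12 * mean(diag(G)), ncol(G)))
  }
  prev <- Inf
  for (it in seq_len(max_iter)) {
    keepW <- W; keepB <- B; keepA <- A
    W <- solveLS(X1, khatriRao(A, B))
    B <- solveLS(X2, khatriRao(A, W))
    A <- solveLS(X3, khatriRao(B, W))
    # norm-balance into W
    for (j in seq_len(r)) {
      nb <- sqrt(sum(B[, j]^2)); na <- sqrt(sum(A[, j]^2))
      if (nb > 0) { B[, j] <- B[, j] / nb } ; if (na > 0) { A[, j] <- A[, j] / na }
      W[, j] <- W[, j] * nb * na
    }
    # residual computed directly: the Gram-matrix shortcut cancels
    # catastrophically when overfitted factors become collinear
    sse <- sum((X1 - W %*% t(khatriRao(A, B)))^2)
    if (is.finite(prev) && sse > prev) {
      # ill-conditioned subproblem at machine-precision residual: the ridge
      # jitter dominates; keep the previous (better) factors and stop
      W <- keepW; B <- keepB; A <- keepA
      break
    }
    obj <- c(obj, sse)
    if (sse < 1e-12 * normX2) break   # perfect fit
    if (is.finite(prev) && abs(prev - sse) < tol * max(prev, .Machine$double.eps)) break
    prev <- sse
  }
  list(W = W, B = B, A = A, objective = obj)
}

#' Fit a CP model by alternating least squares
#'
#' Each sweep cyclically solves the three least-squares subproblems (unit,
#' trial, then within-trial factors, each with the other two fixed), then
#' rebalances component scale into the unit factors. The best of
#' `n_restarts` random initializations is returned. The objective (sum of
#' squared residuals) is non-increasing across sweeps.
#'
#' @param X a \linkS4class{TrialTensor} or a 3-way array.
#' @param r rank, 1 <= r <= min(dim).
#' @param n_restarts random restarts (default 4).
#' @param tol relative objective-change stopping tolerance (default 1e-8).
#' @param max_iter maximum sweeps per restart (default 300).
#' @param seed integer; per-restart seeds derive from it.
#' @return a \linkS4class{CPModel}.
#' @export
cpALS <- function(X, r, n_restarts = 4L, tol = 1e-8, max_iter = 300L,
                  seed = 1L) {
  A3 <- if (is(X, "TrialTensor")) tensorData(X) else X
  d <- dim(A3)
  if (length(d) != 3L) stop("X must be a 3-way tensor")
  if (r < 1L || r > min(d)) stop("rank must be between 1 and min(dim)")
  if (tol <= 0) stop("tol must be positive")
  if (all(A3 == 0)) stop("degenerate all-zero tensor")
  best <- NULL
  for (s in seq_len(n_restarts)) {
    init <- withSeed(childSeed(seed, s), {
      list(W = matrix(stats::rnorm(d[1] * r), d[1], r),
           B = matrix(stats::rnorm(d[2] * r), d[2], r),
           A = matrix(stats::rnorm(d[3] * r), d[3], r))
    })
    fit <- .cpSweepFit(A3, r, init, tol, max_iter)
    if (is.null(best) ||
        utils::tail(fit$objective, 1) < utils::tail(best$objective, 1)) {
      best <- fit
    }
  }
  new("CPModel", W = best$W, B = best$B, A = best$A, rank = as.integer(r),
      objective = best$objective)
}

# enumerate permutations of 1..n (n <= 8 here)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Cross-run similarity of two CP models
#'
#' Components are matched one-to-one to maximize the summed per-component
#' congruence — the product over modes of the absolute cosine between
#' corresponding factor columns. The score is the mean matched congruence:
#' 1 for identical models up to component permutation and sign/scale
#' rebalancing, near 0 for unrelated models.
#'
#' @param m1,m2 \linkS4class{CPModel}s of equal rank and dimensions.
#' @return similarity score in [0, 1].
#' @export
factorSimilarity <- function(m1, m2) {
  if (cpRank(m1) != cpRank(m2)) stop("models have different ranks")
  r <- cpRank(m1)
  cong <- matrix(0, r, r)
  for (i in seq_len(r)) {
    for (j in seq_len(r)) {
      cong[i, j] <- abs(cosineSim(m1@W[, i], m2@W[, j])) *
        abs(cosineSim(m1@B[, i], m2@B[, j])) *
        abs(cosineSim(m1@A[, i], m2@A[, j]))
    }
  }
  if (r <= 8L) {
    perms <- .permutations(r)
    best <- 0
    for (p in seq_len(nrow(perms))) {
      s <- mean(cong[cbind(seq_len(r), perms[p, ])])
      if (s > best) best <- s
    }
    best
  } else {
    # greedy fallback for large ranks
    used <- logical(r); tot <- 0
    for (i in order(apply(cong, 1L, max), decreasing = TRUE)) {
      j <- which.max(replace(cong[i, ], used, -Inf))
      used[j] <- TRUE; tot <- tot + cong[i, j]
    }
    tot / r
  }
}

# largest pairwise 3-mode congruence product among a model's own
# components; ~1 when the fit has split one component into collinear copies
.modelRedundancy <- function(m) {
  r <- cpRank(m)
  if (r < 2L) return(0)
  worst <- 0
  for (i in seq_len(r - 1L)) {
    for (j in seq(i + 1L, r)) {
      cij <- abs(cosineSim(m@W[, i], m@W[, j])) *
        abs(cosineSim(m@B[, i], m@B[, j])) *
        abs(cosineSim(m@A[, i], m@A[, j]))
      if (cij > worst) worst <- cij
    }
  }
  worst
}

#' Select the CP rank by cross-run convergence
#'
#' For each candidate rank (ascending), `runs_per_candidate` independently
#' seeded models are fitted; a candidate "converges" when (a) the mean
#' pairwise \code{\link{factorSimilarity}} across its runs reaches
#' `similarity_threshold`, and (b) the majority of runs actually recover
#' that many distinct components — a run whose own components are mutually
#' congruent (>= `redundancy_threshold`) has split one component into
#' collinear copies and is counted as degenerate. The rank is grown until
#' convergence breaks down, and the last converging candidate before the
#' first failure is selected — the smallest component count that the data
#' support reproducibly. (Small ranks below the true component count also
#' converge, because their best blended fit is unique; the breakdown point
#' is what identifies the planted structure. A pure-noise tensor fails
#' already at the first candidate and yields `NA`.)
#'
#' @param X a \linkS4class{TrialTensor} or 3-way array.
#' @param candidates ascending candidate ranks (default 1:8).
#' @param runs_per_candidate independent fits per candidate (default 10).
#' @param similarity_threshold convergence threshold in (0, 1] (default 0.8).
#' @param seed master seed; run-level seeds derive from it.
#' @param redundancy_threshold intra-model congruence above which two
#'   components of one run count as collinear copies (default 0.95).
#' @param tol,max_iter per-run ALS settings; tighter than the
#'   \code{\link{cpALS}} defaults because cross-run agreement requires
#'   well-converged fits.
#' @return list of class "RankSelectionResult": `selected_r` (integer or
#'   NA), `similarity` (mean pairwise score per evaluated candidate),
#'   `degenerate_frac` (fraction of runs with split components),
#'   `recon_error` (relative reconstruction error of the best run per
#'   candidate).
#' @export
selectRank <- function(X, candidates = 1:8, runs_per_candidate = 10L,
                       similarity_threshold = 0.8, seed = 1L,
                       redundancy_threshold = 0.95,
                       tol = 1e-10, max_iter = 800L) {
  if (!length(candidates)) stop("no candidate ranks")
  if (is.unsorted(candidates)) stop("candidates must be ascending")
  if (similarity_threshold <= 0 || similarity_threshold > 1) {
    stop("similarity_threshold must lie in (0, 1]")
  }
  A3 <- if (is(X, "TrialTensor")) tensorData(X) else X
  normX <- sqrt(sum(A3^2))
  sim <- numeric(length(candidates))
  err <- numeric(length(candidates))
  dfr <- numeric(length(candidates))
  selected <- NA_integer_
  n_eval <- 0L
  for (ci in seq_along(candidates)) {
    n_eval <- ci
    r <- candidates[ci]
    runs <- lapply(seq_len(runs_per_candidate), function(run) {
      cpALS(A3, r, n_restarts = 1L, seed = childSeed(seed, 1000L * ci + run),
            tol = tol, max_iter = max_iter)
    })
    pair <- utils::combn(runs_per_candidate, 2L)
    sims <- apply(pair, 2L, function(p) factorSimilarity(runs[[p[1]]],
                                                         runs[[p[2]]]))
    sim[ci] <- mean(sims)
    dfr[ci] <- mean(vapply(runs, .modelRedundancy, numeric(1)) >=
                      redundancy_threshold)
    sse <- vapply(runs, function(m) utils::tail(objectiveTrace(m), 1),
                  numeric(1))
    err[ci] <- sqrt(min(sse)) / normX
    if (sim[ci] < similarity_threshold || dfr[ci] > 0.5) break
    selected <- as.integer(r)
  }
  structure(list(selected_r = selected,
                 candidates = candidates[seq_len(n_eval)],
                 similarity = sim[seq_len(n_eval)],
                 degenerate_frac = dfr[seq_len(n_eval)],
                 recon_error = err[seq_len(n_eval)],
                 threshold = similarity_threshold),
            class = "RankSelectionResult")
}

#' @export
print.RankSelectionResult <- function(x, ...) {
  cat("RankSelectionResult: selected r =", x$selected_r, "\n")
  print(data.frame(r = x$candidates, similarity = round(x$similarity, 3),
                   degenerate = round(x$degenerate_frac, 2),
                   recon_error = round(x$recon_error, 4)))
  invisible(x)
}

#' Compare unit-factor loadings between groups
#'
#' Per component: group means of the unit loadings, their difference, and
#' the standardized difference (Cohen's d with pooled SD). Significance
#' testing on real data is left to standard tools.
#'
#' @param model a \linkS4class{CPModel}.
#' @param group_labels character vector of length U with two levels.
#' @return data.frame, one row per component.
#' @export
compareGroupLoadings <- function(model, group_labels) {
  W <- unitFactors(model)
  if (length(group_labels) != nrow(W)) {
    stop("group_labels length must match the number of units")
  }
  lv <- sort(unique(group_labels))
  if (length(lv) != 2L) stop("exactly two group levels required")
  out <- lapply(seq_len(ncol(W)), function(j) {
    a <- W[group_labels == lv[1], j]
    b <- W[group_labels == lv[2], j]
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                  (length(b) - 1) * stats::var(b)) /
                 (length(a) + length(b) - 2))
    data.frame(component = j,
               mean_a = mean(a), mean_b = mean(b),
               difference = mean(b) - mean(a),
               cohens_d = if (sp > 0) (mean(b) - mean(a)) / sp else 0)
  })
  res <- do.call(rbind, out)
  attr(res, "groups") <- lv
  res
}
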