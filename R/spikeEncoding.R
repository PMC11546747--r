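# Single-unit encoding analysis: session-mean normalization, cross-unit
# z-scoring, Gaussian-kernel smoothing, the four clustering features, and
# encoding-pattern discovery by iterative k-means.

#' Smoothing configuration for unit PSTHs
#'
#' The firing-rate kernel is a truncated Gaussian sliding window of
#' `kernel_bins` bins with `kernel_sigma` (in bins), renormalized so it sums
#' to 1.
#'
#' @param bin_width PSTH bin width in seconds (default 0.1).
#' @param kernel_bins kernel length in bins (default 8).
#' @param kernel_sigma kernel sigma in bins (default 3).
#' @param span peri-cue PSTH span in seconds (default c(-2, 8)).
#' @return list of class "SmoothingConfig".
#' @export
smoothingConfig <- function(bin_width = 0.1, kernel_bins = 8L,
                            kernel_sigma = 3, span = c(-2, 8)) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (kernel_bins < 1L) stop("kernel_bins must be >= 1")
  structure(list(bin_width = bin_width, kernel_bins = as.integer(kernel_bins),
                 kernel_sigma = kernel_sigma, span = span),
            class = "SmoothingConfig")
}

#' Build normalized, z-scored, smoothed peri-cue PSTHs for all units
#'
#' Per unit, spike counts are binned around each cue onset and converted to
#' rates; each unit's rate is normalized to its average firing rate over the
#' entire session; normalized rates are then standardized (z-scored) across
#' units per time bin (using the cross-unit mean and sd of the trial-averaged
#' normalized rates); finally the truncated Gaussian kernel is applied.
#' Units with zero spikes are excluded with a warning; time bins with zero
#' cross-unit variance get z = 0 with a warning.
#'
#' @param session a \linkS4class{SpikeSession}.
#' @param events a \linkS4class{TrialEvents} with cue_on events.
#' @param cfg a \code{\link{smoothingConfig}}.
#' @return list of "UnitPSTH" lists, each with `unit_id`, `z` (trial x bin
#'   matrix), `time` (bin centers, s relative to cue onset), and
#'   `normalization` (session mean rate and the cross-unit parameters).
#' @export
buildUnitPSTHs <- function(session, events, cfg = smoothingConfig()) {
  cues <- eventTimes(events, "cue_on")
  if (!length(cues)) stop("events contain no cue_on entries")
  spikes <- spikeTimes(session)
  if (!length(spikes)) stop("session contains no units")
  dur <- sessionDuration(session)

  nz <- vapply(spikes, length, integer(1)) > 0L
  if (any(!nz)) {
    warning(sprintf("excluding %d unit(s) with zero spikes", sum(!nz)))
    spikes <- spikes[nz]
  }
  if (!length(spikes)) stop("all units have zero spikes")

  span <- cfg$span
  edges <- seq(span[1], span[2], by = cfg$bin_width)
  centers <- edges[-length(edges)] + cfg$bin_width / 2
  nb <- length(centers)
  # keep cues whose span lies inside the session
  cues <- cues[cues + span[1] >= 0 & cues + span[2] <= dur]
  if (!length(cues)) stop("no cue has full PSTH span coverage")

  norm_rates <- lapply(spikes, function(st) {
    mean_rate <- length(st) / dur
    m <- matrix(0, length(cues), nb)
    for (i in seq_along(cues)) {
      rel <- st[st >= cues[i] + span[1] & st < cues[i] + span[2]] - cues[i]
      cnt <- tabulate(findInterval(rel, edges, rightmost.closed = FALSE),
                      nbins = nb)
      m[i, ] <- cnt / cfg$bin_width
    }
    m / mean_rate
  })
  # cross-unit standardization per time bin, computed on trial averages
  avg <- t(vapply(norm_rates, colMeans, numeric(nb)))   # units x bins
  mu <- colMeans(avg)
  sdv <- apply(avg, 2L, stats::sd)
  if (any(sdv == 0 | !is.finite(sdv))) {
    warning("zero cross-unit variance in some time bins; z set to 0 there")
    sdv[sdv == 0 | !is.finite(sdv)] <- Inf
  }
  S <- gaussSmoothMatrix(nb, cfg$kernel_bins, cfg$kernel_sigma)
  out <- lapply(seq_along(norm_rates), function(u) {
    z <- sweep(sweep(norm_rates[[u]], 2L, mu), 2L, sdv, "/")
    z <- z %*% t(S)
    list(unit_id = names(spikes)[u], z = z, time = centers,
         normalization = list(mean_rate = length(spikes[[u]]) / dur,
                              cross_unit_mean = mu, cross_unit_sd = sdv))
  })
  names(out) <- names(spikes)
  out
}

#' Extract the four encoding features from a unit PSTH
#'
#' The clustering features are (i) the number of transients — excursions of
#' the trial-averaged z trace beyond `threshold_z` in either direction
#' (peaks and troughs), counted with hysteresis: an excursion starts when
#' |z| crosses `threshold_z` and ends only when |z| falls back below
#' `exit_z`, so jitter around the threshold is not double-counted; (ii) the
#' time of the first transient relative to cue onset (span end as sentinel
#' when none); (iii) mean activity during cue presentation, z over [0, 2) s;
#' and (iv) mean activity after reward delivery, z over [2, 7) s.
#'
#' The default entry threshold is 1.5: cross-unit standardization bounds
#' trial-averaged excursions of activated units near z = 2, so 1.5 falls
#' between typical activated plateaus (>= 1.8) and inhibited troughs
#' (|z| <= 1.1) instead of sitting on top of the activated level.
#'
#' @param psth a "UnitPSTH" from \code{\link{buildUnitPSTHs}}.
#' @param threshold_z excursion entry threshold (default 1.5).
#' @param exit_z excursion exit threshold (default `threshold_z - 0.5`).
#' @param cue_window,reward_window analysis windows in seconds.
#' @return named numeric vector: `n_transients`, `t_first_transient`,
#'   `mean_cue_activity`, `mean_reward_activity`.
#' @export
extractEncodingFeatures <- function(psth, threshold_z = 1.5,
                                    exit_z = threshold_z - 0.5,
                                    cue_window = c(0, 2),
                                    reward_window = c(2, 7)) {
  tm <- psth$time
  if (min(tm) > 0 || max(tm) < 7) stop("PSTH must cover [0, 7] s")
  bw <- diff(tm[1:2])
  avg <- colMeans(psth$z)
  # hysteresis: candidate runs are |z| >= exit_z; only runs that reach the
  # entry threshold count as transients
  above_exit <- abs(avg) >= exit_z
  runs <- rle(above_exit)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  qual <- which(runs$values &
                  vapply(seq_along(runs$values), function(i) {
                    runs$values[i] &&
                      any(abs(avg[starts[i]:ends[i]]) >= threshold_z)
                  }, logical(1)))
  n_trans <- length(qual)
  t_first <- if (n_trans == 0) max(tm) + bw / 2 else {
    seg <- starts[qual[1]]:ends[qual[1]]
    tm[seg[which(abs(avg[seg]) >= threshold_z)[1]]]
  }
  in_cue <- tm >= cue_window[1] & tm < cue_window[2]
  in_rwd <- tm >= reward_window[1] & tm < reward_window[2]
  c(n_transients = n_trans,
    t_first_transient = t_first,
    mean_cue_activity = mean(avg[in_cue]),
    mean_reward_activity = mean(avg[in_rwd]))
}

# semantic tag for one centroid: magnitudes judged in standardized units
# (absolute z levels depend on the population mix), signs taken from the raw
# activity values
.semanticLabel <- function(raw, std, activity_floor = 0.5) {
  mc <- raw[["mean_cue_activity"]]
  mr <- raw[["mean_reward_activity"]]
  smc <- abs(std[["mean_cue_activity"]])
  smr <- abs(std[["mean_reward_activity"]])
  if (smc < activity_floor && smr < activity_floor) return("nonencoding")
  if (mc < 0 && mr < 0 && min(smc, smr) > 0.5 * max(smc, smr)) {
    return("press_inhibited")   # sustained inhibition spanning both windows
  }
  if (smc >= smr) {
    if (mc > 0) "cue_activated" else "cue_inhibited"
  } else {
    if (mr > 0) "reward_activated" else "reward_inhibited"
  }
}

#' Discover encoding patterns by iterative k-means
#'
#' k-means (50 restarts, seeded) is run on the standardized features at
#' increasing k; the largest k that still introduces a new encoding pattern
#' is kept (k-means solutions are not nested, so one redundant step does
#' not end the search before `max_k`). "New pattern" is judged on each
#' centroid's reconstructed PSTH profile — a template trace holding the
#' centroid's mean cue activity over the cue window and mean reward
#' activity over the reward window — compared with every centroid of the
#' previous model: a centroid is a repeat when its best-matching previous
#' profile has the same shape (cosine >= `redundancy_threshold`) at a
#' comparable magnitude. Centroids whose cluster holds fewer than
#' `min_cluster_frac` of the units are outlier fragments, not patterns. Clusters whose centroid shows no appreciable cue or
#' reward activity are the "nonencoding" pattern; individual units farther
#' (in standardized feature space) from their centroid than the
#' `outlier_quantile` of all within-cluster distances are also labeled
#' nonencoding. The reported `k` counts encoding clusters only.
#'
#' @param features matrix or data.frame, one row per unit, columns as
#'   returned by \code{\link{extractEncodingFeatures}}.
#' @param k_start first k to try (default 2).
#' @param max_k largest k to try (default 8).
#' @param seed integer seed (restarts are sub-seeded deterministically).
#' @param redundancy_threshold cosine similarity above which a new centroid
#'   is considered a repeat of an existing pattern (default 0.9).
#' @param outlier_quantile within-cluster distance quantile beyond which a
#'   unit is nonencoding (default 0.975).
#' @param activity_floor minimum |mean activity| (z) for a centroid to count
#'   as encoding (default 0.5).
#' @param feature_weights per-feature weights applied after
#'   standardization. The transient count and latency are derived from a
#'   hard threshold crossing and are therefore intrinsically noisier than
#'   the window activity means; the default halves their influence so that
#'   threshold jitter near the crossing point does not masquerade as
#'   cluster structure.
#' @param min_cluster_frac smallest fraction of units a cluster must hold
#'   for its centroid to count as a new pattern (default 0.05).
#' @return a \linkS4class{ClusterModel}.
#' @export
clusterEncodingPatterns <- function(features, k_start = 2L, max_k = 8L,
                                    seed = 1L,
                                    redundancy_threshold = 0.9,
                                    outlier_quantile = 0.975,
                                    activity_floor = 0.5,
                                    feature_weights = c(0.5, 0.5, 1, 1),
                                    min_cluster_frac = 0.05) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) {
    colnames(X) <- c("n_transients", "t_first_transient",
                     "mean_cue_activity", "mean_reward_activity")
  }
  n <- nrow(X)
  if (n < k_start) stop("fewer units than k_start")
  sds <- apply(X, 2L, stats::sd)
  sds[sds == 0] <- 1
  sds <- sds / feature_weights
  Xs <- sweep(sweep(X, 2L, colMeans(X)), 2L, sds, "/")
  n_distinct <- nrow(unique(Xs))

  fitK <- function(k) {
    withSeed(childSeed(seed, k), {
      stats::kmeans(Xs, centers = k, nstart = 50L, iter.max = 100L)
    })
  }
  rawCenter <- function(c_std) c_std * sds + colMeans(X)
  # reconstructed PSTH template of a centroid: cue-window level then
  # reward-window level, weighted by window durations (2 s and 5 s)
  profileOf <- function(c_std) {
    raw <- rawCenter(c_std)
    c(rep(raw[["mean_cue_activity"]], 8L),
      rep(raw[["mean_reward_activity"]], 20L))
  }
  # similarity of two reconstructed profiles: shape must match (cosine) and
  # magnitudes must be comparable (within about 2x) — a flat trace does not
  # resemble a deep one of the same shape, but the weaker half of one blob
  # still resembles its stronger half. Two near-flat profiles (< 0.25 z RMS)
  # are the same (non)pattern.
  profSim <- function(u, v) {
    nu <- sqrt(mean(u^2)); nv <- sqrt(mean(v^2))
    if (nu < 0.25 && nv < 0.25) return(1)
    if (nu == 0 || nv == 0) return(0)
    if (min(nu, nv) / max(nu, nv) < 0.45) return(0)
    cosineSim(u, v)
  }

  if (n_distinct == 1L) {
    km <- list(cluster = rep(1L, n),
               centers = matrix(colMeans(Xs), 1L,
                                dimnames = list(NULL, colnames(Xs))))
    chosen <- km
    hist <- data.frame(k = 1L, new_pattern = FALSE)
  } else {
    models <- list()
    hist <- data.frame(k = integer(), min_novelty = numeric(),
                       new_pattern = logical())
    k_max_eff <- min(max_k, n_distinct)
    min_size <- max(2L, ceiling(min_cluster_frac * n))
    chosen_k <- k_start
    for (k in seq(k_start, k_max_eff)) {
      models[[k]] <- fitK(k)
      if (k > k_start) {
        # compare against the last ACCEPTED model, not k - 1: k-means splits
        # a blob gradually, and each step can resemble its immediate parent
        # while the cumulative drift is a genuinely new pattern
        cur <- apply(models[[k]]$centers, 1L, profileOf, simplify = FALSE)
        ref <- apply(models[[chosen_k]]$centers, 1L, profileOf,
                     simplify = FALSE)
        # a centroid is novel when no accepted profile matches it and its
        # cluster is large enough to constitute a pattern
        best <- vapply(cur, function(cc) {
          max(vapply(ref, function(pc) profSim(cc, pc), numeric(1)))
        }, numeric(1))
        sizes <- tabulate(models[[k]]$cluster, nbins = k)
        # a near-flat centroid is the nonencoding background separating
        # out, not a new encoding pattern
        rms <- vapply(cur, function(cc) sqrt(mean(cc^2)), numeric(1))
        novel <- best < redundancy_threshold & sizes >= min_size &
          rms >= 0.25
        hist <- rbind(hist, data.frame(k = k, min_novelty = 1 - min(best),
                                       new_pattern = any(novel)))
        if (any(novel)) chosen_k <- k
      } else {
        hist <- rbind(hist, data.frame(k = k, min_novelty = NA_real_,
                                       new_pattern = TRUE))
      }
    }
    chosen <- models[[chosen_k]]
  }

  centers_std <- chosen$centers
  centers_raw <- sweep(sweep(centers_std, 2L, sds, "*"), 2L, colMeans(X), "+")
  labels <- vapply(seq_len(nrow(centers_raw)), function(i) {
    .semanticLabel(centers_raw[i, ], centers_std[i, ], activity_floor)
  }, character(1))
  # disambiguate repeated tags
  dup <- ave(seq_along(labels), labels, FUN = seq_along)
  labels[dup > 1] <- paste0(labels[dup > 1], "_", dup[dup > 1])

  assignments <- labels[chosen$cluster]
  d <- sqrt(rowSums((Xs - centers_std[chosen$cluster, , drop = FALSE])^2))
  cutoff <- stats::quantile(d, outlier_quantile)
  assignments[d > cutoff] <- "nonencoding"

  encoding <- !startsWith(labels, "nonencoding")
  # k counts encoding patterns; a population with no encoding structure at
  # all (e.g. all-identical features) still constitutes one pattern
  new("ClusterModel",
      k = as.integer(max(1L, sum(encoding))),
      assignments = assignments,
      centroids = centers_raw,
      centroidsStd = centers_std,
      featureNames = colnames(X),
      history = hist)
}

#' Trapezoidal AUC of the trial-averaged z trace (AUCz)
#'
#' Mean-normalized firing-rate AUC over an analysis window (cue 0 to 2 s,
#' reward 2 to 7 s, relative to cue onset), by the trapezoidal rule with
#' exact window endpoints.
#'
#' @param psth a "UnitPSTH".
#' @param window numeric length-2 window in seconds.
#' @return AUC in z*s.
#' @export
windowAUCz <- function(psth, window) {
  if (window[1] < min(psth$time) || window[2] > max(psth$time)) {
    stop("window outside PSTH span")
  }
  trapzWindow(psth$time, colMeans(psth$z), window)
}
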