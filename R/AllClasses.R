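#' @import methods
NULL

#' TrialEvents: time-stamped behavioral event stream
#'
#' The common clock for all peri-event analyses. Each record is an event
#' (cue onset/offset, lever press, reward or infusion delivery, trial
#' boundary) with its time in seconds from session start and its trial index.
#'
#' @slot events data.frame with columns `time_s` (numeric, non-decreasing),
#'   `event` (character, one of the recognized event codes) and
#'   `trial_index` (integer, contiguous from 1).
#' @exportClass TrialEvents
setClass("TrialEvents", representation(events = "data.frame"))

.EVENT_CODES <- c("cue_on", "cue_off", "active_press", "inactive_press",
                  "reward", "infusion", "trial_start", "trial_end")

setValidity("TrialEvents", function(object) {
  ev <- object@events
  msgs <- character()
  need <- c("time_s", "event", "trial_index")
  if (!all(need %in% names(ev))) {
    return(paste("events must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(ev)) {
    if (is.unsorted(ev$time_s)) msgs <- c(msgs, "event times must be non-decreasing")
    if (!all(ev$event %in% .EVENT_CODES)) {
      msgs <- c(msgs, paste("unknown event codes:",
                            paste(setdiff(unique(ev$event), .EVENT_CODES), collapse = ", ")))
    }
    tr <- sort(unique(ev$trial_index))
    if (!identical(as.integer(tr), seq_along(tr))) {
      msgs <- c(msgs, "trial indices must be contiguous from 1")
    }
    starts <- ev$trial_index[ev$event == "trial_start"]
    ends <- ev$trial_index[ev$event == "trial_end"]
    if (length(setdiff(ends, starts))) {
      msgs <- c(msgs, "every trial_end must have a matching trial_start")
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' PhotometryRecording: two-channel fluorescence recording
#'
#' Aligned dopamine-sensitive (470 nm) and isosbestic control (405 nm)
#' channels sampled at a common rate. Synthetic recordings carry their
#' planted ground truth in `groundTruth`.
#'
#' @slot signal470 numeric vector, dopamine-sensitive fluorescence.
#' @slot iso405 numeric vector, isosbestic control, same length.
#' @slot fs sampling rate in Hz.
#' @slot t0 time of the first sample in seconds.
#' @slot groundTruth list of planted-signal metadata (may be empty).
#' @exportClass PhotometryRecording
setClass("PhotometryRecording",
         representation(signal470 = "numeric", iso405 = "numeric",
                        fs = "numeric", t0 = "numeric", groundTruth = "list"))

setValidity("PhotometryRecording", function(object) {
  msgs <- character()
  if (length(object@signal470) != length(object@iso405)) {
    msgs <- c(msgs, "channels must have equal length")
  }
  if (length(object@fs) != 1L || object@fs <= 0) msgs <- c(msgs, "fs must be a positive scalar")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' SpikeSession: sorted single-unit spike times plus session metadata
#'
#' @slot spikes named list; one sorted numeric vector of spike times
#'   (seconds) per unit.
#' @slot duration session duration in seconds.
#' @slot groupLabel treatment group, "CTRL" or "PCE".
#' @slot sex "F" or "M".
#' @slot profiles character vector of planted ground-truth encoding profiles
#'   per unit (empty for real data).
#' @exportClass SpikeSession
setClass("SpikeSession",
         representation(spikes = "list", duration = "numeric",
                        groupLabel = "character", sex = "character",
                        profiles = "character"))

setValidity("SpikeSession", function(object) {
  msgs <- character()
  if (length(object@duration) != 1L || object@duration <= 0) {
    msgs <- c(msgs, "duration must be a positive scalar")
  }
  for (u in seq_along(object@spikes)) {
    st <- object@spikes[[u]]
    if (length(st)) {
      if (is.unsorted(st)) { msgs <- c(msgs, "spike times must be sorted"); break }
      if (min(st) < 0 || max(st) > object@duration) {
        msgs <- c(msgs, "spike times must lie within [0, duration]"); break
      }
    }
  }
  if (length(object@profiles) && length(object@profiles) != length(object@spikes)) {
    msgs <- c(msgs, "profiles must match the number of units")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' TrialTensor: unit x trial x within-trial-time activity tensor
#'
#' @slot data numeric array of dimension U x T x P.
#' @slot unitInfo data.frame with one row per unit (at least `unit_id`;
#'   optionally `group`).
#' @slot timeAxis numeric vector of length P, seconds relative to cue onset.
#' @exportClass TrialTensor
setClass("TrialTensor",
         representation(data = "array", unitInfo = "data.frame",
                        timeAxis = "numeric"))

setValidity("TrialTensor", function(object) {
  d <- dim(object@data)
  msgs <- character()
  if (length(d) != 3L) msgs <- c(msgs, "data must be a 3-way array")
  else {
    if (d[2] < 2L) msgs <- c(msgs, "need at least 2 trials")
    if (nrow(object@unitInfo) && nrow(object@unitInfo) != d[1]) {
      msgs <- c(msgs, "unitInfo rows must match the unit dimension")
    }
    if (length(object@timeAxis) && length(object@timeAxis) != d[3]) {
      msgs <- c(msgs, "timeAxis must match the time dimension")
    }
  }
  if (any(!is.finite(object@data))) msgs <- c(msgs, "tensor entries must be finite")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' CPModel: canonical polyadic decomposition of a trial tensor
#'
#' Reconstruction is X_hat[u,t,p] = sum_r W[u,r] * B[t,r] * A[p,r]. After
#' fitting, component scale is concentrated into the unit factors `W` while
#' trial (`B`) and time (`A`) factor columns are unit-norm, resolving the CP
#' scale ambiguity so unit loadings are comparable across groups.
#'
#' @slot W unit-factor matrix (U x r), carries component scale.
#' @slot B trial-factor matrix (T x r), unit-norm columns.
#' @slot A within-trial time-factor matrix (P x r), unit-norm columns.
#' @slot rank number of components r.
#' @slot objective numeric vector, per-sweep sum of squared residuals
#'   (non-increasing).
#' @exportClass CPModel
setClass("CPModel",
         representation(W = "matrix", B = "matrix", A = "matrix",
                        rank = "integer", objective = "numeric"))

setValidity("CPModel", function(object) {
  r <- object@rank
  if (ncol(object@W) != r || ncol(object@B) != r || ncol(object@A) != r) {
    return("all factor matrices must have 'rank' columns")
  }
  if (length(object@objective) > 1L &&
      any(diff(object@objective) > 1e-8 * (1 + object@objective[1]))) {
    return("objective trace must be non-increasing")
  }
  TRUE
})

#' DemandFit: fitted exponential model of demand for one subject
#'
#' Model: log10 Q(price) = log10 Q0 + k * (exp(-alpha * Q0 * price) - 1).
#' Derived quantities: EV = 1 / (alpha * k^1.5 * 100) and
#' Pmax = 1 / (Q0 * alpha * k^1.5) * (0.083 * k + 0.65).
#'
#' @slot Q0 maximal demand at zero cost (rewards).
#' @slot alpha rate of decline in relative consumption (1 / (price*reward)).
#' @slot k log10-range scaling constant.
#' @slot EV essential value (dimensionless).
#' @slot Pmax price at the transition from inelastic to elastic demand.
#' @slot r2 goodness of fit in log10 space.
#' @slot kPolicy how k was set: "shared_pooled", "fixed" or "per_subject".
#' @slot data data.frame of the fitted observations (price, consumption).
#' @exportClass DemandFit
setClass("DemandFit",
         representation(Q0 = "numeric", alpha = "numeric", k = "numeric",
                        EV = "numeric", Pmax = "numeric", r2 = "numeric",
                        kPolicy = "character", data = "data.frame"))

setValidity("DemandFit", function(object) {
  if (object@Q0 <= 0 || object@alpha <= 0 || object@k <= 0) {
    return("Q0, alpha and k must all be positive")
  }
  TRUE
})

#' ClusterModel: encoding patterns discovered by iterative k-means
#'
#' @slot k final number of encoding clusters (nonencoding excluded).
#' @slot assignments character vector per unit: a cluster label such as
#'   "cue_activated" or "nonencoding".
#' @slot centroids matrix (clusters x features) in raw feature units.
#' @slot centroidsStd matrix (clusters x features) in standardized units.
#' @slot featureNames character vector naming the feature columns.
#' @slot history data.frame of the k-growth iterations (k tried, redundancy
#'   score, stopped).
#' @exportClass ClusterModel
setClass("ClusterModel",
         representation(k = "integer", assignments = "character",
                        centroids = "matrix", centroidsStd = "matrix",
                        featureNames = "character", history = "data.frame"))

setValidity("ClusterModel", function(object) {
  if (object@k < 1L) return("k must be at least 1")
  TRUE
})

# ---- show methods ---------------------------------------------------------

setMethod("show", "TrialEvents", function(object) {
  ev <- object@events
  cat("TrialEvents:", nrow(ev), "events,",
      if (nrow(ev)) max(ev$trial_index) else 0L, "trials,",
      if (nrow(ev)) sprintf("%.1f s", max(ev$time_s)) else "0 s", "span\n")
  if (nrow(ev)) {
    tab <- table(ev$event)
    cat("  ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  }
})

setMethod("show", "PhotometryRecording", function(object) {
  cat(sprintf("PhotometryRecording: %d samples @ %g Hz (%.1f s)\n",
              length(object@signal470), object@fs,
              length(object@signal470) / object@fs))
  if (length(object@groundTruth)) {
    cat("  with planted ground truth (",
        length(object@groundTruth$transient_times), " transients)\n", sep = "")
  }
})

setMethod("show", "SpikeSession", function(object) {
  cat(sprintf("SpikeSession: %d units over %.1f s [%s/%s]\n",
              length(object@spikes), object@duration,
              object@groupLabel, object@sex))
  if (length(object@profiles)) {
    tab <- table(object@profiles)
    cat("  planted profiles:", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  }
})

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@data)
  cat(sprintf("TrialTensor: %d units x %d trials x %d time bins\n",
              d[1], d[2], d[3]))
})

setMethod("show", "CPModel", function(object) {
  cat(sprintf("CPModel: rank %d, dims %d x %d x %d, final SSE %.4g (%d sweeps)\n",
              object@rank, nrow(object@W), nrow(object@B), nrow(object@A),
              utils::tail(object@objective, 1), length(object@objective)))
})

setMethod("show", "DemandFit", function(object) {
  cat(sprintf(
    "DemandFit: Q0 = %.3f, alpha = %.5g, k = %.3f (%s)\n  EV = %.4f, Pmax = %.3f, r2 = %.3f\n",
    object@Q0, object@alpha, object@k, object@kPolicy,
    object@EV, object@Pmax, object@r2))
})

setMethod("show", "ClusterModel", function(object) {
  tab <- table(object@assignments)
  cat(sprintf("ClusterModel: k = %d encoding patterns, %d units\n",
              object@k, length(object@assignments)))
  cat("  ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
})
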