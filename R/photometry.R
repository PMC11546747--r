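# Fiber-photometry processing: isosbestic detrending, peri-event z-scored
# PSTHs, window metrics, and spontaneous transient detection.

#' Default peri-event analysis windows
#'
#' Baseline -4 to -2 s relative to cue onset; cue window 0 to 2 s; reward
#' window 2 to 7 s for food (2 to 8 s for drug infusions); PSTH spans -4 to
#' +8 s. All intervals are half-open [start, end).
#'
#' @param reward_end end of the consumption window (7 s food, 8 s drug).
#' @return list of class "WindowSpec".
#' @export
windowSpec <- function(reward_end = 7) {
  ws <- list(baseline = c(-4, -2), cue = c(0, 2), reward = c(2, reward_end),
             psth_span = c(-4, 8))
  if (ws$baseline[2] > ws$cue[1]) stop("baseline must precede the cue window")
  structure(ws, class = "WindowSpec")
}

#' Isosbestic detrending of a photometry recording
#'
#' Removes bleaching and motion artifacts by scaling the isosbestic control
#' channel (405 nm) and regressing it onto the dopamine-sensitive channel
#' (470 nm) with ordinary least squares over the full session. The corrected
#' trace is dF/F = (signal - fitted_iso) / fitted_iso (the processing-script
#' convention); `mode = "subtract"` returns the raw residual instead. An
#' optional zero-phase Butterworth low-pass (default 6 Hz, order 6) is
#' applied to both channels first.
#'
#' @param rec a \linkS4class{PhotometryRecording}.
#' @param lowpass_hz low-pass cutoff in Hz, or `NULL` to skip filtering.
#' @param filter_order Butterworth order (default 6).
#' @param mode "divide" for dF/F (default) or "subtract" for the residual.
#' @return numeric vector, the corrected trace; the fitted coefficients are
#'   attached as attribute "fit".
#' @examples
#' rec <- genPhotometrySession(list(duration = 20, transient_times = 5,
#'                                  seed = 1))
#' dff <- detrendIsosbestic(rec)
#' @export
detrendIsosbestic <- function(rec, lowpass_hz = NULL, filter_order = 6L,
                              mode = c("divide", "subtract")) {
  mode <- match.arg(mode)
  sig <- signalChannel(rec)
  iso <- isoChannel(rec)
  if (length(sig) < 2L) stop("recording too short to detrend")
  if (any(!is.finite(sig)) || any(!is.finite(iso))) {
    stop("channels must be finite")
  }
  if (!is.null(lowpass_hz)) {
    sig <- filtfiltButter(sig, lowpass_hz, samplingRate(rec), filter_order)
    iso <- filtfiltButter(iso, lowpass_hz, samplingRate(rec), filter_order)
  }
  if (stats::sd(iso) < .Machine$double.eps * max(abs(iso), 1)) {
    stop("degenerate regression: isosbestic channel has zero variance")
  }
  fit <- stats::lm.fit(cbind(1, iso), sig)
  fitted <- drop(cbind(1, iso) %*% fit$coefficients)
  out <- if (mode == "divide") (sig - fitted) / fitted else sig - fitted
  attr(out, "fit") <- c(intercept = unname(fit$coefficients[1]),
                        slope = unname(fit$coefficients[2]))
  out
}

#' Peri-event z-scored PSTH
#'
#' For each event, the trace segment over the PSTH span is z-scored against
#' that trial's own baseline window: z = (x - baseline_mean) / baseline_sd.
#' Trials whose span is not fully covered by the trace are dropped with a
#' warning.
#'
#' @param trace numeric vector (corrected fluorescence or any signal).
#' @param events event times in seconds.
#' @param fs sampling rate of `trace` in Hz.
#' @param windows a \code{\link{windowSpec}}.
#' @param t0 time of the first trace sample (default 0).
#' @return list of class "EventPSTH": `z` (trial x time matrix), `time`
#'   (s relative to event), `baseline_stats` (per-trial mean and sd of the
#'   raw baseline samples), `events_used`.
#' @export
eventPSTH <- function(trace, events, fs, windows = windowSpec(), t0 = 0) {
  if (!length(events)) stop("no events supplied")
  span <- windows$psth_span
  n <- length(trace)
  rel_idx <- seq(floor(span[1] * fs), ceiling(span[2] * fs) - 1L)
  time <- rel_idx / fs
  keep <- logical(length(events))
  rows <- list()
  stats_m <- numeric(); stats_s <- numeric()
  bl <- windows$baseline
  for (i in seq_along(events)) {
    center <- round((events[i] - t0) * fs) + 1L
    idx <- center + rel_idx
    if (idx[1] < 1L || idx[length(idx)] > n) next
    x <- trace[idx]
    in_bl <- time >= bl[1] & time < bl[2]
    m <- mean(x[in_bl]); s <- stats::sd(x[in_bl])
    if (!is.finite(s) || s == 0) {
      stop(sprintf("zero baseline variance for trial %d", i))
    }
    keep[i] <- TRUE
    rows[[length(rows) + 1L]] <- (x - m) / s
    stats_m <- c(stats_m, m); stats_s <- c(stats_s, s)
  }
  if (!length(rows)) stop("no event has full PSTH span coverage")
  if (any(!keep)) {
    warning(sprintf("dropped %d trial(s) with incomplete PSTH span",
                    sum(!keep)))
  }
  structure(list(z = do.call(rbind, rows), time = time,
                 baseline_stats = data.frame(mean = stats_m, sd = stats_s),
                 events_used = events[keep], windows = windows),
            class = "EventPSTH")
}

#' @export
print.EventPSTH <- function(x, ...) {
  cat(sprintf("EventPSTH: %d trials x %d samples, span [%g, %g] s\n",
              nrow(x$z), ncol(x$z), min(x$time), max(x$time)))
  invisible(x)
}

#' AUC and peak of the trial-averaged PSTH in a window
#'
#' AUC is the trapezoidal integral of the trial-averaged z trace over the
#' window (endpoints interpolated exactly, so a constant z = 1 over a 2-s
#' window gives AUC = 2 z*s); peak is the maximum of the averaged trace in
#' the window.
#'
#' @param psth an "EventPSTH" (or any list with `z` matrix and `time`).
#' @param window numeric length-2, seconds relative to the event.
#' @return list with `auc` (z*s) and `peak` (z).
#' @export
windowMetrics <- function(psth, window) {
  if (length(window) != 2L || !(window[2] > window[1])) {
    stop("'window' must be an increasing [start, end] pair")
  }
  if (window[1] < min(psth$time) || window[2] > max(psth$time)) {
    stop("window outside PSTH span")
  }
  avg <- colMeans(psth$z)
  inwin <- psth$time >= window[1] & psth$time < window[2]
  list(auc = trapzWindow(psth$time, avg, window),
       peak = max(avg[inwin]))
}

#' Detect spontaneous transients by topographic peak prominence
#'
#' Local maxima whose topographic prominence reaches `min_prominence` are
#' returned with their time and amplitude. Units follow the trace's units:
#' % dF/F0 for spontaneous fluorescence analysis, z for PSTH-based analysis.
#'
#' @param trace numeric vector.
#' @param fs sampling rate (Hz).
#' @param min_prominence detection threshold (default 1).
#' @param t0 time of the first sample (s).
#' @return data.frame `time_s`, `amplitude`, `prominence` (possibly empty).
#' @export
detectTransients <- function(trace, fs, min_prominence = 1, t0 = 0) {
  if (any(!is.finite(trace))) stop("trace must be finite")
  pk <- peakProminences(trace)
  pk <- pk[pk$prominence >= min_prominence, , drop = FALSE]
  data.frame(time_s = t0 + (pk$index - 1) / fs,
             amplitude = pk$value,
             prominence = pk$prominence)
}
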