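# Seeded synthetic-data generators with planted ground truth. Every
# downstream stage of the pipeline is testable against these without any
# recorded data: photometry traces with shared artifacts and planted
# dopamine transients, inhomogeneous-Poisson spike sessions with planted
# encoding profiles, low-rank trial tensors, and exponential-demand
# consumption tables.

#' Generate a synthetic two-channel photometry session
#'
#' Both channels share a multiplicative exponential bleaching trend and an
#' additive band-limited motion artifact (channel-specific gain); dopamine
#' transients — difference-of-exponentials kernels — ride only on the
#' 470 nm signal channel. The planted transient list is attached as ground
#' truth.
#'
#' @param spec list with fields `fs` (Hz, default 100), `duration` (s),
#'   `artifact_amp` (fraction of baseline, default 0.02), `bleach_tau` (s,
#'   default 1200), `transient_times` (s), `transient_amp` (dF/F fraction,
#'   default 0.05), `transient_rise_tau` (s, default 0.1),
#'   `transient_decay_tau` (s, default 0.5), `noise_sd` (dF/F fraction,
#'   default 0.003), `seed`.
#' @param events optional \linkS4class{TrialEvents}; cue onsets are added to
#'   `transient_times` when supplied.
#' @return a \linkS4class{PhotometryRecording} with `groundTruth` holding the
#'   planted transient times/amplitude and artifact components.
#' @examples
#' rec <- genPhotometrySession(list(duration = 60, transient_times = c(10, 30),
#'                                  seed = 1))
#' samplingRate(rec)
#' @export
genPhotometrySession <- function(spec, events = NULL) {
  fs <- spec$fs %||% 100
  duration <- spec$duration
  if (is.null(duration) || duration <= 0) stop("spec$duration must be positive")
  if (fs <= 0) stop("spec$fs must be positive")
  artifact_amp <- spec$artifact_amp %||% 0.02
  bleach_tau <- spec$bleach_tau %||% 1200
  rise <- spec$transient_rise_tau %||% 0.1
  decay <- spec$transient_decay_tau %||% 0.5
  if (bleach_tau <= 0 || rise <= 0 || decay <= 0) stop("time constants must be positive")
  amp <- spec$transient_amp %||% 0.05
  noise_sd <- spec$noise_sd %||% 0.003
  tt <- spec$transient_times %||% numeric()
  if (!is.null(events)) tt <- sort(c(tt, eventTimes(events, "cue_on")))
  if (length(tt) && (min(tt) < 0 || max(tt) >= duration)) {
    stop("transient times must lie within [0, duration)")
  }
  seed <- spec$seed %||% 1L

  n <- floor(duration * fs)
  t <- (seq_len(n) - 1) / fs
  base470 <- 1.0
  base405 <- 0.8
  bleach <- exp(-t / bleach_tau)

  withSeed(seed, {
    # band-limited motion artifact: white noise smoothed to ~2 Hz bandwidth,
    # shared between channels with channel-specific gains
    raw <- stats::rnorm(n)
    artifact <- filtfiltButter(raw, cutoff_hz = min(2, fs / 4), fs = fs,
                               order = 2L)
    artifact <- artifact / max(stats::sd(artifact), .Machine$double.eps) *
      artifact_amp
    # difference-of-exponentials transient kernel, unit peak
    klen <- ceiling(6 * decay * fs)
    kt <- (0:klen) / fs
    kern <- exp(-kt / decay) - exp(-kt / rise)
    kern <- kern / max(kern)
    transients <- numeric(n)
    for (tau in tt) {
      i0 <- floor(tau * fs) + 1L
      idx <- i0:min(n, i0 + klen)
      transients[idx] <- transients[idx] + amp * kern[seq_along(idx)]
    }
    sig <- base470 * bleach * (1 + transients) + base470 * artifact +
      stats::rnorm(n, sd = noise_sd)
    iso <- base405 * bleach + base405 * artifact +
      stats::rnorm(n, sd = noise_sd)
    new("PhotometryRecording", signal470 = sig, iso405 = iso,
        fs = fs, t0 = 0,
        groundTruth = list(transient_times = tt, transient_amp = amp,
                           bleach = bleach, artifact = artifact,
                           noise_sd = noise_sd))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.PROFILES <- c("cue_activated", "cue_inhibited", "reward_activated",
               "reward_inhibited", "press_inhibited", "nonencoding")

# plateau modulation kernel on [t0, t1]: cosine ramps over the outer 15% of
# the window, full modulation in between — so the window-averaged rate of a
# gain-g unit is close to g times baseline
.windowKernel <- function(t, t0, t1) {
  w <- t1 - t0
  ramp <- 0.15 * w
  out <- numeric(length(t))
  x <- t - t0
  inside <- x >= 0 & x <= w
  xi <- x[inside]
  v <- rep(1, length(xi))
  up <- xi < ramp
  v[up] <- 0.5 * (1 - cos(pi * xi[up] / ramp))
  dn <- xi > w - ramp
  v[dn] <- 0.5 * (1 - cos(pi * (w - xi[dn]) / ramp))
  out[inside] <- v
  out
}

# peri-event rate modulation factor for one profile at peri-cue time t
# (seconds relative to cue onset); drift scales the modulation depth
.profileGain <- function(profile, t, gain, drift) {
  mod <- switch(profile,
    cue_activated    = (gain - 1) * .windowKernel(t, 0, 2),
    cue_inhibited    = -0.85 * .windowKernel(t, 0, 2),
    reward_activated = (gain - 1) * .windowKernel(t, 2, 6),
    reward_inhibited = -0.85 * .windowKernel(t, 2, 6),
    press_inhibited  = -0.85 * .windowKernel(t, 1, 4),
    nonencoding      = numeric(length(t)),
    stop(sprintf("unknown profile '%s'", profile))
  )
  1 + drift * mod
}

#' Generate a synthetic spike session with planted encoding profiles
#'
#' Units fire as inhomogeneous Poisson processes. Each unit is assigned one
#' of the encoding profiles (cue-activated/inhibited, reward-
#' activated/inhibited, press-inhibited, nonencoding); activated units
#' multiply their baseline rate by `gain` inside the profile's peri-cue
#' window, inhibited units suppress firing there. Cue-activated modulation is
#' additionally scaled by `trial_drift(trial)` to emulate across-trial gain
#' decline. Spikes are generated by thinning a homogeneous process, so the
#' planted rate function is the exact ground-truth intensity.
#'
#' @param spec list with fields `n_units`, `profile_mix` (named proportions
#'   over the profiles, summing to 1), `baseline_rate_range` (Hz, default
#'   c(2, 10)), `gain` (default 3), `trial_drift` (function of trial index
#'   -> multiplier in (0, 1], default constant 1), `seed`.
#' @param events a \linkS4class{TrialEvents} with cue_on events.
#' @return a \linkS4class{SpikeSession}; planted profiles are in
#'   \code{unitProfiles()}, per-unit baseline rates in the session's
#'   `profiles` attribute order.
#' @export
genSpikeSession <- function(spec, events) {
  if (is.null(events) || nTrials(events) == 0L) stop("'events' must contain trials")
  n_units <- spec$n_units
  if (is.null(n_units) || n_units < 1) stop("spec$n_units must be >= 1")
  mix <- spec$profile_mix
  if (is.null(mix)) mix <- c(cue_activated = 0.25, cue_inhibited = 0.25,
                             reward_activated = 0.25, reward_inhibited = 0.25)
  if (!all(names(mix) %in% .PROFILES)) {
    stop("unknown profile in profile_mix: ",
         paste(setdiff(names(mix), .PROFILES), collapse = ", "))
  }
  if (abs(sum(mix) - 1) > 1e-8) stop("profile_mix proportions must sum to 1")
  rate_range <- spec$baseline_rate_range %||% c(2, 10)
  if (any(rate_range <= 0)) stop("baseline rates must be positive")
  gain <- spec$gain %||% 3
  drift_fn <- spec$trial_drift %||% function(trial) rep(1, length(trial))
  seed <- spec$seed %||% 1L

  cues <- eventTimes(events, "cue_on")
  duration <- max(eventTable(events)$time_s) + 10
  window <- c(-2, 8)   # modulation confined to the peri-cue analysis span

  withSeed(seed, {
    # deterministic profile counts (largest remainder), shuffled order
    counts <- floor(mix * n_units)
    rem <- n_units - sum(counts)
    if (rem > 0) {
      frac <- mix * n_units - counts
      add <- order(frac, decreasing = TRUE)[seq_len(rem)]
      counts[add] <- counts[add] + 1
    }
    profiles <- sample(rep(names(mix), counts))
    base_rates <- stats::runif(n_units, rate_range[1], rate_range[2])
    max_gain <- max(gain, 1) + 0.01

    spikes <- vector("list", n_units)
    for (u in seq_len(n_units)) {
      lambda_max <- base_rates[u] * max_gain
      n_cand <- stats::rpois(1L, lambda_max * duration)
      cand <- sort(stats::runif(n_cand, 0, duration))
      # peri-cue time and trial index of each candidate spike (events are
      # spaced so windows do not overlap)
      rel <- rep(NA_real_, length(cand))
      tri <- rep(NA_integer_, length(cand))
      for (ci in seq_along(cues)) {
        in_win <- cand >= cues[ci] + window[1] & cand < cues[ci] + window[2]
        rel[in_win] <- cand[in_win] - cues[ci]
        tri[in_win] <- ci
      }
      g <- rep(1, length(cand))
      idx <- !is.na(rel)
      if (any(idx)) {
        g[idx] <- .profileGain(profiles[u], rel[idx], gain, drift_fn(tri[idx]))
      }
      keep <- stats::runif(length(cand)) < base_rates[u] * g / lambda_max
      spikes[[u]] <- cand[keep]
    }
    names(spikes) <- sprintf("unit_%03d", seq_len(n_units))
    sess <- new("SpikeSession", spikes = spikes, duration = duration,
                groupLabel = spec$group_label %||% "CTRL",
                sex = spec$sex %||% "F",
                profiles = profiles)
    attr(sess, "baseRates") <- base_rates
    sess
  })
}

#' Generate a low-rank synthetic trial tensor with planted CP structure
#'
#' Builds X = sum_r w_r o b_r o a_r + Gaussian noise. Within-trial factors
#' a_r are smooth bumps or dips localized to the cue (0-2 s) or reward
#' (2-7 s) windows; trial factors b_r are monotone or flat trends; unit
#' loadings are non-negative with optional group-dependent mean shifts.
#' Components are scaled to equal Frobenius norm — assemblies of comparable
#' strength — before noise is added.
#'
#' @param spec list with fields `U`, `T`, `P` (dimensions, defaults
#'   100 x 8 x 60), `r_true` (planted rank, default 4), `noise_sd` (absolute
#'   noise sd) or `snr` (signal-sd / noise-sd; used when `noise_sd` absent;
#'   default snr = 5), `group_labels` (length-U character, CTRL/PCE),
#'   `group_loading_shift` (per-component additive mean shift for PCE units,
#'   default 0), `seed`.
#' @return list with `tensor` (a \linkS4class{TrialTensor}) and `truth`
#'   (a \linkS4class{CPModel} holding the planted factors, plus the noise sd
#'   used, as attribute "noise_sd").
#' @export
genTrialTensor <- function(spec) {
  U <- spec$U %||% 100L
  Tt <- spec$T %||% 8L
  P <- spec$P %||% 60L
  r <- spec$r_true %||% 4L
  if (r > min(U, Tt, P)) stop("r_true exceeds the smallest tensor dimension")
  seed <- spec$seed %||% 1L
  shift <- spec$group_loading_shift %||% 0
  labels <- spec$group_labels %||%
    rep(c("CTRL", "PCE"), length.out = U)
  if (length(labels) != U) stop("group_labels must have length U")

  t_axis <- seq(-1, 8, length.out = P)
  # assembly templates: cue-activated, reward-activated, cue-inhibited,
  # reward-inhibited motifs (cycled if r > 4); bump centers are staggered
  # inside their windows so components are distinguishable
  templates <- list(
    list(ctr = 0.7, wid = 0.5, sign = +1, trend = "down"),
    list(ctr = 3.0, wid = 1.1, sign = +1, trend = "flat"),
    list(ctr = 1.3, wid = 0.5, sign = -1, trend = "up"),
    list(ctr = 5.0, wid = 1.1, sign = -1, trend = "flat")
  )
  withSeed(seed, {
    A <- matrix(0, P, r)
    B <- matrix(0, Tt, r)
    W <- matrix(0, U, r)
    # each unit belongs predominantly to one assembly (discrete cell
    # assemblies, as uncovered by the clustering analyses), with a small
    # background loading on the others; membership is balanced within each
    # group so that group_loading_shift = 0 means symmetric groups
    membership <- integer(U)
    for (g in unique(labels)) {
      idx <- which(labels == g)
      membership[idx] <- sample(rep(seq_len(r), length.out = length(idx)))
    }
    for (j in seq_len(r)) {
      tp <- templates[[(j - 1L) %% length(templates) + 1L]]
      ctr <- tp$ctr + stats::runif(1, -0.1, 0.1)
      A[, j] <- tp$sign * exp(-(t_axis - ctr)^2 / (2 * tp$wid^2))
      B[, j] <- switch(tp$trend,
        down = seq(1, 0.3, length.out = Tt),
        up   = seq(0.3, 1, length.out = Tt),
        flat = rep(1, Tt) + stats::runif(Tt, -0.05, 0.05))
      W[, j] <- pmax(stats::rnorm(U, mean = 0.1, sd = 0.05), 0)
      own <- membership == j
      W[own, j] <- abs(stats::rnorm(sum(own), mean = 1, sd = 0.25))
      if (shift != 0) W[labels == "PCE", j] <- W[labels == "PCE", j] + shift
    }
    # norm-balance: unit-norm B and A columns, scale in W; then equalize
    # component Frobenius norms
    for (j in seq_len(r)) {
      nb <- sqrt(sum(B[, j]^2)); na <- sqrt(sum(A[, j]^2))
      B[, j] <- B[, j] / nb; A[, j] <- A[, j] / na
      W[, j] <- W[, j] * nb * na
      W[, j] <- W[, j] / sqrt(sum(W[, j]^2))
    }
    X1 <- W %*% t(khatriRao(A, B))       # U x (T*P), trial index fastest
    signal <- array(X1, dim = c(U, Tt, P))
    noise_sd <- spec$noise_sd %||% (stats::sd(signal) / (spec$snr %||% 5))
    X <- signal + array(stats::rnorm(length(signal), sd = noise_sd),
                        dim = dim(signal))
    truth <- new("CPModel", W = W, B = B, A = A, rank = as.integer(r),
                 objective = numeric())
    attr(truth, "noise_sd") <- noise_sd
    tensor <- new("TrialTensor", data = X,
                  unitInfo = data.frame(unit_id = sprintf("unit_%03d", seq_len(U)),
                                        group = labels),
                  timeAxis = t_axis)
    list(tensor = tensor, truth = truth)
  })
}

#' Generate synthetic demand observations
#'
#' Consumption follows the exponential model of demand,
#' Q(price) = Q0 * 10^(k * (exp(-alpha * Q0 * price) - 1)), perturbed by
#' multiplicative lognormal noise (consumption is positive and count-like).
#' Additive Gaussian noise is available via `noise_model = "additive"`.
#'
#' @param spec list with fields `Q0_true`, `alpha_true`, `k_true`, `prices`
#'   (defaults to the food demand schedule), `noise_sd` (sd of log10
#'   consumption noise, default 0), `noise_model` ("lognormal" or
#'   "additive"), `seed`.
#' @return data.frame with columns `price`, `consumption`, and the ground
#'   truth attached as attribute "truth".
#' @examples
#' obs <- genDemandObservations(list(Q0_true = 50, alpha_true = 0.002,
#'                                   k_true = 2, seed = 1))
#' @export
genDemandObservations <- function(spec) {
  Q0 <- spec$Q0_true; alpha <- spec$alpha_true; k <- spec$k_true
  if (is.null(Q0) || is.null(alpha) || is.null(k) ||
      Q0 <= 0 || alpha <= 0 || k <= 0) {
    stop("Q0_true, alpha_true and k_true must all be positive")
  }
  prices <- spec$prices %||% demandPriceSchedule("food_demand")
  noise_sd <- spec$noise_sd %||% 0
  model <- spec$noise_model %||% "lognormal"
  seed <- spec$seed %||% 1L
  q <- Q0 * 10^(k * (exp(-alpha * Q0 * prices) - 1))
  withSeed(seed, {
    consumption <- if (noise_sd == 0) q
      else if (model == "lognormal") q * 10^stats::rnorm(length(q), sd = noise_sd)
      else pmax(0, q + stats::rnorm(length(q), sd = noise_sd * q))
    out <- data.frame(price = prices, consumption = consumption)
    attr(out, "truth") <- list(Q0 = Q0, alpha = alpha, k = k)
    out
  })
}
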