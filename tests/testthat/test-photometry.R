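# Isosbestic detrending, peri-event z-scored PSTHs, window metrics, and
# transient detection.

test_that("detrending removes a pure shared artifact to numerical zero", {
  iso <- operantNeuro:::withSeed(1, cumsum(rnorm(2000)) / 40 + 10)
  rec <- new("PhotometryRecording", signal470 = 2 * iso, iso405 = iso,
             fs = 100, t0 = 0, groundTruth = list())
  dff <- detrendIsosbestic(rec)
  expect_lt(max(abs(dff)), 1e-10)
})

test_that("detrending recovers a planted transient within 10%", {
  rec <- genPhotometrySession(list(duration = 120,
                                   transient_times = seq(10, 110, by = 10),
                                   transient_amp = 0.05, noise_sd = 0.001,
                                   seed = 3))
  dff <- detrendIsosbestic(rec)
  peaks <- vapply(seq(10, 110, by = 10), function(t0) {
    max(dff[(t0 * 100):(t0 * 100 + 100)])
  }, numeric(1))
  expect_lt(abs(mean(peaks) - 0.05) / 0.05, 0.1)
})

test_that("uncorrelated isosbestic noise fits with near-zero slope", {
  set.seed(12)
  n <- 5000
  sig <- rnorm(n, mean = 1, sd = 0.01)
  iso <- rnorm(n, mean = 0.8, sd = 0.01)
  rec <- new("PhotometryRecording", signal470 = sig, iso405 = iso,
             fs = 100, t0 = 0, groundTruth = list())
  dff <- detrendIsosbestic(rec)
  slope <- attr(dff, "fit")["slope"]
  se <- 0.01 / (0.01 * sqrt(n))   # sd(sig)/ (sd(iso) sqrt(n))
  expect_lt(abs(slope), 3 * se)
})

test_that("subtraction-mode detrending is idempotent; divide mode refits to zero slope", {
  rec <- genPhotometrySession(list(duration = 30, transient_times = c(5, 20),
                                   seed = 6))
  r1 <- detrendIsosbestic(rec, mode = "subtract")
  rec2 <- new("PhotometryRecording", signal470 = as.numeric(r1),
              iso405 = isoChannel(rec), fs = samplingRate(rec), t0 = 0,
              groundTruth = list())
  r2 <- detrendIsosbestic(rec2, mode = "subtract")
  expect_lt(max(abs(r2 - r1)), 1e-8)
  # divide mode: residual is uncorrelated with the isosbestic channel
  d1 <- detrendIsosbestic(rec)
  recd <- new("PhotometryRecording", signal470 = as.numeric(d1),
              iso405 = isoChannel(rec), fs = samplingRate(rec), t0 = 0,
              groundTruth = list())
  refit <- detrendIsosbestic(recd, mode = "subtract")
  expect_lt(abs(attr(refit, "fit")["slope"]) * stats::sd(isoChannel(rec)) /
              stats::sd(d1), 0.05)
})

test_that("detrending error contracts hold", {
  rec <- new("PhotometryRecording", signal470 = rnorm(100),
             iso405 = rep(1, 100), fs = 10, t0 = 0, groundTruth = list())
  expect_error(detrendIsosbestic(rec), "zero variance")
})

test_that("the optional low-pass is zero-phase and attenuates above cutoff", {
  fs <- 100; t <- (0:2999) / fs
  lo <- sin(2 * pi * 1 * t); hi <- sin(2 * pi * 20 * t)
  yl <- operantNeuro:::filtfiltButter(lo, 6, fs, 6L)
  yh <- operantNeuro:::filtfiltButter(hi, 6, fs, 6L)
  expect_gt(stats::sd(yl) / stats::sd(lo), 0.98)
  expect_lt(stats::sd(yh) / stats::sd(hi), 0.05)
  # zero phase: the passband peak does not shift
  expect_lt(abs(which.max(yl[100:200]) - which.max(lo[100:200])), 2)
})

test_that("event PSTHs are z-scored against each trial's own baseline", {
  set.seed(3)
  fs <- 50
  trace <- rnorm(60 * fs, mean = 5)
  events <- c(10, 25, 40)
  ps <- eventPSTH(trace, events, fs)
  bl <- ps$time >= -4 & ps$time < -2
  # baseline-window mean exactly 0 and sd exactly 1 per trial
  expect_lt(max(abs(rowMeans(ps$z[, bl]))), 1e-12)
  expect_equal(apply(ps$z[, bl], 1, stats::sd), rep(1, 3), tolerance = 1e-12)

  # constant trace: zero-variance error naming the trial
  expect_error(eventPSTH(rep(1, 60 * fs), events, fs), "trial 1")
  # incomplete span dropped with a warning
  expect_warning(ps2 <- eventPSTH(trace, c(2, 25), fs), "incomplete")
  expect_identical(nrow(ps2$z), 1L)
  expect_error(suppressWarnings(eventPSTH(trace, 1, fs)), "coverage")
})

test_that("planted cue responses appear at the expected z amplitude", {
  # 3-sigma bump on unit-sd noise -> trial-averaged peak z near 3
  set.seed(8)
  fs <- 50
  events <- seq(10, 10 + 13 * 35, by = 35)   # 14 events... use 40 trials
  events <- seq(10, 10 + 39 * 14, by = 14)
  n <- (max(events) + 10) * fs
  trace <- rnorm(n)
  for (e in events) {
    idx <- round(e * fs):round((e + 0.6) * fs)
    trace[idx] <- trace[idx] + 3
  }
  ps <- eventPSTH(trace, events, fs)
  peak <- max(colMeans(ps$z))
  expect_lt(abs(peak - 3) / 3, 0.2)
})

test_that("window metrics integrate the trial-averaged trace exactly", {
  time <- seq(-4, 8, by = 0.05)
  zc <- matrix(rep(as.numeric(time >= 0 & time <= 2), 3), nrow = 3,
               byrow = TRUE)
  psth <- list(z = zc, time = time)
  m <- windowMetrics(psth, c(0, 2))
  expect_equal(m$auc, 2.0, tolerance = 1e-12)
  expect_equal(m$peak, 1.0)

  # symmetric triangle, peak 4 over [0, 2]: area 4, peak 4
  tri <- pmax(0, 4 * (1 - abs(time - 1)))
  psth2 <- list(z = rbind(tri, tri), time = time)
  m2 <- windowMetrics(psth2, c(0, 2))
  expect_equal(m2$auc, 4.0, tolerance = 1e-12)
  expect_equal(m2$peak, 4.0)

  expect_error(windowMetrics(psth, c(7, 9)), "outside")
  expect_error(windowMetrics(psth, c(2, 2)), "window")
})

test_that("transient detection honors topographic prominence", {
  expect_identical(nrow(detectTransients(rep(0, 500), 100)), 0L)
  # 5 planted peaks of prominence 2 on a quiet baseline
  tr <- numeric(2000)
  tr[c(200, 600, 1000, 1400, 1800)] <- 2
  sm <- operantNeuro:::filtfiltButter(tr, 6, 100)
  sm <- sm / max(sm) * 2
  d <- detectTransients(sm, 100, min_prominence = 1)
  expect_identical(nrow(d), 5L)
  expect_equal(d$time_s, c(200, 600, 1000, 1400, 1800) / 100 - 0.01,
               tolerance = 0.05)
  # sub-threshold peaks yield nothing
  expect_identical(nrow(detectTransients(sm / 4, 100, min_prominence = 1)),
                   0L)
  # count is monotone non-increasing in the threshold
  set.seed(5)
  noisy <- operantNeuro:::filtfiltButter(rnorm(3000, sd = 1.5), 4, 100)
  counts <- vapply(c(0.2, 0.5, 1, 2), function(p) {
    nrow(detectTransients(noisy, 100, min_prominence = p))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("doubled planted cue amplitude doubles the measured peak (20 replicates)", {
  ratios <- vapply(1:20, function(s) {
    specA <- list(duration = 130, transient_times = seq(10, 120, by = 10),
                  transient_amp = 0.06, noise_sd = 0.004, seed = s)
    specB <- specA; specB$transient_amp <- 0.03; specB$seed <- s + 100L
    peak <- function(spec) {
      rec <- genPhotometrySession(spec)
      ps <- eventPSTH(detrendIsosbestic(rec), spec$transient_times,
                      samplingRate(rec))
      windowMetrics(ps, c(0, 2))$peak
    }
    peak(specA) / peak(specB)
  }, numeric(1))
  expect_true(all(ratios >= 1.6 & ratios <= 2.4))
})
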