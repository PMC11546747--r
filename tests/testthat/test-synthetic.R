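# Synthetic-data generators: seeded determinism and planted ground truth.

test_that("photometry generator plants transients on the signal channel only", {
  spec <- list(duration = 30, transient_times = c(5, 15, 25),
               transient_amp = 0.05, noise_sd = 0.002, seed = 2)
  rec <- genPhotometrySession(spec)
  expect_s4_class(rec, "PhotometryRecording")
  expect_length(signalChannel(rec), 3000L)
  gt <- groundTruth(rec)
  expect_equal(gt$transient_times, c(5, 15, 25))

  # zero amplitude: channels differ only by independent noise around their
  # shared structure (no planted signal)
  spec0 <- spec; spec0$transient_amp <- 0
  rec0 <- genPhotometrySession(spec0)
  resid <- detrendIsosbestic(rec0, mode = "subtract")
  expect_lt(stats::sd(resid), 3 * spec0$noise_sd)

  # determinism
  rec2 <- genPhotometrySession(spec)
  expect_identical(signalChannel(rec), signalChannel(rec2))
  expect_identical(isoChannel(rec), isoChannel(rec2))
  expect_error(genPhotometrySession(list(duration = 10,
                                         transient_times = 12, seed = 1)),
               "within")
})

test_that("photometry channels share their artifact (correlation >= 0.99 noiseless)", {
  spec <- list(duration = 60, transient_amp = 0, noise_sd = 0,
               artifact_amp = 0.05, seed = 5)
  rec <- genPhotometrySession(spec)
  gt <- groundTruth(rec)
  art470 <- signalChannel(rec) - 1.0 * gt$bleach
  art405 <- isoChannel(rec) - 0.8 * gt$bleach
  expect_gte(stats::cor(art470, art405), 0.99)
})

test_that("spike generator plants the requested encoding profiles", {
  ev <- makeCueEvents(120)
  spec <- list(n_units = 1L, profile_mix = c(cue_activated = 1),
               baseline_rate_range = c(6, 6), gain = 3, seed = 7)
  sess <- genSpikeSession(spec, ev)
  st <- spikeTimes(sess)[[1]]
  cues <- eventTimes(ev, "cue_on")
  # plateau window [0.35, 1.65] vs pre-cue baseline [-2, 0)
  n_win <- sum(vapply(cues, function(c0) {
    sum(st >= c0 + 0.35 & st < c0 + 1.65)
  }, numeric(1)))
  n_base <- sum(vapply(cues, function(c0) {
    sum(st >= c0 - 2 & st < c0)
  }, numeric(1)))
  ratio <- (n_win / 1.3) / (n_base / 2)
  se <- ratio * sqrt(1 / n_win + 1 / n_base)
  expect_lt(abs(ratio - 3), 2 * se + 0.05)

  # all-nonencoding: peri-cue rate flat within Poisson error
  specN <- list(n_units = 8L, profile_mix = c(nonencoding = 1),
                baseline_rate_range = c(6, 6), seed = 8)
  sessN <- genSpikeSession(specN, ev)
  for (u in spikeTimes(sessN)[1:3]) {
    n_win <- sum(vapply(cues, function(c0) sum(u >= c0 & u < c0 + 2),
                        numeric(1)))
    n_base <- sum(vapply(cues, function(c0) sum(u >= c0 - 2 & u < c0),
                         numeric(1)))
    expect_lt(abs(n_win - n_base) / sqrt(n_win + n_base), 3.5)
  }

  # determinism and error contract
  sess2 <- genSpikeSession(spec, ev)
  expect_identical(spikeTimes(sess), spikeTimes(sess2))
  expect_error(genSpikeSession(spec, NULL), "trials")
  expect_error(genSpikeSession(list(n_units = 2,
                                    profile_mix = c(flying = 1), seed = 1),
                               ev),
               "unknown profile")
})

test_that("trial-drift scales cue-activated modulation across trials", {
  ev <- makeCueEvents(100)
  drift <- function(tr) 1 - 0.6 * (tr - 1) / 99      # 1 -> 0.4
  spec <- list(n_units = 1L, profile_mix = c(cue_activated = 1),
               baseline_rate_range = c(8, 8), gain = 3,
               trial_drift = drift, seed = 3)
  sess <- genSpikeSession(spec, ev)
  st <- spikeTimes(sess)[[1]]
  cues <- eventTimes(ev, "cue_on")
  counts <- vapply(cues, function(c0) sum(st >= c0 & st < c0 + 2),
                   numeric(1))
  early <- mean(counts[1:30]); late <- mean(counts[71:100])
  expect_gt(early, late)   # modulation declines across trials
})

test_that("tensor generator plants an exact low-rank model", {
  g <- genTrialTensor(list(U = 20L, T = 6L, P = 30L, r_true = 1L,
                           noise_sd = 0, seed = 4))
  X <- tensorData(g$tensor)
  # exactly rank 1: second singular value of every unfolding vanishes
  for (m in 1:3) {
    unf <- switch(m, matrix(X, 20, 180),
                  matrix(aperm(X, c(2, 1, 3)), 6, 600),
                  matrix(aperm(X, c(3, 1, 2)), 30, 120))
    sv <- svd(unf)$d
    expect_lt(sv[2] / sv[1], 1e-12)
  }
  # reconstruction from planted factors reproduces the noiseless tensor
  expect_equal(reconstruct(g$truth), X, tolerance = 1e-12)

  # group shift 0: CTRL and PCE loadings identical in expectation
  g2 <- genTrialTensor(list(U = 400L, T = 6L, P = 30L, r_true = 2L,
                            noise_sd = 0, group_loading_shift = 0, seed = 6))
  W <- unitFactors(g2$truth)
  lab <- unitInfo(g2$tensor)$group
  d <- abs(mean(W[lab == "CTRL", 1]) - mean(W[lab == "PCE", 1]))
  expect_lt(d / stats::sd(W[, 1]), 0.35)

  expect_error(genTrialTensor(list(U = 5L, T = 3L, P = 4L, r_true = 4L)),
               "exceeds")
  # determinism
  ga <- genTrialTensor(list(seed = 9)); gb <- genTrialTensor(list(seed = 9))
  expect_identical(tensorData(ga$tensor), tensorData(gb$tensor))
})

test_that("demand generator follows the exponential model exactly when noiseless", {
  spec <- list(Q0_true = 50, alpha_true = 0.002, k_true = 2, noise_sd = 0,
               seed = 1)
  obs <- genDemandObservations(spec)
  expect_identical(obs$price, demandPriceSchedule("food_demand"))
  # monotone decreasing in price for the food schedule order (descending
  # prices => increasing consumption down the table)
  expect_true(all(diff(obs$consumption) > 0))
  manual <- 50 * 10^(2 * (exp(-0.002 * 50 * obs$price) - 1))
  expect_equal(obs$consumption, manual, tolerance = 1e-12)
  # price -> 0 limit equals Q0
  at0 <- predictConsumption(list(Q0 = 50, alpha = 0.002, k = 2), 0)
  expect_identical(at0$consumption, 50)
  expect_error(genDemandObservations(list(Q0_true = -1, alpha_true = 1,
                                          k_true = 1)),
               "positive")
})
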