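# Unit PSTH normalization, encoding features, iterative k-means, and AUCz.

test_that("session-mean normalization gives mean 1 for a homogeneous unit", {
  ev <- makeCueEvents(60)
  spec <- list(n_units = 3L, profile_mix = c(nonencoding = 1),
               baseline_rate_range = c(10, 10), seed = 2)
  sess <- genSpikeSession(spec, ev)
  st <- spikeTimes(sess)[[1]]
  dur <- sessionDuration(sess)
  edges <- seq(0, floor(dur), by = 0.5)
  rate <- tabulate(findInterval(st, edges), nbins = length(edges) - 1) / 0.5
  norm <- rate / (length(st) / dur)
  se <- stats::sd(norm) / sqrt(length(norm))
  expect_lt(abs(mean(norm) - 1), 2 * se + 0.01)
})

test_that("Gaussian smoothing preserves constants and the trace mean", {
  x <- rep(2.5, 80)
  expect_equal(operantNeuro:::smoothTrace(x), x, tolerance = 1e-12)
  set.seed(4)
  y <- rnorm(120) + sin(seq(0, 10, length.out = 120))
  ys <- operantNeuro:::smoothTrace(y)
  expect_lt(abs(mean(ys) - mean(y)), 1e-10)
  # smoothing actually smooths
  expect_lt(stats::sd(diff(ys)), stats::sd(diff(y)))
})

test_that("unit PSTHs: identical trains give identical PSTHs; zero-spike units drop", {
  ev <- makeCueEvents(10)
  st <- sort(runif(400, 0, 150))
  sess <- new("SpikeSession",
              spikes = list(u1 = st, u2 = st, u3 = numeric()),
              duration = 150, groupLabel = "CTRL", sex = "F",
              profiles = character())
  expect_warning(
    expect_warning(ps <- buildUnitPSTHs(sess, ev), "zero spikes"),
    "zero cross-unit variance")
  expect_length(ps, 2L)
  expect_identical(ps[[1]]$z, ps[[2]]$z)
  # two identical units: zero cross-unit variance -> z = 0 with warning
  expect_true(all(ps[[1]]$z == 0))
})

test_that("encoding features follow their arithmetic definitions", {
  time <- seq(-2 + 0.05, 8 - 0.05, by = 0.1)
  flat <- list(z = matrix(0, 2, length(time)), time = time)
  f <- extractEncodingFeatures(flat)
  expect_equal(unname(f["n_transients"]), 0)
  expect_equal(unname(f["t_first_transient"]), 8)    # sentinel: span end
  expect_equal(unname(f["mean_cue_activity"]), 0)
  expect_equal(unname(f["mean_reward_activity"]), 0)

  # constant z = 2 on [0, 2), 0 elsewhere
  zc <- as.numeric(time >= 0 & time < 2) * 2
  f2 <- extractEncodingFeatures(list(z = rbind(zc, zc), time = time))
  expect_equal(unname(f2["mean_cue_activity"]), 2)
  expect_equal(unname(f2["mean_reward_activity"]), 0)
  expect_equal(unname(f2["n_transients"]), 1)

  # single bump peaking z = 4 at 0.5 s
  bump <- 4 * exp(-(time - 0.5)^2 / (2 * 0.15^2))
  f3 <- extractEncodingFeatures(list(z = rbind(bump, bump), time = time),
                                threshold_z = 2)
  expect_equal(unname(f3["n_transients"]), 1)
  expect_lt(abs(f3["t_first_transient"] - 0.5), 0.35)
  expect_error(extractEncodingFeatures(list(z = matrix(0, 1, 10),
                                            time = seq(0, 0.9, by = 0.1))),
               "cover")
})

test_that("hysteresis merges threshold jitter into one transient", {
  time <- seq(-2 + 0.05, 8 - 0.05, by = 0.1)
  z <- numeric(length(time))
  seg <- time >= 0 & time < 2
  z[seg] <- 1.8
  z[which(seg)[10:11]] <- 1.2        # mid-plateau dip below entry, above exit
  f <- extractEncodingFeatures(list(z = rbind(z, z), time = time),
                               threshold_z = 1.5)
  expect_equal(unname(f["n_transients"]), 1)
  # a dip below the exit threshold splits the excursion
  z2 <- z; z2[which(seg)[10:11]] <- 0.5
  f2 <- extractEncodingFeatures(list(z = rbind(z2, z2), time = time),
                                threshold_z = 1.5)
  expect_equal(unname(f2["n_transients"]), 2)
})

test_that("iterative k-means recovers planted encoding patterns", {
  w4 <- clusterWorld(MIX_PURE4, 150L, seed = 77)
  expect_identical(finalK(w4$model), 4L)
  expect_gte(w4$ari, 0.9)
  labs <- unique(clusterAssignments(w4$model))
  expect_true(all(c("cue_activated", "cue_inhibited", "reward_activated",
                    "reward_inhibited") %in% labs))

  w3 <- clusterWorld(MIX_PURE3, 120L, seed = 78)
  expect_identical(finalK(w3$model), 3L)
  expect_gte(w3$ari, 0.9)
})

test_that("degenerate clustering inputs behave per contract", {
  f <- matrix(rep(c(1, 8, 0, 0), each = 40), nrow = 40)
  colnames(f) <- c("n_transients", "t_first_transient",
                   "mean_cue_activity", "mean_reward_activity")
  cl <- clusterEncodingPatterns(f, seed = 1)
  expect_identical(finalK(cl), 1L)        # all units identical -> one pattern
  expect_error(clusterEncodingPatterns(f[1, , drop = FALSE], seed = 1),
               "fewer units")
})

test_that("raising the outlier quantile never removes clustered units", {
  w <- clusterWorld(MIX_PURE4, 100L, seed = 5)
  counts <- vapply(c(0.90, 0.95, 0.975, 0.99), function(q) {
    cl <- clusterEncodingPatterns(w$features, seed = 5, outlier_quantile = q)
    sum(clusterAssignments(cl) != "nonencoding")
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("windowAUCz integrates trial-averaged z traces exactly and linearly", {
  time <- seq(-2, 8, by = 0.1)
  z1 <- matrix(as.numeric(time >= 0 & time <= 2), 1)
  expect_equal(windowAUCz(list(z = z1, time = time), c(0, 2)), 2.0,
               tolerance = 1e-12)
  zneg <- matrix(-as.numeric(time >= 2 & time <= 7), 1)
  expect_equal(windowAUCz(list(z = zneg, time = time), c(2, 7)), -5.0,
               tolerance = 1e-12)
  tri <- matrix(pmax(0, 2 * (1 - abs(time - 1))), 1)
  expect_equal(windowAUCz(list(z = tri, time = time), c(0, 2)), 2.0,
               tolerance = 1e-12)
  # linearity
  set.seed(2)
  zr <- matrix(rnorm(length(time)), 1)
  a <- windowAUCz(list(z = zr, time = time), c(0, 7))
  a3 <- windowAUCz(list(z = 3 * zr, time = time), c(0, 7))
  expect_equal(a3, 3 * a, tolerance = 1e-12)
  expect_error(windowAUCz(list(z = zr, time = time), c(5, 9)), "outside")
})
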