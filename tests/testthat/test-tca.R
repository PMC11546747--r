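# CP decomposition by ALS, factor similarity, rank selection, group
# comparison, and trial truncation.

randomCPModel <- function(U, Tt, P, r, seed) {
  operantNeuro:::withSeed(seed, {
    B <- matrix(rnorm(Tt * r), Tt, r); A <- matrix(rnorm(P * r), P, r)
    B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
    A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
    new("CPModel", W = matrix(rnorm(U * r), U, r), B = B, A = A,
        rank = as.integer(r), objective = numeric())
  })
}

test_that("cpALS fits a noiseless planted rank-2 tensor to machine precision", {
  set.seed(7)
  W <- matrix(runif(20 * 2), 20, 2); B <- matrix(runif(6 * 2), 6, 2)
  A <- matrix(runif(15 * 2), 15, 2)
  X <- array(W %*% t(operantNeuro:::khatriRao(A, B)), c(20, 6, 15))
  m <- cpALS(X, 2, n_restarts = 3, tol = 1e-12, max_iter = 1000, seed = 3)
  rel <- sqrt(utils::tail(objectiveTrace(m), 1)) / sqrt(sum(X^2))
  expect_lt(rel, 1e-6)
  # reconstruction matches
  expect_lt(max(abs(reconstruct(m) - X)), 1e-5)
})

test_that("cpALS objective is monotone non-increasing and respects contracts", {
  g <- genTrialTensor(list(U = 40L, T = 8L, P = 30L, r_true = 3L, snr = 4,
                           seed = 2))
  m <- cpALS(g$tensor, 3, n_restarts = 2, seed = 4)
  expect_true(all(diff(objectiveTrace(m)) <=
                    1e-8 * (1 + objectiveTrace(m)[1])))
  # rank-1 all-ones tensor reproduces itself exactly
  ones <- array(1, c(5, 4, 6))
  m1 <- cpALS(ones, 1, seed = 1)
  expect_lt(max(abs(reconstruct(m1) - ones)), 1e-8)
  expect_error(cpALS(ones, 7, seed = 1), "rank")
  expect_error(cpALS(array(0, c(4, 4, 4)), 1, seed = 1), "zero tensor")
})

test_that("factorSimilarity is a permutation/scale-invariant match score", {
  m <- randomCPModel(30, 8, 20, 4, seed = 5)
  expect_equal(factorSimilarity(m, m), 1.0, tolerance = 1e-12)
  # permuted, rescaled, sign-flipped copy still scores 1
  perm <- c(3, 1, 4, 2)
  m2 <- new("CPModel", W = m@W[, perm] * 2.5,
            B = -m@B[, perm], A = -m@A[, perm] / 2.5,
            rank = 4L, objective = numeric())
  expect_equal(factorSimilarity(m, m2), 1.0, tolerance = 1e-12)
  expect_error(factorSimilarity(m, randomCPModel(30, 8, 20, 3, 1)), "rank")
  # two unrelated random models score low (19/20 seeds below 0.5)
  low <- vapply(1:20, function(s) {
    factorSimilarity(randomCPModel(100, 8, 60, 4, s),
                     randomCPModel(100, 8, 60, 4, s + 1000L))
  }, numeric(1))
  expect_gte(sum(low < 0.5), 19L)
})

test_that("planted factors are recovered with high congruence", {
  g0 <- genTrialTensor(list(U = 60L, T = 8L, P = 40L, r_true = 4L,
                            noise_sd = 0, seed = 3))
  m0 <- cpALS(g0$tensor, 4, n_restarts = 4, tol = 1e-12, max_iter = 1500,
              seed = 5)
  expect_gte(factorSimilarity(m0, g0$truth), 0.95)
  g5 <- genTrialTensor(list(U = 100L, T = 8L, P = 60L, r_true = 4L, snr = 5,
                            seed = 4))
  m5 <- cpALS(g5$tensor, 4, n_restarts = 4, seed = 5)
  expect_gte(factorSimilarity(m5, g5$truth), 0.8)
})

test_that("rank selection identifies planted structure and rejects noise", {
  # noiseless rank-1 tensor: over-factored runs split components and are
  # flagged degenerate, so the selection stays at 1
  g1 <- genTrialTensor(list(U = 30L, T = 6L, P = 20L, r_true = 1L,
                            noise_sd = 0, seed = 2))
  s1 <- selectRank(tensorData(g1$tensor), candidates = 1:4, seed = 1)
  expect_identical(s1$selected_r, 1L)
  # pure noise: nothing converges
  Xn <- operantNeuro:::withSeed(8, array(rnorm(50 * 8 * 30), c(50, 8, 30)))
  sn <- selectRank(Xn, candidates = 1:3, seed = 1)
  expect_true(is.na(sn$selected_r))
  expect_error(selectRank(Xn, candidates = 1:3, similarity_threshold = 1.5),
               "threshold")
  expect_error(selectRank(Xn, candidates = c(3, 1)), "ascending")
  # determinism
  g <- genTrialTensor(list(U = 40L, T = 8L, P = 24L, r_true = 2L, snr = 6,
                           seed = 5))
  sa <- selectRank(tensorData(g$tensor), candidates = 1:4, seed = 9,
                   runs_per_candidate = 5L)
  sb <- selectRank(tensorData(g$tensor), candidates = 1:4, seed = 9,
                   runs_per_candidate = 5L)
  expect_identical(sa$similarity, sb$similarity)
  expect_identical(sa$selected_r, sb$selected_r)
})

test_that("group loading comparison detects a planted shift on one component", {
  g <- genTrialTensor(list(U = 300L, T = 8L, P = 40L, r_true = 3L,
                           noise_sd = 0, seed = 6))
  W <- unitFactors(g$truth)
  lab <- unitInfo(g$tensor)$group
  # plant a shift on component 1 only
  W2 <- W; W2[lab == "PCE", 1] <- W2[lab == "PCE", 1] +
    stats::sd(W[, 1])
  m <- new("CPModel", W = W2, B = trialFactors(g$truth),
           A = timeFactors(g$truth), rank = 3L, objective = numeric())
  res <- compareGroupLoadings(m, lab)
  expect_gt(abs(res$cohens_d[1]), 0.6)
  expect_true(all(abs(res$cohens_d[-1]) < 0.3))
  # no shift: standardized difference near zero
  res0 <- compareGroupLoadings(g$truth, lab)
  expect_true(all(abs(res0$cohens_d) < 0.2))
  expect_error(compareGroupLoadings(m, lab[-1]), "length")
})

test_that("trial truncation keeps the first n trials and concatenates units", {
  ev <- makeCueEvents(12)
  mk <- function(seed) {
    s <- genSpikeSession(list(n_units = 5L,
                              profile_mix = c(cue_activated = 1),
                              seed = seed), ev)
    buildUnitPSTHs(s, ev)
  }
  p1 <- mk(1); p2 <- mk(2)
  tens <- truncateToFirstTrials(list(p1, p2), n = 8L,
                                groups = c("CTRL", "PCE"))
  expect_identical(dim(tensorData(tens)), c(10L, 8L, ncol(p1[[1]]$z)))
  expect_identical(unitInfo(tens)$group, rep(c("CTRL", "PCE"), each = 5))
  # trials 1-8 retained verbatim
  expect_equal(tensorData(tens)[1, , ], p1[[1]]$z[1:8, ])
  # a subject with too few trials errors, naming it
  ev7 <- makeCueEvents(7)
  s7 <- genSpikeSession(list(n_units = 2L,
                             profile_mix = c(cue_activated = 1), seed = 3),
                        ev7)
  p7 <- buildUnitPSTHs(s7, ev7)
  expect_error(truncateToFirstTrials(list(p1, p7), n = 8L), "2")
})
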