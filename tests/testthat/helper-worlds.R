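# Shared fixtures and independent oracles, built in code at test time.

# -- event streams ----------------------------------------------------------

# a full-length food-PR session used by the clustering worlds (cached)
.world_cache <- new.env(parent = emptyenv())

prEvents <- function() {
  if (is.null(.world_cache$ev)) {
    .world_cache$ev <- simulatePRSession(
      list(press_rate = 2, persistence_limit = Inf),
      scheduleSpec("food_PR"), seed = 11)
  }
  .world_cache$ev
}

# bare cue-only event stream with n widely spaced cues
makeCueEvents <- function(n, spacing = 14) {
  t0 <- 5 + spacing * (seq_len(n) - 1)
  new("TrialEvents",
      events = data.frame(time_s = t0, event = "cue_on",
                          trial_index = seq_len(n)))
}

# -- planted clustering worlds ----------------------------------------------

MIX_PURE4 <- c(cue_activated = 0.25, cue_inhibited = 0.25,
               reward_activated = 0.25, reward_inhibited = 0.25)
MIX_T3 <- c(cue_activated = 0.2, cue_inhibited = 0.2,
            reward_activated = 0.2, reward_inhibited = 0.2,
            nonencoding = 0.2)
MIX_PURE3 <- c(cue_activated = 0.34, reward_activated = 0.33,
               press_inhibited = 0.33)
MIX_T4 <- c(cue_activated = 0.27, reward_activated = 0.27,
            press_inhibited = 0.26, nonencoding = 0.2)

clusterWorld <- function(mix, n_units, seed, cluster_seed = seed) {
  sess <- genSpikeSession(list(n_units = n_units, profile_mix = mix,
                               seed = seed), prEvents())
  feats <- t(vapply(buildUnitPSTHs(sess, prEvents()),
                    extractEncodingFeatures, numeric(4)))
  cl <- clusterEncodingPatterns(feats, seed = cluster_seed)
  list(session = sess, features = feats, model = cl,
       ari = operantNeuro:::adjustedRandIndex(clusterAssignments(cl),
                                              unitProfiles(sess)))
}

# -- independent CP oracle: joint L-BFGS on all factor entries --------------
# (a different optimization route than alternating least squares)

cpOracleSSE <- function(X, r, n_starts = 6L, seed = 1L) {
  d <- dim(X); U <- d[1]; Tt <- d[2]; P <- d[3]
  X1 <- matrix(X, U, Tt * P)
  X2 <- matrix(aperm(X, c(2, 1, 3)), Tt, U * P)
  X3 <- matrix(aperm(X, c(3, 1, 2)), P, U * Tt)
  kr <- operantNeuro:::khatriRao
  unpack <- function(th) {
    list(W = matrix(th[seq_len(U * r)], U, r),
         B = matrix(th[U * r + seq_len(Tt * r)], Tt, r),
         A = matrix(th[(U + Tt) * r + seq_len(P * r)], P, r))
  }
  fn <- function(th) {
    f <- unpack(th)
    sum((X1 - f$W %*% t(kr(f$A, f$B)))^2)
  }
  gr <- function(th) {
    f <- unpack(th)
    gW <- -2 * (X1 - f$W %*% t(kr(f$A, f$B))) %*% kr(f$A, f$B)
    gB <- -2 * (X2 - f$B %*% t(kr(f$A, f$W))) %*% kr(f$A, f$W)
    gA <- -2 * (X3 - f$A %*% t(kr(f$B, f$W))) %*% kr(f$B, f$W)
    c(gW, gB, gA)
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    set.seed(seed * 100L + s)
    th0 <- stats::rnorm((U + Tt + P) * r, sd = 0.5)
    o <- stats::optim(th0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = 2000L, factr = 1e1))
    best <- min(best, o$value)
  }
  best
}

# -- brute-force Bayes-factor oracle ----------------------------------------
# plain midpoint Riemann sums over (b0, beta, t) with u = t^2; independent
# of the package's quadrature/Laplace and Gauss-Legendre grid routes

bayesOracle <- function(y, x, nb0 = 161L, nb = 221L, nt = 400L) {
  n0 <- sum(x == 0); n1 <- sum(x == 1)
  y0 <- sum(y[x == 0]); y1 <- sum(y[x == 1])
  z0 <- -n1 / (n0 + n1); z1 <- n0 / (n0 + n1)
  c_scale <- (n0 + n1)^2 / (n0 * n1)
  ll <- function(b0, bb) {
    e0 <- b0 + bb * z0; e1 <- b0 + bb * z1
    y0 * e0 - n0 * log1p(exp(e0)) + y1 * e1 - n1 * log1p(exp(e1))
  }
  # center grids on the (ridge) MLE
  sf <- glm(cbind(c(y0, y1), c(n0 - y0, n1 - y1)) ~ c(z0, z1),
            family = binomial)
  mle <- pmin(pmax(coef(sf), -12), 12)
  se <- sqrt(diag(vcov(sf)))
  se[!is.finite(se)] <- 2
  b0g <- seq(mle[1] - 10 * max(se[1], 0.2), mle[1] + 10 * max(se[1], 0.2),
             length.out = nb0)
  bg <- seq(mle[2] - 10 * max(se[2], 0.2), mle[2] + 10 * max(se[2], 0.2),
            length.out = nb)
  db0 <- diff(b0g[1:2]); db <- diff(bg[1:2])
  L <- outer(b0g, bg, ll)
  lmax <- max(L)
  Mb <- colSums(exp(L - lmax)) * db0              # integral over b0, per beta
  tg <- (seq_len(nt) - 0.5) / nt                  # midpoints on (0,1)
  m1 <- 0
  for (t in tg) {
    u <- t^2; g <- (1 - u) / u
    m1 <- m1 + (1.5 * (1 - t^2) / nt) *
      sum(Mb * stats::dnorm(bg, 0, sqrt(g * c_scale))) * db
  }
  m0 <- sum(exp(ll(b0g, 0) - lmax)) * db0
  m1 / m0
}
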