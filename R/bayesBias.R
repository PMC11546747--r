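# Bayesian logistic regression for encoding-class bias, with a compound
# confluent hypergeometric (CCH) mixing prior on the g-prior shrinkage
# factor, and Bayes-factor evidence categories.
#
# Model. Outcome y_i in {0,1} (e.g. cue- vs reward-encoding), predictor
# x_i in {0,1} (CTRL = 0, PCE = 1), centered to z_i = x_i - mean(x).
#   M0:  logit p_i = b0
#   M1:  logit p_i = b0 + beta * z_i
# Priors. The intercept gets a flat (improper) prior shared by both models,
# so it cancels in the Bayes factor. The slope gets a mixture of g-priors:
#   beta | g ~ N(0, g * c),   c = n / sum(z^2)   (unit-information scaling)
# with the CCH(a, b, s) hyperprior on the shrinkage factor u = 1/(1+g),
#   p(u) proportional to u^(a-1) * (1-u)^(b-1) * exp(-s*u),  u in (0,1).
# With s = 0 this reduces to u ~ Beta(a, b); the analysis uses a = 0.5,
# b = 2, s = 0. The substitution u = t^2 removes the u^(-1/2) endpoint
# singularity: for a = 0.5, b = 2,
#   int f(u) dBeta(u; 0.5, 2) = (3/2) * int_0^1 f(t^2) (1 - t^2) dt,
# a smooth integrand handled by Gauss-Legendre quadrature.
# BF10 = m1 / m0 with marginal likelihoods m_k integrated numerically:
# adaptive quadrature over u crossed with a Laplace approximation over the
# coefficients (default), or full 3-D grid integration ("grid"), kept as an
# independent numerical route.

#' CCH prior specification for the shrinkage mixing parameter
#'
#' @param a,b,s hyperparameters; defaults a = 0.5, b = 2, s = 0 (under which
#'   the prior on u = 1/(1+g) is Beta(a, b)).
#' @return list of class "PriorSpec".
#' @export
priorSpec <- function(a = 0.5, b = 2, s = 0) {
  if (a <= 0 || b <= 0 || s < 0) stop("require a > 0, b > 0, s >= 0")
  if (s != 0) stop("only s = 0 (Beta-form reduction) is implemented")
  structure(list(a = a, b = b, s = s), class = "PriorSpec")
}

# log-likelihood from 2x2 sufficient statistics at (b0, beta)
.biasLoglik <- function(b0, beta, stats) {
  eta0 <- b0 + beta * stats$z0
  eta1 <- b0 + beta * stats$z1
  stats$y0 * eta0 - stats$n0 * log1p(exp(eta0)) +
    stats$y1 * eta1 - stats$n1 * log1p(exp(eta1))
}

.biasStats <- function(y, x) {
  n0 <- sum(x == 0); n1 <- sum(x == 1)
  list(n0 = n0, n1 = n1, y0 = sum(y[x == 0]), y1 = sum(y[x == 1]),
       z0 = -n1 / (n0 + n1), z1 = n0 / (n0 + n1),
       c_scale = (n0 + n1)^2 / (n0 * n1))
}

# ridge-stabilized Newton MLE of (b0, beta); returns estimate and SEs
.biasMLE <- function(st) {
  th <- c(0, 0)
  for (it in 1:50) {
    p0 <- stats::plogis(th[1] + th[2] * st$z0)
    p1 <- stats::plogis(th[1] + th[2] * st$z1)
    g <- c(st$y0 - st$n0 * p0 + st$y1 - st$n1 * p1,
           st$z0 * (st$y0 - st$n0 * p0) + st$z1 * (st$y1 - st$n1 * p1))
    w0 <- st$n0 * p0 * (1 - p0); w1 <- st$n1 * p1 * (1 - p1)
    H <- -matrix(c(w0 + w1, w0 * st$z0 + w1 * st$z1,
                   w0 * st$z0 + w1 * st$z1,
                   w0 * st$z0^2 + w1 * st$z1^2), 2, 2) -
      diag(1e-6, 2)
    step <- solve(H, g)
    th <- th - step
    th <- pmin(pmax(th, -15), 15)
    if (max(abs(step)) < 1e-10) break
  }
  se <- sqrt(diag(solve(-H)))
  list(theta = th, se = se)
}

# Laplace approximation of log int exp(loglik + logprior_beta) d(b0, beta)
# at fixed prior precision tau = 1/(g*c) on beta (tau = 0: no beta, 1-D)
.laplaceJoint <- function(st, tau, init) {
  th <- init
  for (it in 1:60) {
    p0 <- stats::plogis(th[1] + th[2] * st$z0)
    p1 <- stats::plogis(th[1] + th[2] * st$z1)
    g <- c(st$y0 - st$n0 * p0 + st$y1 - st$n1 * p1,
           st$z0 * (st$y0 - st$n0 * p0) + st$z1 * (st$y1 - st$n1 * p1) -
             tau * th[2])
    w0 <- st$n0 * p0 * (1 - p0); w1 <- st$n1 * p1 * (1 - p1)
    H <- -matrix(c(w0 + w1, w0 * st$z0 + w1 * st$z1,
                   w0 * st$z0 + w1 * st$z1,
                   w0 * st$z0^2 + w1 * st$z1^2 + tau), 2, 2)
    step <- tryCatch(solve(H - diag(1e-10, 2), g), error = function(e) g * 0)
    th <- th - step
    if (max(abs(step)) < 1e-11) break
  }
  h <- .biasLoglik(th[1], th[2], st) - 0.5 * tau * th[2]^2 +
    0.5 * log(tau / (2 * pi))          # prior normalizing constant
  h + log(2 * pi) - 0.5 * determinant(-H)$modulus[1]
}

# 1-D Laplace for the null model (flat prior on b0)
.laplaceNull <- function(st) {
  n <- st$n0 + st$n1; ys <- st$y0 + st$y1
  phat <- min(max(ys / n, 1e-12), 1 - 1e-12)
  b0 <- stats::qlogis(phat)
  w <- n * phat * (1 - phat)
  .biasLoglik(b0, 0, st) + 0.5 * log(2 * pi) - 0.5 * log(w)
}

.gaussLegendre <- function(n, a = 0, b = 1) {
  # nodes/weights via eigen-decomposition of the Jacobi matrix
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta; J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

#' Bayesian logistic regression for treatment bias on a binary classification
#'
#' Tests whether the treatment group shifts the probability that a unit
#' falls in one encoding class versus another. Returns the posterior mean
#' and 95% equal-tailed credible interval of the group log-odds coefficient,
#' the Bayes factor BF10 of the treatment model against the intercept-only
#' null, and its Jeffreys evidence category.
#'
#' @param y binary outcome vector (0/1 or logical).
#' @param x binary group vector (0 = CTRL, 1 = PCE).
#' @param prior a \code{\link{priorSpec}}.
#' @param method "laplace" (adaptive quadrature over the mixing variable
#'   crossed with Laplace over the coefficients; default) or "grid"
#'   (brute-force 3-D grid integration, the independent cross-check route).
#' @param n_quad quadrature nodes over the mixing variable (default 40).
#' @return list of class "PosteriorSummary": `beta_mean`, `beta_ci`
#'   (length 2), `bf10`, `bf01`, `evidence_label`, `n_per_cell`, `method`.
#' @export
fitBayesLogistic <- function(y, x, prior = priorSpec(),
                             method = c("laplace", "grid"),
                             n_quad = 40L) {
  method <- match.arg(method)
  y <- as.integer(y); x <- as.integer(x)
  if (length(y) != length(x)) stop("y and x must have equal length")
  if (length(y) < 10L) stop("need at least 10 observations")
  if (!all(y %in% 0:1) || !all(x %in% 0:1)) stop("y and x must be binary")
  if (length(unique(x)) < 2L) stop("predictor has a single level")
  st <- .biasStats(y, x)
  cells <- c(st$y0, st$n0 - st$y0, st$y1, st$n1 - st$y1)
  if (any(cells == 0)) {
    warning("empty cell: quasi-separation; the prior regularizes the fit")
  }

  gl <- .gaussLegendre(n_quad, 0, 1)
  # Beta(0.5, 2) mixing density after u = t^2: weight (3/2) * (1 - t^2)
  uw <- 1.5 * (1 - gl$nodes^2) * gl$weights
  us <- gl$nodes^2
  mle <- .biasMLE(st)

  if (method == "laplace") {
    log_terms <- vapply(us, function(u) {
      g <- (1 - u) / u
      tau <- 1 / (g * st$c_scale)
      .laplaceJoint(st, tau, mle$theta)
    }, numeric(1))
    mmax <- max(log_terms)
    log_m1 <- mmax + log(sum(uw * exp(log_terms - mmax)))
    log_m0 <- .laplaceNull(st)
    # posterior of beta on a grid via 1-D Laplace over b0 per (beta, u)
    bgrid <- seq(mle$theta[2] - 8 * max(mle$se[2], 0.2),
                 mle$theta[2] + 8 * max(mle$se[2], 0.2), length.out = 201L)
    post <- vapply(bgrid, function(bb) {
      lt <- vapply(us, function(u) {
        g <- (1 - u) / u
        .laplaceProfileB0(st, bb) +
          stats::dnorm(bb, 0, sqrt(g * st$c_scale), log = TRUE)
      }, numeric(1))
      m <- max(lt); m + log(sum(uw * exp(lt - m)))
    }, numeric(1))
  } else {
    b0grid <- seq(mle$theta[1] - 10 * max(mle$se[1], 0.2),
                  mle$theta[1] + 10 * max(mle$se[1], 0.2), length.out = 201L)
    bgrid <- seq(mle$theta[2] - 10 * max(mle$se[2], 0.2),
                 mle$theta[2] + 10 * max(mle$se[2], 0.2), length.out = 241L)
    db0 <- diff(b0grid[1:2]); db <- diff(bgrid[1:2])
    ll <- outer(b0grid, bgrid, function(b0, bb) .biasLoglik(b0, bb, st))
    llmax <- max(ll)
    L <- exp(ll - llmax)
    Mb <- colSums(L) * db0                       # over b0, per beta
    m1_scaled <- sum(vapply(seq_along(us), function(i) {
      g <- (1 - us[i]) / us[i]
      uw[i] * sum(Mb * stats::dnorm(bgrid, 0, sqrt(g * st$c_scale))) * db
    }, numeric(1)))
    L0 <- exp(.biasLoglik(b0grid, 0, st) - llmax)
    log_m1 <- llmax + log(m1_scaled)
    log_m0 <- llmax + log(sum(L0) * db0)
    post <- log(vapply(seq_along(bgrid), function(j) {
      sum(vapply(seq_along(us), function(i) {
        g <- (1 - us[i]) / us[i]
        uw[i] * Mb[j] * stats::dnorm(bgrid[j], 0, sqrt(g * st$c_scale))
      }, numeric(1)))
    }, numeric(1)))
  }

  w <- exp(post - max(post)); w <- w / sum(w)
  beta_mean <- sum(w * bgrid)
  cdf <- cumsum(w)
  ci <- c(bgrid[which(cdf >= 0.025)[1]], bgrid[which(cdf >= 0.975)[1]])
  bf10 <- exp(log_m1 - log_m0)
  structure(list(beta_mean = beta_mean, beta_ci = ci,
                 bf10 = bf10, bf01 = 1 / bf10,
                 evidence_label = classifyEvidence(bf10),
                 n_per_cell = c(ctrl_0 = st$n0 - st$y0, ctrl_1 = st$y0,
                                pce_0 = st$n1 - st$y1, pce_1 = st$y1),
                 method = method, prior = prior),
            class = "PosteriorSummary")
}

# log int exp(loglik(b0, beta)) d b0 at fixed beta (flat prior on b0)
.laplaceProfileB0 <- function(st, beta) {
  b0 <- 0
  for (it in 1:60) {
    p0 <- stats::plogis(b0 + beta * st$z0)
    p1 <- stats::plogis(b0 + beta * st$z1)
    g1 <- st$y0 - st$n0 * p0 + st$y1 - st$n1 * p1
    h <- st$n0 * p0 * (1 - p0) + st$n1 * p1 * (1 - p1)
    step <- g1 / max(h, 1e-12)
    b0 <- min(max(b0 + step, -20), 20)
    if (abs(step) < 1e-11) break
  }
  p0 <- stats::plogis(b0 + beta * st$z0)
  p1 <- stats::plogis(b0 + beta * st$z1)
  h <- st$n0 * p0 * (1 - p0) + st$n1 * p1 * (1 - p1)
  .biasLoglik(b0, beta, st) + 0.5 * log(2 * pi) - 0.5 * log(max(h, 1e-12))
}

#' @export
print.PosteriorSummary <- function(x, ...) {
  cat(sprintf("Bayesian logistic bias test (%s):\n", x$method))
  cat(sprintf("  beta = %.3f [%.3f, %.3f] log-odds\n",
              x$beta_mean, x$beta_ci[1], x$beta_ci[2]))
  cat(sprintf("  BF10 = %.3g (%s)\n", x$bf10, x$evidence_label))
  invisible(x)
}

#' Jeffreys evidence category for a Bayes factor
#'
#' BF10 in [1,3) anecdotal, [3,10) moderate, [10,30) strong, [30,100) very
#' strong, >= 100 extreme, each in favor of H1; BF10 < 1 is classified on
#' the reciprocal in favor of H0.
#'
#' @param bf10 positive Bayes factor of H1 against H0.
#' @return character label, e.g. "extreme (H1)" or "moderate (H0)".
#' @examples
#' classifyEvidence(150)    # "extreme (H1)"
#' classifyEvidence(0.005)  # "extreme (H0)"
#' @export
classifyEvidence <- function(bf10) {
  if (!is.finite(bf10) || bf10 <= 0) stop("bf10 must be a positive number")
  side <- if (bf10 >= 1) "H1" else "H0"
  b <- if (bf10 >= 1) bf10 else 1 / bf10
  cat_name <- if (b < 3) "anecdotal" else if (b < 10) "moderate" else
    if (b < 30) "strong" else if (b < 100) "very strong" else "extreme"
  if (b == 1) return("no evidence")
  sprintf("%s (%s)", cat_name, side)
}
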