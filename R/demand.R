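# Exponential model of demand: fitting, prediction, and the derived
# neuroeconomic quantities (essential value and Pmax).
#
# Model (log base 10):
#   log10 Q(price) = log10 Q0 + k * (exp(-alpha * Q0 * price) - 1)
# Q0 is maximal demand at zero cost, alpha the rate of decline in relative
# consumption, k a shared scaling constant reflecting the range of the data.

demandLog10Q <- function(price, Q0, alpha, k) {
  log10(Q0) + k * (exp(-alpha * Q0 * price) - 1)
}

#' Essential value and Pmax from demand parameters
#'
#' EV = 1 / (alpha * k^1.5 * 100);
#' Pmax = 1 / (Q0 * alpha * k^1.5) * (0.083 * k + 0.65). The Pmax expression
#' is the standard closed-form approximation to the price maximizing
#' response output price * Q(price).
#'
#' @param Q0,alpha,k positive demand parameters.
#' @return named list with `EV` and `Pmax`.
#' @examples
#' derivedMetrics(Q0 = 10, alpha = 0.01, k = 2)
#' @export
derivedMetrics <- function(Q0, alpha, k) {
  if (any(c(Q0, alpha, k) <= 0)) stop("Q0, alpha and k must be positive")
  list(EV = 1 / (alpha * k^1.5 * 100),
       Pmax = 1 / (Q0 * alpha * k^1.5) * (0.083 * k + 0.65))
}

#' Fit the exponential model of demand
#'
#' Nonlinear least squares on log10 consumption. The scaling constant k is
#' set by `k_policy`: "shared_pooled" (default) uses the range of log10 mean
#' consumption across the supplied data (optionally pooled over subjects via
#' `pooled_range`), "fixed" uses `k_fixed`, "per_subject" fits k as a third
#' free parameter. Zero-consumption observations are dropped from the
#' log-space fit by default (`zero_handling = "drop"`) or replaced with 0.1
#' reward (`"replace"`). Optimization is bounded (Q0 in (0, 10 * max
#' consumption], alpha in (0, 1]) with 5 deterministic multistarts, so the
#' fit is deterministic given data and settings.
#'
#' @param obs data.frame with columns `price` and `consumption`.
#' @param k_policy "shared_pooled", "fixed" or "per_subject".
#' @param k_fixed value of k when `k_policy = "fixed"`.
#' @param zero_handling "drop" or "replace".
#' @param pooled_range optional numeric range of log10 consumption from a
#'   pooled dataset, for shared_pooled k across subjects.
#' @return a \linkS4class{DemandFit}.
#' @examples
#' obs <- genDemandObservations(list(Q0_true = 50, alpha_true = 0.002,
#'                                   k_true = 2, seed = 1))
#' fitDemandCurve(obs, k_policy = "fixed", k_fixed = 2)
#' @export
fitDemandCurve <- function(obs,
                           k_policy = c("shared_pooled", "fixed", "per_subject"),
                           k_fixed = NULL,
                           zero_handling = c("drop", "replace"),
                           pooled_range = NULL) {
  k_policy <- match.arg(k_policy)
  zero_handling <- match.arg(zero_handling)
  if (!all(c("price", "consumption") %in% names(obs))) {
    stop("obs must have columns 'price' and 'consumption'")
  }
  dat <- obs[, c("price", "consumption")]
  if (all(dat$consumption <= 0)) stop("all-zero consumption is unfittable")
  if (zero_handling == "drop") {
    dat <- dat[dat$consumption > 0, , drop = FALSE]
  } else {
    dat$consumption[dat$consumption <= 0] <- 0.1
  }
  if (length(unique(dat$price[dat$consumption > 0])) < 3L) {
    stop("need at least 3 distinct prices with positive consumption")
  }
  y <- log10(dat$consumption)
  p <- dat$price

  k_val <- switch(k_policy,
    fixed = {
      if (is.null(k_fixed) || k_fixed <= 0) stop("k_fixed must be positive")
      k_fixed
    },
    shared_pooled = {
      rng <- if (!is.null(pooled_range)) pooled_range else range(y)
      max(diff(rng), 0.5)   # floor guards near-flat data
    },
    per_subject = NA_real_
  )

  qmax <- max(dat$consumption)
  sse <- function(par) {
    Q0 <- par[1]; alpha <- par[2]
    k <- if (k_policy == "per_subject") par[3] else k_val
    sum((y - demandLog10Q(p, Q0, alpha, k))^2)
  }
  grad <- function(par) {
    Q0 <- par[1]; alpha <- par[2]
    k <- if (k_policy == "per_subject") par[3] else k_val
    e <- exp(-alpha * Q0 * p)
    resid <- y - (log10(Q0) + k * (e - 1))
    dQ0 <- 1 / (Q0 * log(10)) - k * alpha * p * e
    dal <- -k * Q0 * p * e
    g <- c(-2 * sum(resid * dQ0), -2 * sum(resid * dal))
    if (k_policy == "per_subject") g <- c(g, -2 * sum(resid * (e - 1)))
    g
  }
  starts <- list(
    c(qmax, 0.001), c(qmax * 2, 0.01), c(qmax, 1e-4),
    c(qmax / 2, 0.05), c(qmax * 1.2, 1e-3)
  )
  lower <- c(1e-6, 1e-9); upper <- c(10 * qmax, 1)
  if (k_policy == "per_subject") {
    starts <- lapply(starts, function(s) c(s, max(diff(range(y)), 0.5)))
    lower <- c(lower, 0.1); upper <- c(upper, 10)
  }
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(s, sse, gr = grad, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 500L, factr = 1e4)),
               silent = TRUE)
    if (!inherits(fit, "try-error") &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("demand fit failed from all starting points")
  Q0 <- best$par[1]; alpha <- best$par[2]
  k <- if (k_policy == "per_subject") best$par[3] else k_val
  r2 <- 1 - best$value / max(sum((y - mean(y))^2), .Machine$double.eps)
  dm <- derivedMetrics(Q0, alpha, k)
  new("DemandFit", Q0 = Q0, alpha = alpha, k = k,
      EV = dm$EV, Pmax = dm$Pmax, r2 = r2, kPolicy = k_policy,
      data = dat)
}

#' Predict consumption (and response output) from a demand fit
#'
#' Q(price) = Q0 * 10^(k * (exp(-alpha * Q0 * price) - 1)). At price 0 this
#' is exactly Q0; as price grows Q tends to the floor Q0 * 10^(-k).
#'
#' @param fit a \linkS4class{DemandFit} (or list with Q0, alpha, k).
#' @param prices numeric vector of non-negative prices.
#' @return data.frame with `price`, `consumption`, and `response_output`
#'   (= price * consumption, whose maximizer Pmax approximates).
#' @export
predictConsumption <- function(fit, prices) {
  if (any(prices < 0)) stop("prices must be non-negative")
  Q0 <- if (is(fit, "DemandFit")) fit@Q0 else fit$Q0
  alpha <- if (is(fit, "DemandFit")) fit@alpha else fit$alpha
  k <- if (is(fit, "DemandFit")) fit@k else fit$k
  q <- Q0 * 10^(k * (exp(-alpha * Q0 * prices) - 1))
  data.frame(price = prices, consumption = q, response_output = prices * q)
}

#' Numeric maximizer of response output, for Pmax diagnostics
#'
#' Finds the interior maximum of response output price * Q(price) — the
#' price where demand passes from inelastic to elastic. In the exponential
#' model that maximum sits at x = alpha * Q0 * price < 1 (the first
#' unit-elasticity crossing); beyond the elastic region the 10^(-k)
#' consumption floor makes p * Q rise again without bound, which is a model
#' artifact, so the search is confined to x in (0, 1]. For
#' k <= e / ln(10) (about 1.18) demand never becomes elastic and no
#' maximum exists: returns NA with a warning.
#'
#' @param Q0,alpha,k positive demand parameters.
#' @return the price maximizing response output, or NA when demand is
#'   everywhere inelastic.
#' @export
numericPmax <- function(Q0, alpha, k) {
  if (any(c(Q0, alpha, k) <= 0)) stop("parameters must be positive")
  if (k <= exp(1) / log(10)) {
    warning("demand is everywhere inelastic for k <= e/ln(10); no Pmax")
    return(NA_real_)
  }
  f <- function(x) -x * 10^(k * (exp(-x) - 1))
  opt <- stats::optimize(f, interval = c(1e-9, 1), tol = 1e-10)
  opt$minimum / (alpha * Q0)
}
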