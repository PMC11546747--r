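# Internal numerical helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state on exit so seeded generators never perturb
#' the global random stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; keeps results < 2^31 and decorrelates
# per-stage streams.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483647)
}

#' Trapezoidal integral of a sampled trace over an exact window
#'
#' Samples are (t, y) at bin centers; the window endpoints are interpolated
#' linearly so that a constant trace of value v over a window of width w
#' integrates to exactly v * w.
#' @noRd
trapzWindow <- function(t, y, window) {
  stopifnot(length(t) == length(y), length(window) == 2L)
  a <- window[1]; b <- window[2]
  if (!(b > a)) stop("empty integration window")
  if (a < min(t) || b > max(t)) {
    stop(sprintf("window [%g, %g] outside trace span [%g, %g]",
                 a, b, min(t), max(t)))
  }
  inside <- t > a & t < b
  ya <- stats::approx(t, y, xout = a)$y
  yb <- stats::approx(t, y, xout = b)$y
  tt <- c(a, t[inside], b)
  yy <- c(ya, y[inside], yb)
  sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
}

#' Truncated Gaussian smoothing kernel as a doubly-stochastic matrix
#'
#' Eight taps, sigma in bins. Row sums of 1 leave constant traces untouched;
#' Sinkhorn balancing additionally drives column sums to 1 so the trace mean
#' is preserved at the boundaries as well.
#' @noRd
gaussSmoothMatrix <- function(n, kernel_bins = 8L, sigma = 3) {
  stopifnot(n >= 1L, kernel_bins >= 1L, sigma > 0)
  # integer taps with weights centered on the half-sample, so an even-length
  # kernel has pairwise-symmetric weights (w[-4] == w[3], etc.)
  offs <- seq_len(kernel_bins) - kernel_bins / 2 - 1L     # e.g. -4 .. 3
  w <- exp(-(offs + 0.5)^2 / (2 * sigma^2))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    keep <- j >= 1 & j <= n
    S[i, j[keep]] <- w[keep]
  }
  # guard isolated zero columns (cannot happen for kernel_bins >= 2, n >= 2)
  if (any(colSums(S) == 0)) diag(S)[colSums(S) == 0] <- 1
  # balance rows and columns; the asymmetric band makes Sinkhorn converge
  # linearly, so iterate to tolerance and cache per geometry
  key <- sprintf("S_%d_%d_%g", n, kernel_bins, sigma)
  cached <- .smooth_cache[[key]]
  if (!is.null(cached)) return(cached)
  for (it in seq_len(30000L)) {
    S <- S / rowSums(S)
    S <- sweep(S, 2L, colSums(S), "/")
    if (it %% 50L == 0L && max(abs(rowSums(S) - 1)) < 1e-14) break
  }
  S <- S / rowSums(S)
  .smooth_cache[[key]] <- S
  S
}

.smooth_cache <- new.env(parent = emptyenv())

smoothTrace <- function(y, kernel_bins = 8L, sigma = 3) {
  n <- length(y)
  if (n == 1L) return(y)
  drop(gaussSmoothMatrix(n, kernel_bins, sigma) %*% y)
}

#' Local maxima with topographic prominence
#'
#' A peak's prominence is its height above the higher of the two lowest points
#' separating it from higher terrain (or from the trace ends).
#' @noRd
peakProminences <- function(y) {
  n <- length(y)
  if (n < 3L) return(data.frame(index = integer(), value = numeric(),
                                prominence = numeric()))
  is_peak <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(is_peak)) return(data.frame(index = integer(), value = numeric(),
                                          prominence = numeric()))
  prom <- vapply(is_peak, function(i) {
    h <- y[i]
    # walk left until strictly higher terrain (or the end), track minimum
    left_min <- h
    j <- i - 1L
    while (j >= 1L && y[j] <= h) { left_min <- min(left_min, y[j]); j <- j - 1L }
    hit_left <- j >= 1L
    right_min <- h
    j <- i + 1L
    while (j <= n && y[j] <= h) { right_min <- min(right_min, y[j]); j <- j + 1L }
    hit_right <- j <= n
    base <- if (hit_left && hit_right) max(left_min, right_min)
            else if (hit_left) left_min
            else if (hit_right) right_min
            else min(left_min, right_min)
    h - base
  }, numeric(1))
  data.frame(index = is_peak, value = y[is_peak], prominence = prom)
}

#' Zero-phase Butterworth low-pass
#'
#' Order-n Butterworth designed by bilinear transform as a cascade of
#' second-order sections, applied forward and backward (zero phase lag) with
#' reflective edge padding.
#' @noRd
butterLowpass <- function(cutoff_hz, fs, order = 6L) {
  stopifnot(cutoff_hz > 0, cutoff_hz < fs / 2, order >= 1L)
  # analog prototype poles on the unit circle, pre-warped cutoff
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)
  k <- seq_len(ceiling(order / 2))
  sections <- list()
  for (m in k) {
    theta <- pi * (2 * m - 1 + order) / (2 * order)
    p <- wc * complex(real = cos(theta), imaginary = sin(theta))
    if (order %% 2 == 1 && m == length(k)) {
      # odd order: last section is first order with real pole -wc
      pz <- (2 * fs + (-wc)) / (2 * fs - (-wc))
      g <- wc / (2 * fs + wc)
      sections[[m]] <- list(b = g * c(1, 1, 0), a = c(1, -pz, 0))
    } else {
      # second-order section from conjugate pole pair via bilinear transform
      pz <- (2 * fs + p) / (2 * fs - p)
      a1 <- -2 * Re(pz)
      a2 <- Mod(pz)^2
      g <- wc^2 / Mod(2 * fs - p)^2
      sections[[m]] <- list(b = g * c(1, 2, 1), a = c(1, a1, a2))
    }
  }
  sections
}

applySOS <- function(x, sections) {
  for (s in sections) {
    b <- s$b; a <- s$a
    y <- numeric(length(x))
    x1 <- 0; x2 <- 0; y1 <- 0; y2 <- 0
    for (i in seq_along(x)) {
      y[i] <- b[1] * x[i] + b[2] * x1 + b[3] * x2 - a[2] * y1 - a[3] * y2
      x2 <- x1; x1 <- x[i]
      y2 <- y1; y1 <- y[i]
    }
    x <- y
  }
  x
}

filtfiltButter <- function(x, cutoff_hz, fs, order = 6L) {
  n <- length(x)
  if (n < 4L) return(x)
  sos <- butterLowpass(cutoff_hz, fs, order)
  npad <- min(n - 1L, max(50L, 3L * ceiling(fs / cutoff_hz)))
  # odd (point-symmetric) extension reduces edge transients
  pre <- 2 * x[1] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  ext <- c(pre, x, post)
  y <- applySOS(ext, sos)
  y <- rev(applySOS(rev(y), sos))
  y[(npad + 1L):(npad + n)]
}

#' Column-wise Khatri-Rao product
#' @noRd
khatriRao <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  out <- matrix(0, nrow(A) * nrow(B), ncol(A))
  for (r in seq_len(ncol(A))) out[, r] <- kronecker(A[, r], B[, r])
  out
}

#' Adjusted Rand index between two labelings
#' @noRd
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  mx <- (ai + bj) / 2
  if (mx == expected) return(1)
  (nij - expected) / (mx - expected)
}

# FNV-1a hash of a character scalar; used for provenance manifests.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

cosineSim <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(if (nu == 0 && nv == 0) 1 else 0)
  sum(u * v) / (nu * nv)
}
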