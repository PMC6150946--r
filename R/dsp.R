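# Minimal DSP layer: Butterworth / notch IIR design, zero-phase (bidirectional)
# filtering, and Slepian (DPSS) tapers. The conda image ships no R 'signal'
# package, so these primitives are implemented here and validated in the test
# suite against coefficients and tapers frozen from scipy.signal.

## ---- polynomial / zpk helpers -------------------------------------------

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (root in r) p <- c(p, 0) - c(0, p * root)
  p
}

butter_prototype <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))  # left-half-plane poles, wc = 1
}

## Analog lowpass prototype -> target band, then bilinear transform.
## type: "low", "high", "pass", "stop"; w are critical frequencies in Hz.
butter_design <- function(n, w, fs, type = c("low", "high", "pass", "stop")) {
  type <- match.arg(type)
  if (any(w <= 0) || any(w >= fs / 2))
    stop_opmlat(sprintf(
      "critical frequencies (%s Hz) must lie strictly inside (0, Nyquist = %g Hz)",
      paste(w, collapse = ", "), fs / 2), "opmlat_config_error")
  p <- butter_prototype(n)   # prototype: no zeros, gain 1, prod(-p) = 1
  z <- complex(0)
  k <- 1
  warp <- function(f) 2 * fs * tan(pi * f / fs)  # bilinear pre-warp
  if (type %in% c("low", "high")) {
    wc <- warp(w[1])
    if (type == "low") {
      p <- p * wc
      k <- wc^n
    } else {
      p <- wc / p
      z <- rep(0 + 0i, n)
      k <- 1          # k / Re(prod(-p_proto)) with Butterworth prod(-p) = 1
    }
  } else {
    if (length(w) != 2L || w[2] <= w[1])
      stop_opmlat("band edges must be increasing", "opmlat_config_error")
    w1 <- warp(w[1]); w2 <- warp(w[2])
    bw <- w2 - w1
    w0 <- sqrt(w1 * w2)
    if (type == "pass") {
      pb <- p * bw / 2
      p <- c(pb + sqrt(pb^2 - w0^2), pb - sqrt(pb^2 - w0^2))
      z <- rep(0 + 0i, n)
      k <- bw^n
    } else {
      pb <- (bw / 2) / p
      p <- c(pb + sqrt(pb^2 - w0^2), pb - sqrt(pb^2 - w0^2))
      z <- rep(c(1i * w0, -1i * w0), n)
      k <- 1
    }
  }
  ## bilinear transform: s -> 2fs (z-1)/(z+1)
  fs2 <- 2 * fs
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  kd <- k * Re(prod(fs2 - z)) / Re(prod(fs2 - p))
  ## pad zeros at z = -1 to equalize orders
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

## Second-order IIR notch (RBJ biquad), centre f0 Hz, quality factor Q.
notch_design <- function(f0, Q, fs) {
  if (f0 <= 0 || f0 >= fs / 2)
    stop_opmlat(sprintf("notch frequency %g Hz outside (0, Nyquist = %g Hz)",
                        f0, fs / 2), "opmlat_config_error")
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

freq_response <- function(coefs, f, fs) {
  zb <- outer(2 * pi * f / fs, seq_along(coefs$b) - 1)
  za <- outer(2 * pi * f / fs, seq_along(coefs$a) - 1)
  (exp(-1i * zb) %*% coefs$b) / (exp(-1i * za) %*% coefs$a)
}

## ---- filtering ------------------------------------------------------------

## Single-pass IIR filter, zero initial conditions, along columns.
## Implemented as FIR convolution followed by the recursive (AR) part, both
## delegated to stats::filter (C speed, matrix-capable).
iir_filter1 <- function(b, a, x) {
  nb <- length(b)
  n <- nrow(x)
  v <- stats::filter(rbind(matrix(0, nb - 1, ncol(x)), x), b,
                     method = "convolution", sides = 1)
  v <- v[nb:(nb - 1 + n), , drop = FALSE]
  if (length(a) > 1L)
    v <- stats::filter(v, -a[-1], method = "recursive")
  matrix(as.numeric(v), n, ncol(x))
}

## Zero-phase forward-backward filtering with odd-reflection padding.
## x may be a vector or a matrix (filtered along columns). The column means
## are removed first (and restored through the DC gain) to suppress the
## zero-initial-condition startup transient.
filtfilt_opm <- function(coefs, x, padlen = NULL) {
  b <- coefs$b; a <- coefs$a
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  gdc <- sum(b) / sum(a)
  mu <- colMeans(x)
  x <- sweep(x, 2, mu)
  np <- padlen %||% min(n - 1L, max(3L * (max(length(a), length(b)) - 1L), 250L))
  if (np > 0) {
    head_pad <- 2 * matrix(x[1, ], np, ncol(x), byrow = TRUE) -
      x[(np + 1):2, , drop = FALSE]
    tail_pad <- 2 * matrix(x[n, ], np, ncol(x), byrow = TRUE) -
      x[(n - 1):(n - np), , drop = FALSE]
    xe <- rbind(head_pad, x, tail_pad)
  } else xe <- x
  y <- iir_filter1(b, a, xe)
  y <- iir_filter1(b, a, y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE]
  y <- sweep(y[(np + 1):(np + n), , drop = FALSE], 2, mu * gdc^2, "+")
  if (vec) as.numeric(y) else y
}

## ---- Slepian tapers --------------------------------------------------------

## Discrete prolate spheroidal sequences via the symmetric tridiagonal
## eigenproblem (Slepian 1978). n samples, half-bandwidth W cycles/sample,
## k tapers; columns are unit-energy tapers ordered by concentration.
dpss_tapers <- function(n, W, k) {
  if (k < 1) stop_opmlat("need at least one taper", "opmlat_config_error")
  if (2 * n * W < k)
    warn_opmlat(sprintf("requesting %d tapers with 2NW = %.2f: higher-order tapers are poorly concentrated",
                        k, 2 * n * W), "opmlat_taper_warning")
  t0 <- 0:(n - 1)
  dg <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * W)
  od <- (t0[-1] * (n - t0[-1])) / 2
  M <- diag(dg)
  M[cbind(1:(n - 1), 2:n)] <- od
  M[cbind(2:n, 1:(n - 1))] <- od
  ev <- eigen(M, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tj <- tap[, j]
    tj <- tj / sqrt(sum(tj^2))
    # sign convention: positive mean (even order) / positive initial slope
    s <- if (abs(sum(tj)) > 1e-8) sign(sum(tj)) else sign(tj[2] - tj[1])
    tap[, j] <- tj * s
  }
  tap
}
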