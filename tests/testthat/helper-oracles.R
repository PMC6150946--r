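# Independent oracle computations shared across test files. These are
# deliberately coded from first principles, not via the package's own
# numerical paths.

## oracle 1: radial component of the primary current-dipole field
primary_radial <- function(q, src, spos, sori, center = c(0, 0, 40)) {
  r0 <- (src - center) * 1e-3
  r <- (spos - center) * 1e-3
  a <- r - r0
  bxp <- 1e-7 * c(q[2] * a[3] - q[3] * a[2],
                  q[3] * a[1] - q[1] * a[3],
                  q[1] * a[2] - q[2] * a[1]) / sum(a^2)^1.5
  sum(bxp * sori)
}

## oracle 2: numeric gradient of the magnetic scalar potential
scalar_potential_field <- function(q, src, spos, sori, center = c(0, 0, 40),
                                   h = 1e-7) {
  U <- function(r) {
    r0 <- (src - center) * 1e-3
    rr <- r - center * 1e-3
    qxr0 <- c(q[2] * r0[3] - q[3] * r0[2], q[3] * r0[1] - q[1] * r0[3],
              q[1] * r0[2] - q[2] * r0[1])
    a <- rr - r0
    an <- sqrt(sum(a^2)); rn <- sqrt(sum(rr^2))
    Fv <- an * (rn * an + rn^2 - sum(r0 * rr))
    1e-7 * sum(qxr0 * rr) / Fv
  }
  g <- vapply(1:3, function(k) {
    e <- numeric(3); e[k] <- h
    (U(spos * 1e-3 + e) - U(spos * 1e-3 - e)) / (2 * h)
  }, numeric(1))
  sum(g * sori)
}


## Independent FFT-based band power (not the package's filter/multitaper
## path): variance of the Fourier components inside the band.
fft_band_var <- function(x, fs, band) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  f <- (0:(n - 1)) * fs / n
  keep <- (f >= band[1] & f <= band[2]) | (f >= fs - band[2] & f <= fs - band[1])
  sum(abs(X[keep])^2) / n^2
}

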