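# Beamformer: unit gain, oracle equivalence with exhaustive scanning,
# F-map behaviour, rotation covariance, confidence volumes, virtual channels.

## shared small fixture: source on a grid point, modest noise, preprocessed
## and band-filtered
recon_fixture <- function(n_trials = 15, seed = 51, spacing = 20, ...) {
  arr <- fix_helmet()
  sph <- fix_sphere(arr)
  grid <- fix_grid(sph, spacing = spacing)
  lf <- compute_leadfields(arr, grid, sph)
  ## truth at the grid point closest to the canonical IFG coordinate
  target <- which.min(colSums((t(grid$points) - c(-53.26, 17.3, 19.03))^2))
  truth <- simulation_truth(source_pos = grid$points[target, ],
                            n_trials = n_trials, seed = seed, ...)
  ds <- suppressWarnings(simulate_dataset(truth, arr, lf))
  clean <- synthetic_gradiometry(downsample_and_filter(ds))$ds
  list(filtered = band_filter(clean), lf = lf, grid = grid, target = target,
       truth = truth, clean = clean)
}

test_that("band_filter preserves the passband and rejects out-of-band", {
  fs <- 200
  arr <- mk_array(2, 1, fs)
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  data <- array(0, dim = c(3, length(t), 1))
  data[1, , 1] <- sin(2 * pi * 20 * t)
  data[2, , 1] <- sin(2 * pi * 5 * t)
  out <- band_filter(mk_ds(data, fs, arr), c(15, 30))
  mid <- 300:700
  expect_equal(rms(out$data[1, mid, 1]), rms(data[1, mid, 1]), tolerance = 0.01)
  expect_lt(rms(out$data[2, mid, 1]) / rms(data[2, mid, 1]), 10^(-30 / 20))
  expect_equal(out$data[3, , 1], rep(0, length(t)))
  expect_error(band_filter(mk_ds(data, fs, arr), c(15, 120)),
               class = "opmlat_config_error")
})

fx51 <- recon_fixture()

test_that("LCMV weights satisfy unit gain and match the exhaustive-scan oracle", {
  w <- lcmv_weights(fx51$filtered, fx51$lf)
  gains <- vapply(seq_len(nrow(w$W)), function(p) {
    if (any(is.na(w$ori[p, ]))) return(1)       # silent point, zero weights
    sum(w$W[p, ] * (fx51$lf$L[, , p] %*% w$ori[p, ]))
  }, numeric(1))
  expect_lt(max(abs(gains - 1)), 1e-8)
  ## exhaustive oracle: per grid point, scan orientations densely inside the
  ## non-silent (rank-truncated) moment subspace -- 1-D angle sweep at 0.1
  ## degrees; per-point optimal power and the map peak must match the eigen
  ## solution
  Ci <- w$Ci
  sb <- rowMeans(opmlat:::trial_scatter_vec(fx51$filtered, c(-1, 0)))
  sa <- rowMeans(opmlat:::trial_scatter_vec(fx51$filtered, c(0, 1)))
  np <- dim(fx51$lf$L)[3]
  nch <- dim(fx51$lf$L)[1]
  Sb <- matrix(sb, nch, nch); Sa <- matrix(sa, nch, nch)
  alpha <- seq(0, pi, by = pi / 1800)
  pow_fan <- F_fan <- rep(NA_real_, np)
  for (p in seq_len(np)) {
    L <- fx51$lf$L[, , p]
    sv <- svd(L)
    r <- sum(sv$d > 1e-6 * sv$d[1])
    if (r == 0) next
    dirs <- if (r == 1) sv$v[, 1, drop = FALSE]
            else cbind(cos(alpha)) %*% t(sv$v[, 1]) +
                 cbind(sin(alpha)) %*% t(sv$v[, 2])
    if (r == 3) dirs <- rbind(dirs, t(sv$v[, 3]))   # never happens for a sphere
    M <- crossprod(L, Ci %*% L)
    q <- rowSums((dirs %*% M) * dirs)
    j <- which.min(q)
    pow_fan[p] <- 1 / q[j]
    wv <- as.numeric(Ci %*% (L %*% dirs[j, ])) / q[j]
    vb <- sum(Sb %*% wv * wv); va <- sum(Sa %*% wv * wv)
    F_fan[p] <- max(va / vb, vb / va)
  }
  keep <- !is.na(pow_fan)
  expect_equal(pow_fan[keep], w$power[keep], tolerance = 1e-5)
  ## peak selection equals brute force (two-sided F, like the map)
  m <- f_map(fx51$filtered, w)
  expect_equal(which.max(F_fan), which.max(m$map$F))
  ## F is more orientation-sensitive than power; 0.1 degree granularity
  expect_equal(max(F_fan, na.rm = TRUE), max(m$map$F, na.rm = TRUE),
               tolerance = 1e-3)
  ## singular covariance without regularization errors
  one <- fx51$filtered
  one$data <- one$data[, , 1, drop = FALSE] * 0
  expect_error(lcmv_weights(one, fx51$lf, regularization = 0),
               class = "opmlat_conditioning_error")
})

test_that("F map: identity under equal windows, peak near truth, FDR subsets", {
  w <- lcmv_weights(fx51$filtered, fx51$lf)
  same <- f_map(fx51$filtered, w, baseline_window = c(-1, 0),
                active_window = c(-1, 0))
  ok <- !is.na(same$map$F)
  expect_equal(same$map$F[ok], rep(1, sum(ok)))
  m <- f_map(fx51$filtered, w)
  pk <- which.max(m$map$F)
  d <- sqrt(sum((unlist(m$map[pk, c("x", "y", "z")]) -
                   fx51$grid$points[fx51$target, ])^2))
  expect_lte(d, fx51$grid$spacing + 1e-9)
  expect_equal(m$map$sign[pk], -1)              # a desynchronization
  ## FDR pass set is a p-sorted prefix (Benjamini-Hochberg structure)
  p <- m$map$p[ok]; pass <- m$map$fdr_pass[ok]
  if (any(pass)) expect_lte(max(p[pass]), min(c(p[!pass], Inf)))
  expect_error(f_map(fx51$filtered, w, baseline_window = c(-1, 0),
                     active_window = c(0, 2)),
               class = "opmlat_config_error")
})

test_that("orientation sign flips leave power invariant and weights negate", {
  w <- lcmv_weights(fx51$filtered, fx51$lf)
  p <- fx51$target
  L <- fx51$lf$L[, , p]
  sol1 <- opmlat:::lcmv_point_solve(w$Ci, L)
  ## flipping the lead-field moment basis cannot change power or |w|
  sol2 <- opmlat:::lcmv_point_solve(w$Ci, -L)
  expect_equal(sol2$power, sol1$power, tolerance = 1e-12)
  expect_equal(abs(sol2$w), abs(sol1$w), tolerance = 1e-10)
})

test_that("rotating the whole world leaves data and F maps unchanged", {
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  arr <- fix_helmet()
  sph <- fix_sphere(arr)
  grid <- fix_grid(sph, spacing = 25)
  lf <- compute_leadfields(arr, grid, sph)
  rot <- function(m) m %*% t(R)
  arr_r <- sensor_array(arr$labels, rot(arr$positions), rot(arr$orientations),
                        arr$role)
  sph_r <- structure(list(center = as.numeric(R %*% sph$center),
                          radius = sph$radius), class = "opm_sphere")
  grid_r <- grid
  grid_r$points <- rot(grid$points)
  grid_r$sphere <- sph_r
  lf_r <- compute_leadfields(arr_r, grid_r, sph_r)
  tr <- simulation_truth(n_trials = 4, seed = 55)
  tr_r <- simulation_truth(source_pos = as.numeric(R %*% c(-53.26, 17.3, 19.03)),
                           source_ori = as.numeric(R %*% tr$source_ori[1, ]),
                           n_trials = 4, seed = 55)
  d0 <- simulate_dataset(tr, arr, lf)
  d1 <- simulate_dataset(tr_r, arr_r, lf_r)
  expect_equal(d1$data, d0$data, tolerance = 1e-10)
  f0 <- band_filter(synthetic_gradiometry(downsample_and_filter(d0))$ds)
  f1 <- band_filter(synthetic_gradiometry(downsample_and_filter(d1))$ds)
  m0 <- f_map(f0, lcmv_weights(f0, lf))
  m1 <- f_map(f1, lcmv_weights(f1, lf_r))
  ## forward-model rotation error (~1e-12) is amplified through
  ## filtering, regression and the covariance inverse
  expect_equal(m1$map$F, m0$map$F, tolerance = 1e-6)
})

test_that("confidence volumes: degenerate exactness and determinism", {
  ## noise-free single source: every bootstrap localizes identically
  fxn <- suppressWarnings(
    recon_fixture(n_trials = 8, seed = 56, noise_fT_rtHz = 0,
                  interference = list(low_amp = 0, line50_amp = 0,
                                      line77_amp = 0)))
  cv <- confidence_volume(fxn$filtered, fxn$lf, "IFG_left", n_boot = 10,
                          seed = 3)
  expect_equal(unname(cv$extent), c(0, 0, 0))
  expect_equal(nrow(unique(cv$peaks)), 1)
  cv2 <- confidence_volume(fx51$filtered, fx51$lf, "IFG_left", n_boot = 10,
                           seed = 9)
  cv3 <- confidence_volume(fx51$filtered, fx51$lf, "IFG_left", n_boot = 10,
                           seed = 9)
  expect_identical(cv2$extent, cv3$extent)
  expect_error(confidence_volume(fx51$filtered, fx51$lf,
                                 rep(FALSE, nrow(fx51$grid$points)),
                                 n_boot = 10, seed = 1),
               class = "opmlat_config_error")
})

test_that("virtual channels recover the source envelope and its sign", {
  fx <- recon_fixture(n_trials = 20, seed = 57)
  w <- lcmv_weights(fx$filtered, fx$lf)
  tc <- source_timecourse(fx$clean, w, fx$target, n_boot = 20, seed = 1)
  tidx <- tc$time >= 0.5 & tc$time <= 2.5
  expect_lt(mean(tc$pct[1, tidx]), 0)           # desynchronization
  ## correlation with the true envelope-induced power profile: compare the
  ## percent-change course with the square of the truth envelope
  env <- opmlat:::task_envelope(tc$time, fx$truth$depth, fx$truth$ramp_s)
  expect_gt(stats::cor(as.numeric(tc$pct), env^2), 0.8)
  ## weight scaling leaves percent change unchanged
  w2 <- w; w2$W <- 3 * w2$W
  tc2 <- source_timecourse(fx$clean, w2, fx$target, n_boot = 20, seed = 1)
  expect_equal(tc2$pct, tc$pct, tolerance = 1e-10)
})

test_that("regularization smooths the noise-only F map monotonically", {
  ## the smoothing effect concerns spatially structured covariance; average
  ## the spatial variance of log F over seeds to sit above Monte-Carlo noise
  arr <- fix_helmet()
  lf <- fix_leadfields(arr, spacing = 20)
  regs <- c(0.01, 0.05, 0.5)
  nch <- 30; ns <- 600; ntr <- 10
  sv <- matrix(NA_real_, 8, 3)
  for (s in 1:8) {
    set.seed(100 + s)
    A <- matrix(rnorm(nch * 3), nch, 3) * 1e-12
    data <- array(0, dim = c(nch, ns, ntr))
    for (t in seq_len(ntr))
      data[, , t] <- A %*% matrix(rnorm(3 * ns), 3, ns) +
        matrix(rnorm(nch * ns, sd = 1e-14), nch, ns)
    ds <- mk_ds(data, 200, arr)
    ds$time <- ds$time - 2
    dsf <- band_filter(ds)
    sv[s, ] <- vapply(regs, function(reg) {
      m <- f_map(dsf, lcmv_weights(dsf, lf, regularization = reg))
      stats::var(m$map$logF, na.rm = TRUE)
    }, numeric(1))
  }
  mu <- colMeans(sv)
  expect_true(all(diff(mu) <= 0.1 * mu[1]))     # non-increasing within MC error
})
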