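# Laterality curves: Eq. arithmetic on supra-threshold counts, antisymmetry,
# saturation, undefined handling, and the trial-bootstrap machinery.

## hand-built statmap over a toy grid: n left points, n right points
toy_map <- function(F_left, F_right) {
  n <- length(F_left) + length(F_right)
  pts <- cbind(c(rep(-30, length(F_left)), rep(30, length(F_right))),
               seq_len(n), 0)
  grid <- structure(list(points = pts, spacing = 10,
                         hemisphere = ifelse(pts[, 1] < 0, "left", "right"),
                         roi_masks = list(L = pts[, 1] < 0, R = pts[, 1] > 0)),
                    class = "opm_grid")
  structure(list(map = data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                                  F = c(F_left, F_right)),
                 grid = grid), class = "opm_statmap")
}

test_that("LI arithmetic follows the supra-threshold count formula", {
  m <- toy_map(F_left = c(5, 5, 5, 5, 5, 5, 5, 5, 5, 5), F_right = rep(0.5, 10))
  li <- laterality_index(m, "L", "R", thresholds = c(1, 2, 3))
  expect_equal(li$curve$LI, c(1, 1, 1))                 # 10 vs 0
  m2 <- toy_map(F_left = c(5, 5), F_right = c(5, 5))
  expect_equal(laterality_index(m2, "L", "R", 2)$curve$LI, 0)
  m3 <- toy_map(F_left = c(5, 5, 5), F_right = c(5, 0.1, 0.1))
  expect_equal(laterality_index(m3, "L", "R", 2)$curve$LI, 0.5)  # 3 vs 1
  ## counts use F >= threshold (boundary included)
  m4 <- toy_map(F_left = 2, F_right = 0.5)
  expect_equal(laterality_index(m4, "L", "R", 2)$curve$count_left, 1)
})

test_that("LI is antisymmetric, saturating, and undefined entries are flagged", {
  set.seed(61)
  m <- toy_map(F_left = runif(20, 1, 10), F_right = runif(20, 1, 4))
  th <- seq(1, 15, length.out = 29)
  li <- laterality_index(m, "L", "R", th)
  li_sw <- laterality_index(m, "R", "L", th)
  def <- li$curve$defined
  expect_equal(li_sw$curve$LI[def], -li$curve$LI[def])  # exact antisymmetry
  ## counts non-increasing in threshold
  expect_true(all(diff(li$curve$count_left) <= 0))
  expect_true(all(diff(li$curve$count_right) <= 0))
  ## saturation: where countR = 0 and countL > 0, LI = 1
  sat <- li$curve$count_right == 0 & li$curve$count_left > 0
  expect_true(any(sat))
  expect_true(all(li$curve$LI[sat] == 1))
  ## undefined entries are NA + flagged, never silent zeros
  und <- !li$curve$defined
  expect_true(any(und))                                 # thresholds above max F
  expect_true(all(is.na(li$curve$LI[und])))
  ## validation
  gridmask <- m$grid$roi_masks$L
  expect_error(laterality_index(m, "L", "L", th), class = "opmlat_config_error")
  expect_error(laterality_index(m, "L", "R", c(3, 2)),
               class = "opmlat_config_error")
})

test_that("bootstrap LI: near-noiseless left source gives LI 1 with degenerate CIs", {
  ## note: with *exactly* zero noise the data are rank one, every virtual
  ## channel is proportional to the same source, and the F map is flat
  ## (LI = 0 by symmetry); a ~1 fT noise floor restores the intended
  ## degenerate behaviour of a perfectly lateralized map
  arr <- fix_helmet()
  sph <- fix_sphere(arr)
  grid <- fix_grid(sph, spacing = 20)
  lf <- compute_leadfields(arr, grid, sph)
  target <- which.min(colSums((t(grid$points) - c(-53.26, 17.3, 19.03))^2))
  truth <- simulation_truth(source_pos = grid$points[target, ],
                            n_trials = 8, seed = 62, noise_fT_rtHz = 1,
                            interference = list(low_amp = 0, line50_amp = 0,
                                                line77_amp = 0))
  ds <- suppressWarnings(simulate_dataset(truth, arr, lf))
  dsf <- band_filter(suppressWarnings(synthetic_gradiometry(
    downsample_and_filter(ds)))$ds)
  li <- bootstrap_li(dsf, lf, "IFG_left", "IFG_right",
                     thresholds = seq(1.25, 2.5, by = 0.25), n_boot = 12,
                     seed = 5)
  def <- li$curve$defined
  expect_true(any(def))
  expect_true(all(li$curve$LI[def] == 1))
  ## zero-width [1, 1] CIs on the mid-threshold range
  mid <- li$ci$threshold >= 1.75 & li$ci$threshold <= 2.25
  expect_true(all(li$ci$ci_low[mid] == 1 & li$ci$ci_high[mid] == 1))
  ## determinism under fixed seed
  li2 <- bootstrap_li(dsf, lf, "IFG_left", "IFG_right",
                      thresholds = seq(1.25, 2.5, by = 0.25), n_boot = 12,
                      seed = 5)
  expect_identical(li2$replicates, li$replicates)
  expect_error(bootstrap_li(dsf, lf, "IFG_left", "IFG_left", n_boot = 5,
                            seed = 1),
               class = "opmlat_config_error")
})

test_that("x-mirrored simulations negate the LI curve", {
  arr <- fix_helmet()
  sph <- fix_sphere(arr)
  grid <- fix_grid(sph, spacing = 20)
  lf <- compute_leadfields(arr, grid, sph)
  run_li <- function(pos, seed) {
    truth <- simulation_truth(source_pos = pos, n_trials = 12, seed = seed)
    ds <- suppressWarnings(simulate_dataset(truth, arr, lf))
    dsf <- band_filter(synthetic_gradiometry(downsample_and_filter(ds))$ds)
    bootstrap_li(dsf, lf, "IFG_left", "IFG_right",
                 thresholds = seq(1.25, 2.5, by = 0.25), n_boot = 15, seed = 3)
  }
  li_l <- run_li(c(-53.26, 17.3, 19.03), seed = 63)
  li_r <- run_li(c(53.26, 17.3, 19.03), seed = 63)
  both <- li_l$curve$defined & li_r$curve$defined
  expect_true(any(both))
  ## negated within the bootstrap CI width at each defined threshold
  width <- pmax(li_l$ci$ci_high - li_l$ci$ci_low,
                li_r$ci$ci_high - li_r$ci$ci_low, 0.1)[both]
  expect_true(all(abs(li_l$curve$LI[both] + li_r$curve$LI[both]) <= width + 1e-9))
  expect_true(all(li_l$curve$LI[both] > 0))
  expect_true(all(li_r$curve$LI[both] < 0))
})
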