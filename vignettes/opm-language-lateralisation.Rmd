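---
title: "Mapping language lateralisation with simulated wearable OPM-MEG arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping language lateralisation with simulated wearable OPM-MEG arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Covert verb generation produces a robust decrease of 15-30 Hz (beta band)
oscillatory power over left frontal cortex in most people, and the
left/right asymmetry of that desynchronization is a clinically useful index
of language dominance. Wearable on-scalp magnetometer (OPM) arrays can
record this effect without cryogenics, but they are magnetometers: they see
environmental interference that gradiometer-based systems reject by
construction, and their data need a reference-array regression step
("synthetic gradiometry") before source analysis.

`opmlat` implements the full analysis chain for this paradigm — and,
because no recordings of this kind are publicly deposited, a synthetic-data
generator that states the world the chain assumes. The package is intended
both as a reusable pipeline for simulated OPM studies and as a test bed for
the statistical behaviour of each stage.

## The model

**Forward model.** Sources are current dipoles inside a homogeneous
conducting sphere; the field at a sensor is the analytic (Sarvas) solution
projected on the sensor's radial sensing axis. For a sphere this coincides
with the single-shell model used for real data, with two structural
properties the tests rely on: dipoles with a radial moment are magnetically
silent, and the field depends on the sphere centre but not its radius. The
sphere stands in for a subject's inner-skull surface: it is fit to the
scalp sensor positions by least squares and shrunk by a 15 mm
scalp-to-inner-skull margin (plus the 6.5 mm sensor stand-off, since the
sensitive cell of an OPM sits above the scalp).

**Synthetic data.** Each trial is `[-2 s, +3 s]` around task onset at
1000 Hz (3 s task, ~2 s rest; 120 trials by default). The source time
course is Gaussian noise band-passed to 15-30 Hz whose amplitude envelope
drops by the desynchronization depth `d` during the task with a 200 ms
cosine ramp; the band power therefore drops by `1 - (1-d)^2` (64% for the
default `d = 0.4`). Sensor data are lead field x source, plus
interference, plus white sensor noise (default 15 fT/sqrt(Hz), a typical
commercial-OPM noise floor). The interference model has six temporal
components — four slow (< 10 Hz) random-walk drifts, one 50 Hz mains line
and one 77 Hz line mimicking the aliased on-board modulation field — whose
spatial patterns are rank-4 and sampled by both the scalp and the 4-channel
reference array. That rank restriction is deliberate: it makes the
reference regression well-specified, so its failure modes can be probed
separately by switching on a fifth, reference-invisible component
(`misspecified = TRUE`).

**Preprocessing.** 50 Hz notch (2nd-order biquad, Q = 35) and 75-79 Hz
band-stop (4th-order Butterworth) at the acquisition rate, an 80 Hz
anti-alias low-pass, 5x decimation to 200 Hz — all zero-phase
(forward-backward). Synthetic gradiometry then regresses the reference
channels (plus an intercept; harmless for mean-centred data, physically
sensible for magnetometers) out of every scalp channel *per trial*, via the
Moore-Penrose pseudoinverse, to absorb interference non-stationarity. The
expected cost is a `k/n` leakage of brain variance for `k` regressors over
`n` samples — about 0.5% at 5 regressors and 1000 samples — which the test
suite verifies empirically.

**Sensor-level spectra.** Sliding-window Slepian multitaper power,
window 1 s, step 0.1 s. "3 Hz bandwidth with 1 s resolution" is read as the
*full* smoothing bandwidth: half-bandwidth W = 1.5 Hz, hence
`floor(2 * 1.5 * 1) - 1 = 2` tapers; the half-bandwidth reading (W = 3 Hz,
5 tapers) is available via `half_bandwidth = 3` since the upstream
convention cannot be pinned down. Band power is converted to percent change
from the rest-period mean on the trial-averaged spectrogram; variability is
a trial bootstrap (100 resamples). Per-bin significance uses a
maximum-statistic familywise correction by default: the threshold is the
95th percentile of the bootstrap distribution of the largest deviation over
all channels and bins. This choice is deliberate — percentile intervals at
Bonferroni depth (`alpha`/#tests ~ 1e-3 to 1e-5) are not estimable from
O(100) replicates, and a normal-approximation Bonferroni is anticonservative
because small-trial-count band-power ratios are heavy-tailed; the
maximum-statistic calibration respects both the correlation structure of
overlapping windows and those tails, and empirically controls the null
familywise rate. `correction = "bonferroni"` (normal-approximation,
corrected over channels x bins) remains available. Windows that would
overrun the epoch are dropped, not padded.

**Source reconstruction.** Scalar LCMV beamformer: the covariance is pooled
over whole, band-filtered (5th-order bidirectional Butterworth, 15-30 Hz)
epochs; `0.05 * mean(diag(C))` diagonal loading is the default
regularization (unstated upstream, pinned in all acceptance runs). Lead
fields of a spherical conductor have rank 2, so the orientation of maximal
power is found in the rank-truncated moment subspace (relative singular
value cut 1e-6) as the generalized eigenvector; weights are unit-gain.
Points with an exactly silent lead field (the sphere centre) get NA, never
a spurious value. The statistic contrasts the beamformed variance of the
final rest second against the first task second as a per-trial-mean ratio,
two-sided on log F. Because the paradigm's effect is a power *decrease*,
the reported F is `max(ratio, 1/ratio)` with the direction kept in a `sign`
column; this keeps the conventional F >= 1 thresholding of the laterality
sweep well defined. P values use an F reference with
`trials x 2BT` degrees of freedom per window (spectral dof counting,
B = 15 Hz, T = 1 s; a package convention, exposed as `dof`), and maps are
thresholded with Benjamini-Hochberg FDR at q = 0.05.

**Confidence volumes and laterality.** Trial bootstraps rerun
covariance -> orientations -> weights -> F map per resample. The
localisation confidence volume is twice the per-axis SD of the
ROI-restricted bootstrap peaks (with a deterministic near-tie rule — first
point within 1e-9 relative of the maximum — so that degenerate noise-free
data give zero extent). The laterality index
`LI = (nL - nR) / (nL + nR)` counts supra-threshold (`F >= t`) voxels in
mirrored inferior-frontal ROI balls (radius 20 mm around (-53.26, 17.3,
19.03) and its x-mirror — configurable; atlas masks can be supplied as
logical vectors over grid points). Thresholds sweep 29 values over
[1, 15]; CIs are 2.5/97.5 bootstrap percentiles over *defined* replicates,
and thresholds where both counts are zero are reported as missing, never
clamped to zero.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `depth` | 0.4 | fraction of source amplitude | envelope drop during task; band power drops by `1-(1-d)^2` = 64% |
| `amplitude_nAm` | 20 | nA m RMS | calibrated so the best sensor sees a few hundred fT and sensor-level changes of tens of percent; artifact-chosen, not literature-derived |
| `noise_fT_rtHz` | 15 | fT/sqrt(Hz) | typical commercial OPM noise floor |
| `low_amp` | 30 | pT per channel | post-nulling drift scale; far above brain signal, mostly below 10 Hz |
| `regularization` | 0.05 | fraction of mean sensor variance | diagonal loading; smaller values sharpen but can miss off-grid sources on coarse grids |
| `grid spacing` | 5 | mm | display/analysis sampling; Monte-Carlo tests use 10-20 mm for speed |
| `half_bandwidth` | 1.5 | Hz | multitaper smoothing; 2 tapers at 1 s windows |
| `n_boot` | 100 (50 for confidence volumes) | — | trial bootstrap sizes |

## What the generator does and does not emulate

It emulates: the task timing and trial count; the sensor geometry
conventions (26 radial scalp channels over bilateral frontotemporal
patches, 4 distant references, 6.5 mm stand-off); the +/-1.5 nT dynamic
range (violations are flagged, never silently clipped); rank-limited
common-mode interference with mains and modulation lines; and white sensor
noise. It does not emulate head motion, sensor cross-talk, cortical
geometry (sources are free dipoles in a sphere, not constrained to a
mesh), physiological artifacts, or 1/f neural background. A green test
therefore establishes that the chain recovers what it assumes — a
lateralized band-limited power drop under well-specified interference —
not that it is robust to every failure mode of real recordings. The
misspecified-interference variant exists precisely to probe the first such
failure mode.

## Numerical choices and degenerate inputs

* Filters are designed as analog Butterworth prototypes mapped by the
  bilinear transform (verified coefficient-exact against a reference DSP
  implementation) and applied forward-backward with odd-reflection padding;
  column means are removed before filtering and restored through the DC
  gain, suppressing startup transients.
* Slepian tapers come from the symmetric tridiagonal eigenproblem; signs
  follow the positive-mean / positive-slope convention.
* The sphere fit is the algebraic (Kasa) least-squares fit — exact on
  exact spheres, and within a millimetre of the geometric optimum at
  realistic perturbations.
* Exactly silent grid points (zero lead field) yield NA statistics and are
  excluded from FDR; near-ties in bootstrap peak selection resolve to the
  first index within 1e-9 relative of the maximum.
* With *exactly* zero sensor noise and a single source the data are rank
  one and every virtual channel is proportional to the same time course, so
  the F map is flat and the LI degenerates to ~0 by ROI symmetry; the
  documented degenerate behaviour (LI = 1, zero-width CIs) needs any
  non-zero noise floor. Tests use ~1 fT/sqrt(Hz).
* The ratio-F statistic saturates at `1/(1-d)^2` (~2.78 at the default
  depth), so high laterality thresholds are reported as undefined rather
  than supra-threshold; lateralisation saturates at low thresholds.
* HDF5 containers are content-deterministic under a fixed seed; raw bytes
  can differ because HDF5 object headers embed write timestamps.

## Open design points resolved here

* Regression order: reference regression runs after filtering and
  downsampling (recorded in provenance); the stages are separable if a
  different order is wanted.
* Supra-threshold counting uses `F >= t` (boundary included), pinned by a
  test.
* The midline band `|x| < 0.5 mm` is excluded from hemisphere labels to
  keep LI denominators well defined.
* The default helmet layout is a synthetic stand-in (golden-angle spirals
  over frontotemporal patches); no published coordinates exist for such
  arrays, and every layout parameter is configurable.

## Known limitations

Single-sphere conductor only (no BEM/FEM); radial-axis sensing only; the
F map's p values rest on an approximate dof convention and are used for
FDR ranking rather than calibrated inference; Monte-Carlo acceptance tests
run at reduced run counts (12-20 seeds) and 20 trials per run to fit a
fixed compute budget, with thresholds scaled proportionally.
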