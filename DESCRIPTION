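Package: opmlat
Title: Language Lateralisation Analysis for Wearable OPM-MEG Arrays
Version: 0.1.0
Authors@R:
    person("OPM", "Lateralisation Maintainers", email = "maintainers@opmlat.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of on-scalp optically pumped magnetometer
    (OPM) magnetoencephalography recordings of a lateralised beta-band (15-30 Hz)
    desynchronization, as used in covert verb-generation language mapping.
    Provides a current-dipole-in-a-sphere forward model, a trial-epoched
    synthetic-data generator with common-mode interference and reference
    sensors, synthetic gradiometry (per-trial reference-array regression),
    multitaper time-frequency analysis with bootstrap standard errors, scalar
    LCMV beamformer source localisation with F-statistic maps and FDR
    thresholding, bootstrap confidence volumes for peak localisation, and
    threshold-indexed laterality-index curves with bootstrap confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
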