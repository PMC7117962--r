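Package: lfpref
Title: Reference-Scheme Effects on Power and Phase of Multi-Electrode
    Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Vikram", "Shenoy", email = "vshenoy@example.org",
           role = c("aut", "cre"))
Description: Tools to study how the choice of reference scheme (single
    wire, average, bipolar, current source density) alters spectral and
    phase statistics of local field potentials recorded on a regular
    2D microelectrode grid.  Provides electrode-grid geometry and pair
    bookkeeping, re-referencing transforms with correct virtual-electrode
    geometry, single/multi-taper (Slepian) spectral estimation with
    amplifier roll-off correction and noise-frequency masking, sliding
    window power-law (1/f) slope fitting, phase coherence and circular
    statistics including pairwise phase consistency, analyses of the
    average-reference phase-flip mechanism, and a synthetic-data
    generator producing epoched recordings with a frequency-dependent
    globally shared component and Rayleigh-amplitude spectral
    coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
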