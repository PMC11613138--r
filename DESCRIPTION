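Package: meltfold
Title: Hairpin Versus Homoduplex Folding Analysis of Partially
    Palindromic DNA Oligonucleotides from Multi-Technique Melting Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to detect and quantify hairpin versus mismatched
    homoduplex folding of partially palindromic DNA oligonucleotides
    from melting experiments.  Includes singular-value-decomposition
    factor analysis of temperature-dependent UV absorption spectra,
    coupled hairpin/homoduplex equilibrium thermochemistry, two-state
    van't Hoff melting fits of UV scores and NMR chemical-shift
    profiles with linear state baselines, a simultaneous UV+NMR
    combined-model fit yielding duplex-fraction curves, NOESY
    cross-peak distance calibration by the isolated-spin-pair
    sixth-power rule with restraint-table export, fluorescence
    titration unmixing for homoduplex association constants, and
    seeded synthetic-data generators for every input the pipeline
    consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
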