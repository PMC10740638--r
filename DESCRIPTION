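Package: isobolr
Title: Isobolographic Synergy Analysis for Antinociceptive Drug Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of antinociceptive drug-combination studies: conversion of
    cutoff-censored hot-plate latencies to the percent maximum possible effect
    (%MPE) scale, ED50 estimation by nonlinear Hill-model regression with
    delta-method and bootstrap uncertainty, Loewe isobolographic additivity
    (potency ratio, theoretical additive ED50, interaction index, synergy
    classification), and chronic-pain (spinal nerve ligation) behavioral
    time-course statistics with Dunnett many-to-one comparisons. Includes a
    seeded synthetic-data generator emulating the hot-plate and spinal nerve
    ligation designs so that every pipeline stage is testable without animal
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mvtnorm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
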