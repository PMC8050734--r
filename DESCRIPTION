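Package: rhythmshift
Title: Diurnal Rhythm Detection and Feeding-Entrainment Analysis of Omics Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for diurnal omics time series from
    time-restricted feeding designs: cosinor rhythmicity detection with an
    ensemble p-value (cosinor F, Lomb-Scargle, cosine-template Kendall test,
    Fisher-combined with Brown calibration), two-condition rhythm parameter
    comparison with Wald tests, circular phase-shift folding onto a 0-12 h
    window and entrainment classification (phase-locked / intermediate /
    phase-inverted), 12-h ultradian and free-running period-scan detection,
    phase set enrichment via the Kuiper test with a mean-resultant-length
    magnitude, and Fisher-exact gene-set overrepresentation. Includes a
    seeded synthetic-data generator emulating two-condition 24-h designs
    with ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
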