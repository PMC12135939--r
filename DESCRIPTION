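Package: asymscreen
Title: Left-Right Asymmetry Screening and Quantification for Embryonic
    Heart Looping Studies
Version: 0.1.0
Authors@R:
    person("Asymscreen", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for quantifying left-right
    asymmetry in early mouse heart development. Implements a paired
    left/right bulk-transcriptomic screen (mean-coverage normalization,
    expression flags, P50 filtering, a moderated paired t test, fold-change
    and p-value thresholding, engine consensus, MA statistics), 3D in situ
    hybridization spot quantification (Laplacian-of-Gaussian spot
    detection, midline bisection, Hoechst-based side normalization,
    left/right log2 enrichment ratios, stage profiles), landmark-based
    heart-loop morphometry (notochord-frame alignment, right/left
    ventricle axis angle, venous-pole displacement, tube length, looping
    direction tests), an ultrarare-variant severity filter
    (MAC/REVEL/CADD/PTV), exact small-sample nonparametric tests, and
    seeded synthetic-data generators so every stage is testable without
    any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
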