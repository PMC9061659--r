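Package: perisim
Title: In Silico Static Automated Perimetry: Threshold Strategies,
    Severity Scoring and Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Perisim", "Developers", email = "perisim@example.org",
           role = c("aut", "cre"))
Description: Simulates static automated perimetry on synthetic observers
    with known ground-truth sensitivity surfaces and a
    frequency-of-seeing response model.  Implements a four-phase
    interpolation thresholding strategy of the SPARK Precision type and
    a classic 4-2 full-threshold staircase, instrument decibel-scale
    models with differing dynamic ranges (and the resulting floor
    "plateau" effect), normative-database construction, the standard
    global visual-field indices (MS, MD, PSD, NAPDP), the AGIS 0-20
    glaucoma severity score, and the agreement battery used to compare
    thresholding strategies: Bland-Altman limits of agreement,
    proportional-bias regression, Spearman correlation, the Wilcoxon
    signed-rank test and pointwise bias maps.  A pipeline orchestrates
    the full in-silico study on glaucoma-like (focal loss) and
    cataract-like (diffuse loss) cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
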