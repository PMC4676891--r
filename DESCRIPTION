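Package: glaucsurv
Title: Glaucoma Prevalence Survey Analysis with ISGEO Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnostic and statistical machinery for population-based
    glaucoma prevalence surveys of adults aged 40 years and above.
    Implements frequency-doubling technology (FDT C-20) visual field
    grading with reliability rules, derivation of population-specific
    percentile cutoffs for vertical cup:disc ratio (VCDR), VCDR asymmetry
    and intraocular pressure, the four-level ISGEO glaucoma case
    definition with photographic and clinical VCDR fallback, glaucoma
    type assignment from gonioscopy, design-based cluster-sample
    prevalence estimation with direct age standardization, inter-rater
    agreement statistics (Cohen's kappa, Bland-Altman), and a synthetic
    cohort generator that emulates the statistical structure of a
    national blindness survey so that the whole pipeline is testable
    without access to person-level survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
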