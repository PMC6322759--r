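Package: cardioburden
Title: Rare-Variant Triage and Carrier-Burden Testing for Cardiac Gene Panels
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rule-based triage of annotated single-nucleotide variants on a
    70-gene cardiac channelopathy/cardiomyopathy panel, case-level carrier
    aggregation, and carrier- and allele-burden comparison against reference
    populations using exact two-by-two tests under a one-carrier-per-individual
    assumption. Includes a Monte Carlo permutation comparison of
    pathogenic-variant proportions between variant cohorts, a synthetic cohort
    generator with known ground truth for end-to-end validation, and a packaged
    example cohort of putative pathogenic variants observed in 290 stillbirth
    cases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
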