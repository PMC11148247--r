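Package: founderhap
Title: Founder-Variant Haplotype Dating, Read-Depth CNV Detection and
    Cohort Penetrance Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytics for characterising a founder copy-number variant in a
    clinical cohort: read-depth copy-number-variant detection on targeted
    gene-panel count matrices, delineation of the shared founder haplotype
    from phased microsatellite haplotypes, linkage-disequilibrium based
    estimation of the founder-variant age via the Haldane map function,
    haplotype-match-by-chance probabilities from intragenic SNP frequencies,
    point-based ACMG/ClinGen copy-number-loss classification, and penetrance,
    outcome and group-comparison statistics for cascade-screening cohorts.
    Includes seeded simulators for founder-haplotype descent with
    recombination, panel read-depth matrices with embedded deletions, and a
    deterministic cohort fixture, used to validate every estimator against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
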