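Package: kindredX
Title: Kindred-Aware Variant Filtering for Male X-Chromosome Exome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Filters and prioritizes candidate disease-causing variants in
    cohorts of affected hemizygous males sequenced on the X chromosome.
    Implements strand-representation and inter-variant proximity pre-filters,
    identity-based relatedness estimation, sliding-window detection of shared
    identical-by-descent segments, an affected-kindred/cross-cohort filter
    with clinical rescue of recurrent pathogenic variants, reference-panel
    subtraction filters with a female-carrier probability model for the
    minor-allele-frequency cutoff, and hypergeometric gene-set enrichment.
    A synthetic cohort simulator generates exome-like variant call sets,
    reference panels, and ground truth so the whole pipeline can be exercised
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
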