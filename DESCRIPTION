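Package: varmend
Title: Tiered Variant Prioritization, Trio Inheritance Filtering, and
    Star-Allele Calling for Mendelian Genome Interpretation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting whole-genome or exome variant calls in a
    clinical genetics setting. Implements a two-track, four-tier
    prioritization of candidate Mendelian disease-risk variants driven by
    reported-mutation catalogs, multi-source allele frequencies, and
    conservation and pathogenicity consensus scores; a three-state hidden
    Markov model with distance-scaled transitions that segments
    father-mother-child trio genotype data into good-data, reference
    compression, and Mendelian-inheritance-abnormality-rich regions and
    soft-labels the VCF FILTER field; five trio candidate-discovery modes
    (de novo, compound heterozygous, rare homozygous, hemizygous over
    deletions, and dominant with reduced penetrance); an unphased star-allele
    diplotype caller for pharmacogenes with single-variant drug-response
    annotation; and seeded synthetic-data generators with ground-truth
    manifests so the whole pipeline is testable without external downloads.
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
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    vcfR,
    Biostrings,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
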