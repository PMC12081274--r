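Package: cbsprio
Title: Prioritization of CTCF Binding-Site Variants from Binding Activity,
    Allelic PWM Scores, and Mutability-Adjusted Singleton Proportions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for prioritizing single-nucleotide variants that fall in
    CTCF binding sites (CBSs). Summarizes a ChIP-seq Z-score matrix over biosamples
    into a per-locus binding-activity score, builds a CBS catalog by position-weight-
    matrix scanning with cCRE/rDHS support and exclusion filtering, scores REF/ALT
    alleles to obtain delta-PWM with an importance-sampling significance estimate
    (with an exact small-motif oracle), and evaluates selective constraint with the
    mutability-adjusted proportion of singletons (MAPS) calibrated on a synonymous
    variant class. Includes a synthetic-data generator that emulates every input
    (genome, motifs, activity matrix, gnomAD-like variants, mutation rates,
    conservation track) with known ground truth, so the whole pipeline is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    dplyr,
    tibble,
    readr,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
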