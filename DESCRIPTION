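Package: polyped
Title: Pedigree Genome Tracing, Selection Scans and Genetic Load in
    Allotetraploid Rapeseed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the genome of a young allotetraploid crop
    cultivar against its breeding pedigree and population panels: block-wise
    identity-by-descent assignment of a derived assembly to its pedigree
    parents by longest accumulated exact-match coverage, sliding-window
    nucleotide diversity and Weir-Cockerham FST scans with Z-transformed
    divergent-region calling, window-based local-ancestry painting with
    near-fixed introgression summaries, and deleterious-variant genetic-load
    spectra with per-individual load ratios split by subgenome. Includes a
    coalescent-free allotetraploid pedigree and population simulator with
    exact ground truth so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    withr,
    yaml,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
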