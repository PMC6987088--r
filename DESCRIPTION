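Package: proxseq
Title: Analysis of Proximity RNA-seq Co-Barcoding Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for droplet co-barcoding (Proximity RNA-seq) experiments,
    in which RNAs residing in the same crosslinked subcellular particle are
    reverse-transcribed with a shared bead barcode so that shared barcodes
    report spatial RNA proximity. The package validates the fixed primer in
    raw reads, extracts and filters bead barcodes, collapses sequencing-error
    barcode variants into barcode groups, resolves a priority-based custom
    transcriptome annotation, assigns mapped reads to features, collapses
    PCR and within-particle duplicates into proxy reads, counts pairwise RNA
    co-barcoding, and derives significance estimates for RNA-RNA proximity
    from constrained Monte Carlo randomizations that preserve per-transcript
    abundance and the barcode-group size distribution, with an empirical
    local background and Benjamini-Hochberg correction. Per-transcript
    valency (the distribution over barcode-group sizes) is computed and
    classified as a proxy for local RNA density. A seed-deterministic
    synthetic data generator emulates bead barcoding, Poisson droplet
    loading, Zipf-like transcript abundance and planted proximal pairs so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
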