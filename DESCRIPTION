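Package: fingerquant
Title: Marker-Gene Fingerprints and Copy-Number-Aware Quantification of
    Synthetic Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-isolate marker-gene fingerprints (all intragenomic
    haplotypes of a multi-copy gene such as 16S rRNA, together with their copy
    numbers) from a genome assembly and its raw sequencing reads; trims
    fingerprints to amplicon regions with in-silico degenerate primers;
    quantifies synthetic-community members from amplicon reads by k-mer
    pseudoalignment with alignment-identity validation, EM resolution of shared
    reads and copy-number normalization; and evaluates the resulting
    compositions against a reference dataset with identity clustering, NRMSE
    and presence/absence metrics. Includes a simulator that generates genomes
    with embedded multi-copy marker variants, shotgun reads and amplicon reads
    with known ground truth, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    BiocGenerics,
    tibble,
    dplyr,
    purrr,
    rlang,
    stringi,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
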