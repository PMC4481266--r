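Package: txrefine
Title: Transcript Structure Refinement and Reference Genome Error Detection from RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for refining assembled transcriptome annotations and for
    flagging candidate reference-genome errors from RNA-seq evidence. Merges
    fragmented transcript models using long-read end-segment links and
    non-canonical splice junctions, filters low-evidence single- and two-exon
    transcripts by local-alignment bit score, scores transcripts against
    annotation sources by gene-locus overlap and exact intron concordance,
    applies hard filters and genotype-category classification to variant
    calls, normalizes indels to a canonical left-aligned form, and evaluates
    the effect of each variant on the longest open reading frame of its host
    transcript. Variants that extend an ORF and are homozygous in genomic
    resequencing of the reference individual are called as candidate
    reference-genome errors, sub-classified as homopolymer slips or
    intron-mimicking deletions. A deterministic synthetic-data generator with
    planted ground truth makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    VariantAnnotation,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
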