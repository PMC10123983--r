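Package: splicevar
Title: Spliced Alignment Transformation and Benchmarking for Long-Read
    RNA-seq Variant Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Makes spliced long-read RNA-seq alignments suitable for DNA
    variant callers by splitting reads at intron (N) CIGAR operations and
    restoring the original alignment flag to every resulting exon fragment.
    Also provides the surrounding benchmarking toolkit: QUAL filtering and
    SNP/indel partitioning of callsets, merging of SNP and indel calls with
    QUAL-based same-site deduplication, construction of high-confidence truth
    regions (variant-density windows, short-read coverage bounds, long-read
    exonic coverage), per-site annotation (exonic coverage and
    intron-containing-read proportion, splice-junction proximity, homopolymer
    context, allele-specific expression via a chi-squared goodness-of-fit
    test with Benjamini-Hochberg correction), stratified precision/recall/F1
    evaluation, set-intersection summaries, and a deterministic synthetic
    fixture generator producing a toy reference, planted variants and spliced
    alignments.
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
    stringr,
    ggplot2,
    generics,
    readr,
    withr,
    stats,
    utils,
    Rsamtools,
    GenomicAlignments,
    Biostrings,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
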