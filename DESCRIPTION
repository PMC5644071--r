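Package: lincorigins
Title: Synteny-Constrained Homology Search and Origin Classification for
    Human lincRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Traces the evolutionary origins of long intergenic non-coding
    RNAs (lincRNAs) by synteny-constrained homology search across multiple
    vertebrate genomes. Implements a seed-and-extend local DNA aligner with
    Karlin-Altschul E-value statistics, flanking-gene synteny filtering and
    cross-species selection of putative orthologs, classification of
    orthologs by genomic context (intergenic, protein-coding, non-coding)
    with exon/intron/intergenic and transposable-element coverage profiles,
    typing of pseudogenization scenarios (unitary versus duplicated), a
    dinucleotide-preserving shuffle null for homology calls, and a bootstrap
    enrichment test for competing endogenous RNA (ceRNA) pairs. Ships a
    synthetic comparative-genome generator with planted ground truth so the
    whole pipeline is testable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    S4Vectors,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
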