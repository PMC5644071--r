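# Internal sequence helpers.  The aligner works on integer-encoded DNA:
# A=0, C=1, G=2, T=3, N=4.  Any other letter is rejected at encode time so
# IUPAC ambiguity codes beyond N cannot slip through to the scorer.

.dna_enc_table <- local({
  tab <- rep(NA_integer_, 256)
  tab[utf8ToInt("A")] <- 0L; tab[utf8ToInt("a")] <- 0L
  tab[utf8ToInt("C")] <- 1L; tab[utf8ToInt("c")] <- 1L
  tab[utf8ToInt("G")] <- 2L; tab[utf8ToInt("g")] <- 2L
  tab[utf8ToInt("T")] <- 3L; tab[utf8ToInt("t")] <- 3L
  tab[utf8ToInt("N")] <- 4L; tab[utf8ToInt("n")] <- 4L
  tab
})

encode_dna <- function(x) {
  x <- as.character(x)
  stopifnot(length(x) == 1L)
  raw <- utf8ToInt(x)
  out <- .dna_enc_table[raw]
  if (anyNA(out)) {
    bad <- unique(intToUtf8(raw[is.na(out)], multiple = TRUE))
    stop("sequence contains letters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ", "))
  }
  out
}

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# single-interval GRanges constructor used throughout
gr1 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_scalar_interval <- function(region) {
  stopifnot(is(region, "GRanges"), length(region) == 1L)
}
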