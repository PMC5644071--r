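# In-code fixtures: tiny genome bundles built directly, and one shared
# synthetic dataset + pipeline run reused by the integration tests (built
# lazily, once per test session).

.fixture_env <- new.env(parent = emptyenv())

# a one-chromosome bundle from a compact gene table:
#   genes: data.frame(gene_id, biotype, exon_starts, exon_ends [";"-sep],
#                     optional pseudogene_subtype)
make_bundle <- function(seq_len = 10000L, genes = NULL, repeats = NULL,
                        species = "test", chrom = "chr1", seq = NULL) {
  seqs <- Biostrings::DNAStringSet(seq %||% random_seq(seq_len))
  names(seqs) <- chrom
  if (is.null(genes)) {
    g <- GenomicRanges::GRanges()
    S4Vectors::mcols(g)$gene_id <- character(0)
    S4Vectors::mcols(g)$biotype <- character(0)
    e <- g
  } else {
    ex <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i)
      data.frame(gene_id = genes$gene_id[i],
                 start = as.integer(strsplit(genes$exon_starts[i], ";")[[1]]),
                 end = as.integer(strsplit(genes$exon_ends[i], ";")[[1]]))))
    e <- GenomicRanges::GRanges(chrom, IRanges::IRanges(ex$start, ex$end))
    S4Vectors::mcols(e)$gene_id <- ex$gene_id
    g <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(rep(1L, nrow(genes)), rep(2L, nrow(genes))))
    S4Vectors::mcols(g)$gene_id <- genes$gene_id
    S4Vectors::mcols(g)$biotype <- genes$biotype
    if (!is.null(genes$pseudogene_subtype))
      S4Vectors::mcols(g)$pseudogene_subtype <- genes$pseudogene_subtype
  }
  r <- if (is.null(repeats)) GenomicRanges::GRanges() else {
    rr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(repeats$start, repeats$end))
    S4Vectors::mcols(rr)$repeat_name <- repeats$repeat_name
    S4Vectors::mcols(rr)$repeat_class <- repeats$repeat_class
    rr
  }
  genome_bundle(species, seqs, g, e, r)
}

make_linc_set <- function(ids, starts, ends, seqs, chrom = "chr1") {
  spans <- GenomicRanges::GRanges(rep(chrom, length(ids)),
                                  IRanges::IRanges(starts, ends))
  S4Vectors::mcols(spans)$linc_id <- ids
  cdna <- Biostrings::DNAStringSet(seqs)
  names(cdna) <- ids
  structure(list(spans = spans, cdna = cdna), class = "linc_set")
}

# shared synthetic dataset at the default study conditions (3 species,
# divergence 0.05, 5 lincRNAs per scenario) plus a full pipeline run
shared_synth <- function() {
  if (!is.null(.fixture_env$shared)) return(.fixture_env$shared)
  dir <- file.path(tempdir(), "lincorigins-shared-sim")
  sim <- generate_comparative_dataset(sim_config(rng_seed = 42L), dir)
  cfg <- pipeline_config_from_sim(dir, rng_seed = 42L)
  res <- run_pipeline(cfg, verbose = FALSE)
  .fixture_env$shared <- list(sim = sim, cfg = cfg, res = res, dir = dir)
  .fixture_env$shared
}
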