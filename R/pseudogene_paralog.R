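# Relating lincRNAs to human pseudogenes and to putative paralogs of their
# aligned proteins, and typing the pseudogenization scenario: a lincRNA
# whose exonic orthologs are coding in other species but which has no human
# paralog and sits on/near a human pseudogene points to a unitary
# pseudogene origin; a significant human paralog points to a duplicated
# pseudogene origin.

#' Protein-coding genes overlapped by putative orthologs ("aligned proteins")
#'
#' For each protein-coding putative ortholog, reports every protein-coding
#' gene of the target species overlapping its region (strand-blind).
#'
#' @param orthologs data.frame of selected putative orthologs with columns
#'   `species`, `chrom`, `start`, `end`, `class`.
#' @param bundles Named list of [genome_bundle()] objects keyed by species.
#' @return data.frame with columns `species`, `gene_id` (unique rows).
#' @export
aligned_proteins <- function(orthologs, bundles) {
  rows <- list()
  keep <- orthologs[orthologs$class == "protein_coding", , drop = FALSE]
  for (r in seq_len(nrow(keep))) {
    b <- bundles[[keep$species[r]]]
    coding <- b$genes[mcols(b$genes)$biotype == "protein_coding"]
    region <- gr1(keep$chrom[r], keep$start[r], keep$end[r])
    ov <- coding[IRanges::overlapsAny(coding, region, ignore.strand = TRUE)]
    if (length(ov))
      rows[[length(rows) + 1L]] <- data.frame(
        species = keep$species[r], gene_id = mcols(ov)$gene_id,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(species = character(0), gene_id = character(0)))
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$species, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Are any two aligned proteins from different species orthologous?
#'
#' @param proteins data.frame with columns `species`, `gene_id`.
#' @param orth An `orthology_map`.
#' @return `TRUE` iff at least one cross-species pair of the aligned
#'   proteins is connected in the orthology map; `FALSE` when fewer than
#'   two species are represented.
#' @export
aligned_protein_orthology_check <- function(proteins, orth) {
  n <- nrow(proteins)
  if (n < 2L || length(unique(proteins$species)) < 2L) return(FALSE)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (proteins$species[i] == proteins$species[j]) next
    if (are_orthologs(orth, proteins$species[i], proteins$gene_id[i],
                      proteins$species[j], proteins$gene_id[j]))
      return(TRUE)
  }
  FALSE
}

#' Spliced exonic sequence of a gene
#'
#' Concatenates the gene's exon union in genomic order (plus strand).
#'
#' @param bundle A [genome_bundle()].
#' @param gene_id Gene identifier.
#' @return Character DNA sequence.
#' @export
spliced_gene_sequence <- function(bundle, gene_id) {
  ex <- bundle$exons[mcols(bundle$exons)$gene_id == gene_id]
  if (!length(ex)) stop("no exons for gene ", gene_id)
  ex <- sort(GenomicRanges::reduce(ex, ignore.strand = TRUE))
  chrom <- as.character(GenomicRanges::seqnames(ex))[1L]
  paste(vapply(seq_along(ex), function(i) {
    as.character(Biostrings::subseq(bundle$seqs[[chrom]],
                                    GenomicRanges::start(ex[i]),
                                    GenomicRanges::end(ex[i])))
  }, character(1)), collapse = "")
}

#' Putative paralogs of a lincRNA
#'
#' The human orthologs (via the orthology map) of the lincRNA's aligned
#' proteins, retained when the lincRNA cDNA aligns to the human gene's
#' spliced exonic sequence with E-value below the cutoff.
#'
#' @param cdna lincRNA cDNA.
#' @param proteins data.frame of aligned proteins (`species`, `gene_id`).
#' @param orth An `orthology_map`.
#' @param human Human [genome_bundle()].
#' @param scheme A [scoring_scheme()].
#' @param ka Cached [ka_params()] (optional).
#' @param human_species Human species label in `orth`.
#' @param evalue_cutoff Significance threshold (default 1e-10).
#' @return Sorted character vector of human gene ids (possibly empty).
#' @export
putative_paralogs <- function(cdna, proteins, orth, human,
                              scheme = scoring_scheme(), ka = NULL,
                              human_species = "human",
                              evalue_cutoff = 1e-10) {
  ka <- ka %||% ka_params(scheme)
  cand <- unique(unlist(lapply(seq_len(nrow(proteins)), function(i)
    ortholog_partners(orth, proteins$species[i], proteins$gene_id[i],
                      human_species))))
  cand <- intersect(cand, mcols(human$genes)$gene_id)
  keep <- vapply(cand, function(g) {
    subj <- spliced_gene_sequence(human, g)
    h <- local_align(cdna, subj, scheme, ka = ka)
    nrow(h) > 0L && min(h$log10_evalue) < log10(evalue_cutoff)
  }, logical(1))
  sort(cand[keep])
}

#' Relation of a lincRNA to human pseudogenes
#'
#' `overlap` when the lincRNA span shares at least 1 bp with a
#' pseudogene-biotype gene span (strand-blind); otherwise `juxtaposed`
#' when the nearest pseudogene boundary lies within `juxtaposition_bp`
#' (inclusive); otherwise `none`.
#'
#' @param linc_span `GRanges` of length 1 (human lincRNA span).
#' @param human Human [genome_bundle()].
#' @param juxtaposition_bp Distance defining "juxtaposed" (default 10 kb).
#' @return List with `relation`, `nearest_pseudogene` (gene id or `NA`)
#'   and `distance` (bp; 0 for overlap, `NA` when none found).
#' @export
pseudogene_relation <- function(linc_span, human, juxtaposition_bp = 10000L) {
  .assert_scalar_interval(linc_span)
  pg <- human$genes[mcols(human$genes)$biotype == "pseudogene"]
  if (!length(pg))
    return(list(relation = "none", nearest_pseudogene = NA_character_,
                distance = NA_integer_))
  d <- GenomicRanges::distance(linc_span, pg, ignore.strand = TRUE)
  if (all(is.na(d)))  # no pseudogene on this chromosome
    return(list(relation = "none", nearest_pseudogene = NA_character_,
                distance = NA_integer_))
  i <- which.min(d)
  dist <- d[i]
  relation <- if (dist == 0L &&
                  IRanges::overlapsAny(linc_span, pg[i], ignore.strand = TRUE))
    "overlap" else if (dist <= juxtaposition_bp) "juxtaposed" else "none"
  list(relation = relation,
       nearest_pseudogene = if (relation == "none") NA_character_ else
         mcols(pg)$gene_id[i],
       distance = if (relation == "none") NA_integer_ else as.integer(dist))
}

#' Pseudogenization-origin hypothesis for a lincRNA
#'
#' Applies to lincRNAs with exonic putative orthologs and no TE coverage:
#' `unitary_candidate` when no human paralog exists and the lincRNA
#' overlaps or is juxtaposed to a pseudogene; `duplicated_candidate` when
#' at least one human paralog exists; otherwise `unclassified`.
#'
#' @param human_paralogs Character vector of putative paralog gene ids.
#' @param relation Pseudogene relation (`"overlap"`, `"juxtaposed"`,
#'   `"none"`).
#' @param eligible Whether the lincRNA meets the preconditions (exonic
#'   ortholog, no TE coverage); when `FALSE` the call is `unclassified`
#'   with a warning.
#' @return One of `"unitary_candidate"`, `"duplicated_candidate"`,
#'   `"unclassified"`.
#' @export
origin_hypothesis <- function(human_paralogs, relation, eligible = TRUE) {
  if (!isTRUE(eligible)) {
    warning("origin_hypothesis applied to an ineligible lincRNA; ",
            "returning unclassified")
    return("unclassified")
  }
  if (length(human_paralogs) > 0L) return("duplicated_candidate")
  if (relation %in% c("overlap", "juxtaposed")) return("unitary_candidate")
  "unclassified"
}
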