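# Synteny-constrained candidate identification and cross-species selection
# of putative orthologs.  The synteny anchor is a pair of conserved
# neighbour protein-coding genes, one upstream and one downstream of the
# lincRNA, whose orthologs must flank the alignment hit in the target
# species within the same window.

#' Neighbouring protein-coding genes of a lincRNA
#'
#' Collects the human protein-coding genes whose span midpoint lies within
#' `window_bp` upstream (respectively downstream) of the lincRNA span
#' boundaries, ordered nearest-first.
#'
#' @param linc_span `GRanges` of length 1 (the lincRNA span) with metadata
#'   column `linc_id`.
#' @param human Human [genome_bundle()].
#' @param window_bp Synteny window (default 750 kb each side).
#' @return An object of class `neighbor_context` with elements `linc_id`,
#'   `upstream`, `downstream` (character vectors of gene ids,
#'   nearest-first) and `window_bp`.
#' @export
neighbor_context <- function(linc_span, human, window_bp = 750000L) {
  .assert_scalar_interval(linc_span)
  coding <- human$genes[mcols(human$genes)$biotype == "protein_coding"]
  coding <- coding[as.character(GenomicRanges::seqnames(coding)) ==
                     as.character(GenomicRanges::seqnames(linc_span))]
  mid <- floor((GenomicRanges::start(coding) + GenomicRanges::end(coding)) / 2)
  d_up <- GenomicRanges::start(linc_span) - mid
  d_dn <- mid - GenomicRanges::end(linc_span)
  up <- which(d_up > 0 & d_up <= window_bp)
  dn <- which(d_dn > 0 & d_dn <= window_bp)
  structure(list(linc_id = mcols(linc_span)$linc_id %||% NA_character_,
                 upstream = mcols(coding)$gene_id[up[order(d_up[up])]],
                 downstream = mcols(coding)$gene_id[dn[order(d_dn[dn])]],
                 window_bp = as.integer(window_bp)),
            class = "neighbor_context")
}

.gene_by_id <- function(bundle, ids) {
  bundle$genes[match(ids, mcols(bundle$genes)$gene_id)]
}

#' Syntenic search windows in a target species
#'
#' For every (upstream, downstream) anchor pair of the context whose
#' orthologs land on the same target chromosome within `2 * window_bp` of
#' each other, emits the interval spanning the two orthologs extended by
#' `window_bp` on each side (clipped to the chromosome).  Overlapping
#' windows of the same anchor pair are merged.
#'
#' @param ctx A [neighbor_context()].
#' @param species Target-species [genome_bundle()].
#' @param orth An `orthology_map`.
#' @param human_species Species label of the human bundle in `orth`.
#' @param window_bp Window size (defaults to the context's).
#' @return `GRanges` with metadata columns `anchor_u`, `anchor_d`.
#' @export
syntenic_windows <- function(ctx, species, orth, human_species = "human",
                             window_bp = ctx$window_bp) {
  stopifnot(inherits(ctx, "neighbor_context"),
            inherits(species, "genome_bundle"),
            inherits(orth, "orthology_map"))
  res <- list()
  known <- mcols(species$genes)$gene_id
  for (u in ctx$upstream) {
    u_ids <- intersect(
      ortholog_partners(orth, human_species, u, species$species), known)
    if (!length(u_ids)) next
    for (d in ctx$downstream) {
      d_ids <- intersect(
        ortholog_partners(orth, human_species, d, species$species), known)
      if (!length(d_ids)) next
      gu <- .gene_by_id(species, u_ids)
      gd <- .gene_by_id(species, d_ids)
      for (i in seq_along(gu)) for (j in seq_along(gd)) {
        if (as.character(GenomicRanges::seqnames(gu[i])) !=
            as.character(GenomicRanges::seqnames(gd[j]))) next
        gap <- max(0L, max(GenomicRanges::start(gu[i]), GenomicRanges::start(gd[j])) -
                     min(GenomicRanges::end(gu[i]), GenomicRanges::end(gd[j])))
        if (gap > 2 * window_bp) next
        chrom <- as.character(GenomicRanges::seqnames(gu[i]))
        lo <- max(1L, min(GenomicRanges::start(gu[i]), GenomicRanges::start(gd[j])) -
                    window_bp)
        hi <- min(length(species$seqs[[chrom]]),
                  max(GenomicRanges::end(gu[i]), GenomicRanges::end(gd[j])) +
                    window_bp)
        w <- gr1(chrom, lo, hi)
        mcols(w)$anchor_u <- u
        mcols(w)$anchor_d <- d
        res[[length(res) + 1L]] <- w
      }
    }
  }
  if (!length(res)) {
    out <- GenomicRanges::GRanges()
    mcols(out)$anchor_u <- character(0)
    mcols(out)$anchor_d <- character(0)
    return(out)
  }
  wins <- do.call(c, res)
  # merge overlapping windows within each anchor pair
  grp <- paste(mcols(wins)$anchor_u, mcols(wins)$anchor_d, sep = "\r")
  merged <- lapply(split(wins, grp), function(g) {
    r <- GenomicRanges::reduce(GenomicRanges::granges(g))
    mcols(r)$anchor_u <- mcols(g)$anchor_u[1L]
    mcols(r)$anchor_d <- mcols(g)$anchor_d[1L]
    r
  })
  out <- unname(do.call(c, unname(merged)))
  sort(out, ignore.strand = TRUE)
}

# side of a gene relative to a hit interval on the same chromosome:
# "left", "right", or NA when overlapping
.flank_side <- function(g_start, g_end, hit_start, hit_end) {
  if (g_end < hit_start) "left" else if (g_start > hit_end) "right" else NA_character_
}

#' Find synteny-anchored ortholog candidates for one lincRNA in one species
#'
#' Aligns the lincRNA cDNA against the merged syntenic windows and retains
#' hits flanked by at least one anchor pair: the ortholog of one anchor
#' entirely on one side of the hit and the ortholog of the other anchor
#' entirely on the other side, each within `window_bp` of the hit.  When
#' several anchor pairs flank a hit, the nearest pair (smallest summed
#' boundary distance) is recorded.
#'
#' @param linc_id lincRNA identifier.
#' @param cdna lincRNA cDNA (character or `DNAString`).
#' @param species Target-species [genome_bundle()].
#' @param ctx The human [neighbor_context()] of this lincRNA.
#' @param orth An `orthology_map`.
#' @param scheme A [scoring_scheme()].
#' @param ka Cached [ka_params()] (optional).
#' @param human_species Species label of the human bundle.
#' @param window_bp Synteny window (defaults to the context's).
#' @param evalue_cutoff E-value threshold for hits (default 1e-10).
#' @return data.frame of candidates: `linc_id`, `species`, `chrom`,
#'   `start`, `end`, `strand`, `score`, `evalue`, `log10_evalue`,
#'   `anchor_u`, `anchor_d`.
#' @export
find_candidates <- function(linc_id, cdna, species, ctx, orth,
                            scheme = scoring_scheme(), ka = NULL,
                            human_species = "human",
                            window_bp = ctx$window_bp,
                            evalue_cutoff = 1e-10) {
  empty <- data.frame(linc_id = character(0), species = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = integer(0), evalue = numeric(0),
                      log10_evalue = numeric(0), anchor_u = character(0),
                      anchor_d = character(0))
  wins <- syntenic_windows(ctx, species, orth, human_species, window_bp)
  if (!length(wins)) return(empty)
  union_wins <- GenomicRanges::reduce(GenomicRanges::granges(wins))
  hits <- search_windows(cdna, species, union_wins, scheme, ka, evalue_cutoff)
  if (nrow(hits) == 0L) return(empty)

  # candidate anchor orthologs, resolved once per context
  anchor_pairs <- unique(data.frame(
    u = rep(ctx$upstream, each = length(ctx$downstream)),
    d = rep(ctx$downstream, times = length(ctx$upstream)),
    stringsAsFactors = FALSE))
  known <- mcols(species$genes)$gene_id
  orth_of <- function(h_gene) intersect(
    ortholog_partners(orth, human_species, h_gene, species$species), known)

  rows <- list()
  for (r in seq_len(nrow(hits))) {
    h <- hits[r, ]
    best <- NULL
    for (p in seq_len(nrow(anchor_pairs))) {
      u <- anchor_pairs$u[p]; d <- anchor_pairs$d[p]
      for (gu_id in orth_of(u)) for (gd_id in orth_of(d)) {
        gu <- .gene_by_id(species, gu_id); gd <- .gene_by_id(species, gd_id)
        if (as.character(GenomicRanges::seqnames(gu)) != h$chrom ||
            as.character(GenomicRanges::seqnames(gd)) != h$chrom) next
        su <- .flank_side(GenomicRanges::start(gu), GenomicRanges::end(gu),
                          h$start, h$end)
        sd <- .flank_side(GenomicRanges::start(gd), GenomicRanges::end(gd),
                          h$start, h$end)
        if (is.na(su) || is.na(sd) || su == sd) next
        dist_u <- if (su == "left") h$start - GenomicRanges::end(gu) else
          GenomicRanges::start(gu) - h$end
        dist_d <- if (sd == "left") h$start - GenomicRanges::end(gd) else
          GenomicRanges::start(gd) - h$end
        if (dist_u > window_bp || dist_d > window_bp) next
        tot <- dist_u + dist_d
        if (is.null(best) || tot < best$tot) best <- list(u = u, d = d, tot = tot)
      }
    }
    if (is.null(best)) next
    rows[[length(rows) + 1L]] <- data.frame(
      linc_id = linc_id, species = species$species, chrom = h$chrom,
      start = h$start, end = h$end, strand = h$strand, score = h$score,
      evalue = h$evalue, log10_evalue = h$log10_evalue,
      anchor_u = best$u, anchor_d = best$d, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select at most one putative ortholog per lincRNA per species
#'
#' Applies the cross-species selection cascade to a candidate table:
#' candidates are grouped across species by their anchor pair; groups
#' supported by fewer than `min_species_support` species are dropped; per
#' species the candidate of the group with the most supporting species
#' wins, ties broken by lowest E-value, remaining ties by smaller
#' (chrom, start).
#'
#' @param candidates data.frame as produced by [find_candidates()]
#'   (possibly several lincRNAs row-bound together).
#' @param min_species_support Minimum number of species a candidate group
#'   must be found in (default 2, i.e. loci seen in only one species are
#'   discarded).
#' @return data.frame with the same columns plus `group_id` and
#'   `species_support`; at most one row per (linc_id, species).
#' @export
select_putative_orthologs <- function(candidates, min_species_support = 2L) {
  empty <- cbind(candidates[0, , drop = FALSE],
                 data.frame(group_id = character(0),
                            species_support = integer(0)))
  if (is.null(candidates) || nrow(candidates) == 0L) return(empty)
  out <- list()
  for (linc in unique(candidates$linc_id)) {
    cc <- candidates[candidates$linc_id == linc, , drop = FALSE]
    cc$group_id <- paste(cc$anchor_u, cc$anchor_d, sep = "|")
    support <- vapply(split(cc$species, cc$group_id),
                      function(s) length(unique(s)), integer(1))
    cc$species_support <- unname(support[cc$group_id])
    cc <- cc[cc$species_support >= min_species_support, , drop = FALSE]
    if (nrow(cc) == 0L) next
    for (sp in unique(cc$species)) {
      cs <- cc[cc$species == sp, , drop = FALSE]
      ord <- order(-cs$species_support, cs$log10_evalue, cs$chrom, cs$start)
      out[[length(out) + 1L]] <- cs[ord[1L], , drop = FALSE]
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$linc_id, res$species), , drop = FALSE]
  rownames(res) <- NULL
  res
}
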