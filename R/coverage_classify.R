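# Classification of putative orthologs by overlapping annotation, and
# exon/intron/intergenic plus transposable-element coverage.  All overlap
# logic is strand-blind; coverages are computed in integer bp on the
# bundle's plain interval tables and divided once at the end, so the
# ternary sums exactly to 1.

# RepeatMasker classes that are not transposable elements
.NON_TE_CLASSES <- c("Simple_repeat", "Low_complexity", "Satellite")

# total bp of the union of [starts, ends] clipped to [qs, qe]
.union_clip_bp <- function(starts, ends, qs, qe) {
  s <- pmax(as.integer(starts), qs)
  e <- pmin(as.integer(ends), qe)
  keep <- s <= e
  if (!any(keep)) return(0L)
  s <- s[keep]; e <- e[keep]
  o <- order(s)
  s <- s[o]; e <- e[o]
  tot <- 0L; cur_s <- s[1L]; cur_e <- e[1L]
  for (i in seq_along(s)[-1L]) {
    if (s[i] > cur_e) {
      tot <- tot + (cur_e - cur_s + 1L)
      cur_s <- s[i]; cur_e <- e[i]
    } else if (e[i] > cur_e) cur_e <- e[i]
  }
  tot + (cur_e - cur_s + 1L)
}

.region_fields <- function(region) {
  if (is(region, "GRanges")) {
    .assert_scalar_interval(region)
    return(list(chrom = as.character(GenomicRanges::seqnames(region)),
                start = GenomicRanges::start(region),
                end = GenomicRanges::end(region)))
  }
  if (is.list(region) && all(c("chrom", "start", "end") %in% names(region)))
    return(list(chrom = as.character(region$chrom),
                start = as.integer(region$start),
                end = as.integer(region$end)))
  stop("region must be a length-1 GRanges or a list with chrom/start/end")
}

#' Classify a putative ortholog by its overlapping annotation
#'
#' `protein_coding` if the region shares at least 1 bp with any
#' protein-coding gene span; otherwise `non_coding` if it overlaps any
#' non-coding gene (lncRNA or short non-coding RNA); otherwise
#' `intergenic`.  Pseudogene-biotype annotations trigger neither class.
#' Overlap is strand-blind.
#'
#' @param region `GRanges` of length 1, or a list/data.frame row with
#'   elements `chrom`, `start`, `end` (1-based closed).
#' @param bundle Target-species [genome_bundle()].
#' @return One of `"protein_coding"`, `"non_coding"`, `"intergenic"`.
#' @export
classify_ortholog <- function(region, bundle) {
  r <- .region_fields(region)
  g <- bundle$gene_tab
  hit <- g$chrom == r$chrom & g$start <= r$end & g$end >= r$start
  if (any(hit & g$biotype == "protein_coding")) return("protein_coding")
  if (any(hit & g$biotype %in% c("lincRNA", "other_noncoding")))
    return("non_coding")
  "intergenic"
}

#' Exon/intron/intergenic coverage profile of a region
#'
#' Exonic bp is the overlap of the region with the exon union of all
#' protein-coding genes it touches; intronic bp is the overlap with those
#' genes' spans minus the exonic bp; intergenic bp is the remainder.  Each
#' is divided by the region length, so the three fractions sum to 1
#' exactly.  A region is labelled `exonic` iff its exon coverage is 100%,
#' `intronic` iff its intron coverage is 100%, otherwise `mixed`.
#'
#' @inheritParams classify_ortholog
#' @return List with `exon_cov`, `intron_cov`, `intergenic_cov`,
#'   `structural_label` and the integer bp counts `exon_bp`, `intron_bp`,
#'   `intergenic_bp`.
#' @export
coverage_profile <- function(region, bundle) {
  r <- .region_fields(region)
  len <- r$end - r$start + 1L
  g <- bundle$gene_tab
  ov <- g$chrom == r$chrom & g$biotype == "protein_coding" &
    g$start <= r$end & g$end >= r$start
  genic_bp <- .union_clip_bp(g$start[ov], g$end[ov], r$start, r$end)
  ex <- bundle$exon_tab
  exv <- ex$gene_id %in% g$gene_id[ov] & ex$start <= r$end & ex$end >= r$start
  exon_bp <- .union_clip_bp(ex$start[exv], ex$end[exv], r$start, r$end)
  intron_bp <- genic_bp - exon_bp
  intergenic_bp <- len - genic_bp
  label <- if (exon_bp == len) "exonic" else if (intron_bp == len) "intronic"
           else "mixed"
  list(exon_cov = exon_bp / len, intron_cov = intron_bp / len,
       intergenic_cov = intergenic_bp / len, structural_label = label,
       exon_bp = exon_bp, intron_bp = intron_bp, intergenic_bp = intergenic_bp)
}

#' Transposable-element coverage of a region
#'
#' TE bp is the overlap of the region with the union of TE-class repeat
#' features (all RepeatMasker classes except simple repeats, low-complexity
#' and satellite).  A region counts as TE-derived only when covered by
#' strictly more than `min_te_bp` base pairs of TE.
#'
#' @inheritParams classify_ortholog
#' @param min_te_bp TE-derived threshold: `te_bp > min_te_bp` (default 10,
#'   i.e. 10 bp of TE is not enough, 11 is).
#' @param non_te_classes Repeat classes excluded from the TE set (matched
#'   on the class part before any "/" family suffix).
#' @return List with `te_cov`, `te_bp` and logical `te_derived`.
#' @export
te_coverage <- function(region, bundle, min_te_bp = 10L,
                        non_te_classes = .NON_TE_CLASSES) {
  r <- .region_fields(region)
  len <- r$end - r$start + 1L
  rt <- bundle$repeat_tab
  te <- rt$chrom == r$chrom &
    !(sub("/.*$", "", rt$repeat_class) %in% non_te_classes) &
    rt$start <= r$end & rt$end >= r$start
  te_bp <- .union_clip_bp(rt$start[te], rt$end[te], r$start, r$end)
  list(te_cov = te_bp / len, te_bp = te_bp, te_derived = te_bp > min_te_bp)
}
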