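# Domain containers and readers/writers for the standard formats the
# pipeline touches.  Internally everything lives in GRanges (1-based,
# closed intervals, the Bioconductor convention); 0-based half-open inputs
# (BED) are converted at parse time by rtracklayer, and the ortholog table
# is written back out 0-based half-open.

.BIOTYPES <- c("protein_coding", "lincRNA", "other_noncoding", "pseudogene")

.normalize_biotype <- function(x) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  out[x == "protein_coding"] <- "protein_coding"
  out[x %in% c("lincRNA", "lncRNA", "long_noncoding")] <- "lincRNA"
  out[grepl("pseudogene", x)] <- "pseudogene"
  short_nc <- c("miRNA", "snoRNA", "snRNA", "rRNA", "tRNA", "misc_RNA",
                "antisense", "ncRNA", "other_noncoding")
  out[x %in% short_nc] <- "other_noncoding"
  bad <- is.na(out)
  if (any(bad)) {
    warning("unparseable gene biotype(s) mapped to other_noncoding: ",
            paste(unique(x[bad]), collapse = ", "))
    out[bad] <- "other_noncoding"
  }
  out
}

#' Assemble a genome bundle for one species
#'
#' A genome bundle holds one species' chromosome sequences, its gene models
#' (spans plus exon unions, with biotype), and its repeat annotation, all
#' indexed as `GRanges` so overlap queries are cheap.
#'
#' @param species Species label.
#' @param seqs `DNAStringSet` of chromosome sequences.
#' @param genes `GRanges` of gene spans with metadata columns `gene_id`,
#'   `biotype` (one of `protein_coding`, `lincRNA`, `other_noncoding`,
#'   `pseudogene`) and optionally `pseudogene_subtype`.
#' @param exons `GRanges` of exons with metadata column `gene_id`.
#'   Isoforms are collapsed: exons are unioned per gene and the gene span is
#'   recomputed as the range of its exon union.
#' @param repeats `GRanges` of repeat features with metadata columns
#'   `repeat_name` and `repeat_class` (RepeatMasker-style, e.g. `LINE/L1`).
#' @return An object of class `genome_bundle`.
#' @export
genome_bundle <- function(species, seqs, genes, exons,
                          repeats = GenomicRanges::GRanges()) {
  stopifnot(is.character(species), length(species) == 1L,
            is(seqs, "DNAStringSet"),
            is(genes, "GRanges"), is(exons, "GRanges"),
            is(repeats, "GRanges"),
            !is.null(mcols(genes)$gene_id), !is.null(mcols(genes)$biotype),
            !is.null(mcols(exons)$gene_id))
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  check_chroms <- function(gr, what) {
    chr <- as.character(GenomicRanges::seqnames(gr))
    unknown <- !(chr %in% names(lens))
    if (any(unknown)) {
      stop(what, " annotation references unknown sequence(s): ",
           paste(unique(chr[unknown]), collapse = ", "))
    }
    over <- GenomicRanges::end(gr) > lens[chr] | GenomicRanges::start(gr) < 1L
    if (any(over)) {
      stop(what, " annotation outside sequence bounds: record ",
           which(over)[1L], " (", chr[which(over)[1L]], ")")
    }
  }
  check_chroms(genes, "gene")
  check_chroms(exons, "exon")
  if (length(repeats)) check_chroms(repeats, "repeat")
  if (anyNA(match(mcols(genes)$biotype, .BIOTYPES)))
    stop("gene biotype must be one of: ", paste(.BIOTYPES, collapse = ", "))
  if (anyNA(match(mcols(exons)$gene_id, mcols(genes)$gene_id)))
    stop("exon references unknown gene_id")
  if (anyDuplicated(mcols(genes)$gene_id))
    stop("duplicated gene_id in gene annotation")

  # collapse isoforms: exon union per gene, span = range of the union
  ex_by_gene <- GenomicRanges::reduce(
    GenomicRanges::split(exons, mcols(exons)$gene_id), ignore.strand = TRUE)
  ex_flat <- unlist(ex_by_gene, use.names = TRUE)
  exons2 <- GenomicRanges::granges(ex_flat, use.names = FALSE)
  mcols(exons2)$gene_id <- names(ex_flat)
  span_by_gene <- unlist(range(ex_by_gene, ignore.strand = TRUE))
  idx <- match(mcols(genes)$gene_id, names(span_by_gene))
  if (anyNA(idx)) stop("gene(s) without exons: ",
                       paste(mcols(genes)$gene_id[is.na(idx)], collapse = ", "))
  genes2 <- span_by_gene[idx]
  mcols(genes2) <- mcols(genes)
  names(genes2) <- NULL

  si <- GenomeInfoDb::Seqinfo(names(lens), seqlengths = unname(lens))
  GenomeInfoDb::seqlevels(genes2) <- names(lens)
  GenomeInfoDb::seqinfo(genes2) <- si
  GenomeInfoDb::seqlevels(exons2) <- names(lens)
  GenomeInfoDb::seqinfo(exons2) <- si
  if (length(repeats)) {
    GenomeInfoDb::seqlevels(repeats) <- names(lens)
    GenomeInfoDb::seqinfo(repeats) <- si
  }
  # plain-table mirrors of the annotation for fast bp arithmetic
  gtab <- data.frame(chrom = as.character(GenomicRanges::seqnames(genes2)),
                     start = GenomicRanges::start(genes2),
                     end = GenomicRanges::end(genes2),
                     gene_id = mcols(genes2)$gene_id,
                     biotype = mcols(genes2)$biotype,
                     stringsAsFactors = FALSE)
  etab <- data.frame(chrom = as.character(GenomicRanges::seqnames(exons2)),
                     start = GenomicRanges::start(exons2),
                     end = GenomicRanges::end(exons2),
                     gene_id = mcols(exons2)$gene_id,
                     stringsAsFactors = FALSE)
  rtab <- if (length(repeats)) data.frame(
    chrom = as.character(GenomicRanges::seqnames(repeats)),
    start = GenomicRanges::start(repeats),
    end = GenomicRanges::end(repeats),
    repeat_class = mcols(repeats)$repeat_class,
    stringsAsFactors = FALSE)
  else data.frame(chrom = character(0), start = integer(0),
                  end = integer(0), repeat_class = character(0))
  structure(list(species = species, seqs = seqs, genes = genes2,
                 exons = exons2, repeats = repeats,
                 gene_tab = gtab, exon_tab = etab, repeat_tab = rtab),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("genome_bundle:", x$species, "|", length(x$seqs), "sequence(s),",
      length(x$genes), "genes,", length(x$repeats), "repeats\n")
  invisible(x)
}

.import_gene_gff <- function(gff_path) {
  gr <- rtracklayer::import(gff_path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  exons <- gr[gr$type == "exon"]
  if (!length(genes)) stop("no gene records in ", gff_path)
  gene_id <- genes$ID
  if (is.null(gene_id) || anyNA(gene_id)) stop("gene records lack ID in ", gff_path)
  biotype <- genes$biotype
  if (is.null(biotype)) stop("gene records lack biotype attribute in ", gff_path)
  g <- GenomicRanges::granges(genes)
  mcols(g)$gene_id <- as.character(gene_id)
  mcols(g)$biotype <- .normalize_biotype(biotype)
  subtype <- genes$pseudogene_subtype
  mcols(g)$pseudogene_subtype <-
    if (is.null(subtype)) NA_character_ else as.character(subtype)
  parent <- exons$Parent
  pid <- if (is.null(parent)) as.character(exons$gene_id)
         else vapply(parent, function(p) p[1L], character(1))
  e <- GenomicRanges::granges(exons)
  mcols(e)$gene_id <- pid
  list(genes = g, exons = e)
}

#' Read a RepeatMasker .out annotation file
#'
#' Parses the standard RepeatMasker `.out` body (1-based inclusive
#' coordinates) into repeat features.  Column 5 is the target sequence,
#' columns 6-7 the span, column 10 the repeat name and column 11 the repeat
#' class/family.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return `GRanges` with metadata columns `repeat_name` and `repeat_class`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^\\s*$", lines) &
                  !grepl("^\\s*(SW|score|\\s*perc)", lines))
  # header rows start with "SW" / "score"; everything else must parse
  chrom <- character(0); st <- integer(0); en <- integer(0)
  strand <- character(0); rname <- character(0); rclass <- character(0)
  for (i in body) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 11L)
      stop("malformed RepeatMasker line ", i, " in ", path)
    s <- suppressWarnings(as.integer(f[6])); e <- suppressWarnings(as.integer(f[7]))
    if (is.na(s) || is.na(e))
      stop("malformed RepeatMasker line ", i, " in ", path)
    chrom <- c(chrom, f[5]); st <- c(st, s); en <- c(en, e)
    strand <- c(strand, if (f[9] == "C") "-" else "+")
    rname <- c(rname, f[10]); rclass <- c(rclass, f[11])
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st, en), strand = strand)
  mcols(gr)$repeat_name <- rname
  mcols(gr)$repeat_class <- rclass
  gr
}

.import_repeats <- function(path) {
  if (is.null(path)) return(GenomicRanges::GRanges())
  ext <- tolower(tools::file_ext(path))
  if (ext == "out") return(read_repeatmasker_out(path))
  # BED6 with name "repeat_name#class/family" (RepeatMasker convention)
  gr <- rtracklayer::import(path, format = "bed")
  nm <- gr$name %||% rep("repeat", length(gr))
  parts <- strsplit(nm, "#", fixed = TRUE)
  out <- GenomicRanges::granges(gr)
  mcols(out)$repeat_name <- vapply(parts, `[`, character(1), 1L)
  mcols(out)$repeat_class <- vapply(
    parts, function(p) if (length(p) > 1L) p[2L] else p[1L], character(1))
  out
}

#' Read one species' genome, gene annotation and repeat annotation
#'
#' @param fasta_path Genome FASTA.
#' @param gff_path GFF3 gene annotation; `gene` records need `ID` and
#'   `biotype` attributes, `exon` records a `Parent` (or `gene_id`)
#'   attribute.  Unrecognised biotypes are mapped to `other_noncoding` with
#'   a warning.
#' @param repeats_path RepeatMasker `.out` file or BED6 file whose name field
#'   is `repeat_name#class/family`; `NULL` for no repeat annotation.
#' @param species Species label (defaults to the FASTA basename).
#' @return A [genome_bundle()].
#' @export
read_genome_bundle <- function(fasta_path, gff_path, repeats_path = NULL,
                               species = NULL) {
  for (p in c(fasta_path, gff_path, repeats_path))
    if (!file.exists(p)) stop("file not found: ", p)
  species <- species %||% sub("\\..*$", "", basename(fasta_path))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- .import_gene_gff(gff_path)
  genome_bundle(species, seqs, ann$genes, ann$exons, .import_repeats(repeats_path))
}

#' Read a lincRNA set (spans plus spliced cDNA)
#'
#' @param gff_path GFF3 (gene records with `ID`) or BED file of lincRNA
#'   spans in human coordinates.
#' @param cdna_fasta FASTA of spliced cDNA sequences named by lincRNA id.
#' @param min_len Minimum cDNA length; lincRNAs are by definition longer
#'   than 200 nt, so shorter records are rejected.
#' @return An object of class `linc_set`: `spans` (`GRanges` with
#'   `linc_id`) and `cdna` (`DNAStringSet`).
#' @export
read_lincrnas <- function(gff_path, cdna_fasta, min_len = 200L) {
  ext <- tolower(tools::file_ext(gff_path))
  if (ext %in% c("bed", "bed12")) {
    gr <- rtracklayer::import(gff_path, format = "bed")
    ids <- gr$name
  } else {
    gr <- rtracklayer::import(gff_path, format = "gff3")
    gr <- gr[gr$type %in% c("gene", "lincRNA", "lnc_RNA", "transcript")]
    ids <- gr$ID
  }
  if (is.null(ids) || anyNA(ids)) stop("lincRNA records lack identifiers")
  spans <- GenomicRanges::granges(gr)
  mcols(spans)$linc_id <- as.character(ids)
  cdna <- Biostrings::readDNAStringSet(cdna_fasta)
  names(cdna) <- sub("\\s.*$", "", names(cdna))
  missing <- setdiff(mcols(spans)$linc_id, names(cdna))
  if (length(missing)) stop("cDNA missing for: ", paste(missing, collapse = ", "))
  cdna <- cdna[mcols(spans)$linc_id]
  if (any(Biostrings::width(cdna) < min_len))
    stop("lincRNA cDNA shorter than ", min_len, " nt: ",
         paste(names(cdna)[Biostrings::width(cdna) < min_len], collapse = ", "))
  bad <- grepl("[^ACGTNacgtn]", as.character(cdna))
  if (any(bad)) stop("lincRNA cDNA with letters outside {A,C,G,T,N}: ",
                     paste(names(cdna)[bad], collapse = ", "))
  structure(list(spans = spans, cdna = cdna), class = "linc_set")
}

#' @export
print.linc_set <- function(x, ...) {
  cat("linc_set:", length(x$spans), "lincRNAs\n"); invisible(x)
}

#' Remove lincRNAs overlapping protein-coding genes
#'
#' Drops every lincRNA whose span shares at least 1 bp (strand-blind) with
#' any protein-coding gene span of the human annotation.  This is the
#' pre-filter applied before any homology search, so that alignments cannot
#' be driven by overlapping coding sequence on either strand.
#'
#' @param lincs A `linc_set`.
#' @param human The human [genome_bundle()].
#' @return The filtered `linc_set` (a subset of the input; idempotent).
#' @export
filter_lincrnas <- function(lincs, human) {
  stopifnot(inherits(lincs, "linc_set"), inherits(human, "genome_bundle"))
  if (!length(lincs$spans)) return(lincs)
  coding <- human$genes[mcols(human$genes)$biotype == "protein_coding"]
  hit <- IRanges::overlapsAny(lincs$spans, coding, ignore.strand = TRUE)
  structure(list(spans = lincs$spans[!hit],
                 cdna = lincs$cdna[mcols(lincs$spans)$linc_id[!hit]]),
            class = "linc_set")
}

#' Read a cross-species gene orthology table
#'
#' Tab-separated columns `species_a`, `gene_a`, `species_b`, `gene_b`.
#' The symmetric closure is taken and duplicate edges removed; a gene is
#' never orthologous to itself within one species.
#'
#' @param path TSV path.
#' @return An object of class `orthology_map`.
#' @export
read_orthology_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  orthology_map(df)
}

#' @rdname read_orthology_map
#' @param edges data.frame with columns `species_a`, `gene_a`, `species_b`,
#'   `gene_b`.
#' @export
orthology_map <- function(edges) {
  need <- c("species_a", "gene_a", "species_b", "gene_b")
  stopifnot(all(need %in% names(edges)))
  edges <- edges[need]
  self <- edges$species_a == edges$species_b & edges$gene_a == edges$gene_b
  if (any(self)) stop("orthology self-edge for gene ", edges$gene_a[which(self)[1L]])
  rev_edges <- data.frame(species_a = edges$species_b, gene_a = edges$gene_b,
                          species_b = edges$species_a, gene_b = edges$gene_a,
                          stringsAsFactors = FALSE)
  all_e <- unique(rbind(edges, rev_edges))
  structure(list(edges = all_e,
                 key = paste(all_e$species_a, all_e$gene_a, sep = "\r")),
            class = "orthology_map")
}

#' @export
print.orthology_map <- function(x, ...) {
  cat("orthology_map:", nrow(x$edges) / 2, "undirected edges\n"); invisible(x)
}

#' Orthologs of a gene in another species
#'
#' @param orth An `orthology_map`.
#' @param species,gene Source species and gene id.
#' @param target_species Restrict partners to this species (optional).
#' @return Character vector of partner gene ids (sorted, unique).
#' @export
ortholog_partners <- function(orth, species, gene, target_species = NULL) {
  stopifnot(inherits(orth, "orthology_map"))
  sel <- orth$key == paste(species, gene, sep = "\r")
  e <- orth$edges[sel, , drop = FALSE]
  if (!is.null(target_species)) e <- e[e$species_b %in% target_species, , drop = FALSE]
  sort(unique(e$gene_b))
}

#' Test whether two genes are orthologous
#'
#' @inheritParams ortholog_partners
#' @param species_b,gene_b The other gene.
#' @return Logical scalar.
#' @export
are_orthologs <- function(orth, species, gene, species_b, gene_b) {
  gene_b %in% ortholog_partners(orth, species, gene, species_b)
}

#' Read a ceRNA-mRNA pair table
#'
#' Tab-separated columns `lnc_id` and `gene_id` (lnCeDB-style).  Duplicates
#' are removed; empty ids rejected.
#'
#' @param path TSV path.
#' @return data.frame with columns `lnc_id`, `gene_id` (set semantics).
#' @export
read_cerna_pairs <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("lnc_id", "gene_id") %in% names(df)))
  df <- unique(df[c("lnc_id", "gene_id")])
  if (any(!nzchar(df$lnc_id)) || any(!nzchar(df$gene_id)))
    stop("empty identifier in ceRNA pair table")
  rownames(df) <- NULL
  df
}

#' Write the putative-ortholog table
#'
#' One row per selected putative ortholog with the columns
#' `linc_id, species, chrom, start, end, evalue, class, exon_cov,
#' intron_cov, intergenic_cov, te_cov, structural_label`.  Coordinates are
#' written 0-based half-open; rows are ordered by (linc_id, species) so
#' reruns are byte-identical.
#'
#' @param results data.frame of classified putative orthologs (as produced
#'   by [run_pipeline()]).
#' @param path Output TSV path.
#' @export
write_ortholog_table <- function(results, path) {
  cols <- c("linc_id", "species", "chrom", "start", "end", "evalue", "class",
            "exon_cov", "intron_cov", "intergenic_cov", "te_cov",
            "structural_label")
  if (nrow(results) == 0L) {
    out <- as.data.frame(setNames(replicate(length(cols), character(0),
                                            simplify = FALSE), cols))
  } else {
    stopifnot(all(cols %in% names(results)))
    out <- results[order(results$linc_id, results$species), cols]
    out$start <- out$start - 1L  # 1-based closed -> 0-based half-open
    for (nc in c("evalue", "exon_cov", "intron_cov", "intergenic_cov", "te_cov"))
      out[[nc]] <- trimws(formatC(out[[nc]], format = "g", digits = 8))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
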