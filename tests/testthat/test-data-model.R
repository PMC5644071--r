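test_that("GFF3 coordinates round-trip unchanged through the bundle", {
  dir <- withr::local_tempdir()
  set.seed(11)
  seq <- random_seq(5000)
  fa <- file.path(dir, "g.fa")
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(seq), "chr1"), fa)
  gff <- file.path(dir, "g.gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsim\tgene\t101\t900\t.\t+\t.\tID=g1;biotype=protein_coding",
               "chr1\tsim\texon\t101\t300\t.\t+\t.\tParent=g1",
               "chr1\tsim\texon\t601\t900\t.\t+\t.\tParent=g1"), gff)
  b <- read_genome_bundle(fa, gff, species = "t")
  expect_equal(GenomicRanges::start(b$genes), 101L)
  expect_equal(GenomicRanges::end(b$genes), 900L)
  expect_equal(GenomicRanges::start(b$exons), c(101L, 601L))
  expect_equal(GenomicRanges::end(b$exons), c(300L, 900L))
})

test_that("annotations referencing unknown or out-of-range sequence fail loudly", {
  g <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 10))
  S4Vectors::mcols(g)$gene_id <- "g1"
  S4Vectors::mcols(g)$biotype <- "protein_coding"
  e <- g; S4Vectors::mcols(e) <- NULL; S4Vectors::mcols(e)$gene_id <- "g1"
  seqs <- setNames(Biostrings::DNAStringSet("ACGTACGTAC"), "chr1")
  expect_error(genome_bundle("t", seqs, g, e), "unknown sequence")
  g2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 50))
  S4Vectors::mcols(g2)$gene_id <- "g1"
  S4Vectors::mcols(g2)$biotype <- "protein_coding"
  e2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 50))
  S4Vectors::mcols(e2)$gene_id <- "g1"
  expect_error(genome_bundle("t", seqs, g2, e2), "outside sequence bounds")
})

test_that("RepeatMasker .out rows map to repeat features, BED6 names carry class", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "rm.out")
  writeLines(c(
    "   SW  perc perc perc  query     position in query    matching repeat",
    "score  div. del. ins.  sequence  begin  end  (left)   repeat  class/family  begin end (left) ID",
    "",
    "  463 12.4  0.0  0.0  chr1  1001  1350  (3650)  +  L1MC4  LINE/L1  1  350  (0)  1",
    "  120  8.0  0.0  0.0  chr1  2001  2100  (2900)  C  AluSx  SINE/Alu  1  100  (0)  2"),
    out)
  r <- read_repeatmasker_out(out)
  expect_equal(length(r), 2L)
  expect_equal(GenomicRanges::start(r), c(1001L, 2001L))
  expect_equal(S4Vectors::mcols(r)$repeat_class, c("LINE/L1", "SINE/Alu"))
  expect_equal(as.character(GenomicRanges::strand(r)), c("+", "-"))
  writeLines("garbage line without columns", file.path(dir, "bad.out"))
  expect_error(read_repeatmasker_out(file.path(dir, "bad.out")), "line 1")
  bed <- file.path(dir, "r.bed")
  writeLines("chr1\t1000\t1350\tL1MC4#LINE/L1\t0\t+", bed)
  rb <- lincorigins:::.import_repeats(bed)
  expect_equal(GenomicRanges::start(rb), 1001L)  # BED is 0-based half-open
  expect_equal(S4Vectors::mcols(rb)$repeat_class, "LINE/L1")
})

test_that("unknown biotypes map to other_noncoding with a warning", {
  expect_warning(bt <- lincorigins:::.normalize_biotype(
    c("protein_coding", "weird_type", "processed_pseudogene", "miRNA")),
    "other_noncoding")
  expect_equal(bt, c("protein_coding", "other_noncoding", "pseudogene",
                     "other_noncoding"))
})

test_that("coding-overlap filter is strand-blind, 1-bp sensitive and idempotent", {
  set.seed(5)
  human <- make_bundle(genes = data.frame(
    gene_id = c("pc1", "pc2", "nc1"),
    biotype = c("protein_coding", "protein_coding", "lincRNA"),
    exon_starts = c("1000", "5000", "3000"),
    exon_ends = c("2000", "6000", "3500")))
  lincs <- make_linc_set(
    ids = c("between", "touch1bp", "inside_nc"),
    starts = c(2500L, 2000L, 3100L), ends = c(2950L, 2400L, 3450L),
    seqs = replicate(3, random_seq(300)))
  # opposite strand on the 1-bp overlap must still count
  GenomicRanges::strand(lincs$spans)[2] <- "-"
  f <- filter_lincrnas(lincs, human)
  expect_equal(S4Vectors::mcols(f$spans)$linc_id, c("between", "inside_nc"))
  expect_equal(S4Vectors::mcols(filter_lincrnas(f, human)$spans)$linc_id,
               S4Vectors::mcols(f$spans)$linc_id)
  empty <- make_linc_set(character(0), integer(0), integer(0), character(0))
  expect_equal(length(filter_lincrnas(empty, human)$spans), 0L)
})

test_that("interval queries agree with brute-force overlap scans", {
  set.seed(99)
  for (rep in 1:20) {
    n <- 30L
    df <- data.frame(chrom = "chr1",
                     start = sample.int(5000L, n),
                     gene_id = paste0("g", seq_len(n)))
    df$end <- df$start + sample.int(400L, n)
    b <- make_bundle(seq_len = 10000L, genes = data.frame(
      gene_id = df$gene_id, biotype = "protein_coding",
      exon_starts = as.character(df$start), exon_ends = as.character(df$end)))
    q_start <- sample.int(5000L, 1); q_end <- q_start + sample.int(500L, 1)
    region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(q_start, q_end))
    got <- sort(S4Vectors::mcols(b$genes)$gene_id[
      IRanges::overlapsAny(b$genes, region, ignore.strand = TRUE)])
    want <- sort(df$gene_id[brute_overlaps("chr1", q_start, q_end, df)])
    expect_equal(got, want)
  }
})

test_that("orthology map closes symmetrically and rejects self-edges", {
  m <- orthology_map(data.frame(species_a = "human", gene_a = "G1",
                                species_b = "sp1", gene_b = "g1"))
  expect_equal(ortholog_partners(m, "sp1", "g1", "human"), "G1")
  expect_true(are_orthologs(m, "human", "G1", "sp1", "g1"))
  expect_false(are_orthologs(m, "human", "G1", "sp1", "g2"))
  expect_error(orthology_map(data.frame(
    species_a = "human", gene_a = "G1", species_b = "human", gene_b = "G1")),
    "self-edge")
})

test_that("ortholog table writing is deterministic and 0-based half-open", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "a.tsv"); p2 <- file.path(dir, "b.tsv")
  empty <- data.frame()
  write_ortholog_table(empty, p1)
  expect_equal(readLines(p1), paste(
    c("linc_id", "species", "chrom", "start", "end", "evalue", "class",
      "exon_cov", "intron_cov", "intergenic_cov", "te_cov",
      "structural_label"), collapse = "\t"))
  row <- data.frame(linc_id = "L1", species = "sp1", chrom = "chr1",
                    start = 101L, end = 200L, evalue = 1e-30,
                    class = "intergenic", exon_cov = 0, intron_cov = 0,
                    intergenic_cov = 1, te_cov = 0,
                    structural_label = "mixed")
  write_ortholog_table(row, p1)
  write_ortholog_table(row, p2)
  expect_identical(readLines(p1), readLines(p2))
  f <- strsplit(readLines(p1)[2], "\t")[[1]]
  expect_equal(as.integer(f[4]), 100L)  # 0-based start
  expect_equal(as.integer(f[5]), 200L)
  expect_equal(length(f), 12L)
})
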