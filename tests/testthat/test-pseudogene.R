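test_that("aligned proteins are all coding genes overlapping the region", {
  b1 <- make_bundle(species = "mouse", genes = data.frame(
    gene_id = c("Tssk2", "Other", "nc"),
    biotype = c("protein_coding", "protein_coding", "lincRNA"),
    exon_starts = c("1000", "1900", "5000"),
    exon_ends = c("2000", "2800", "5400")))
  orth_df <- data.frame(species = "mouse", chrom = "chr1",
                        start = 1500L, end = 2200L,
                        class = "protein_coding", stringsAsFactors = FALSE)
  got <- aligned_proteins(orth_df, list(mouse = b1))
  expect_equal(got$gene_id, c("Other", "Tssk2"))   # both overlapped coding genes
  # intergenic orthologs contribute nothing
  orth_df$class <- "intergenic"
  expect_equal(nrow(aligned_proteins(orth_df, list(mouse = b1))), 0L)
})

test_that("orthology check accepts any connected cross-species pair", {
  orth <- orthology_map(data.frame(
    species_a = c("cow", "dog"), gene_a = c("a", "b"),
    species_b = c("dog", "mouse"), gene_b = c("b", "c")))
  p_ok <- data.frame(species = c("cow", "dog"), gene_id = c("a", "b"))
  expect_true(aligned_protein_orthology_check(p_ok, orth))
  # transitive chain a-b, b-c: connected through any listed pair
  p_chain <- data.frame(species = c("cow", "mouse"), gene_id = c("a", "c"))
  expect_false(aligned_protein_orthology_check(p_chain, orth)) # a-c not an edge
  p_all <- data.frame(species = c("cow", "dog", "mouse"),
                      gene_id = c("a", "b", "c"))
  expect_true(aligned_protein_orthology_check(p_all, orth))
  # unrelated genes, or a single species: FALSE
  p_bad <- data.frame(species = c("cow", "mouse"), gene_id = c("a", "zzz"))
  expect_false(aligned_protein_orthology_check(p_bad, orth))
  expect_false(aligned_protein_orthology_check(
    data.frame(species = "cow", gene_id = "a"), orth))
})

test_that("putative paralogs require both an orthology edge and a significant alignment", {
  set.seed(61)
  linc <- random_seq(500)
  # human gene HP carries a diverged copy of the linc in its exon;
  # human gene HX is unrelated sequence
  hp_exon <- paste0(random_seq(100), mutate_sequence(linc, 0.05),
                    random_seq(100))
  hx_exon <- random_seq(700)
  genome <- paste0(random_seq(1000), hp_exon, random_seq(1000), hx_exon,
                   random_seq(1000))
  human <- make_bundle(seq = genome, species = "human", genes = data.frame(
    gene_id = c("HP", "HX"), biotype = "protein_coding",
    exon_starts = as.character(c(1001, 1001 + nchar(hp_exon) + 1000)),
    exon_ends = as.character(c(1000 + nchar(hp_exon),
                               1000 + nchar(hp_exon) + 1000 + nchar(hx_exon)))))
  proteins <- data.frame(species = c("sp1", "sp2"), gene_id = c("g1", "g2"))
  orth <- orthology_map(data.frame(
    species_a = c("sp1", "sp2"), gene_a = c("g1", "g2"),
    species_b = c("human", "human"), gene_b = c("HP", "HX")))
  expect_equal(putative_paralogs(linc, proteins, orth, human), "HP")
  # no orthology edge into human: nothing to test, empty result
  orth2 <- orthology_map(data.frame(
    species_a = "sp1", gene_a = "g1", species_b = "sp2", gene_b = "g2"))
  expect_equal(putative_paralogs(linc, proteins, orth2, human), character(0))
})

test_that("pseudogene relation distinguishes overlap, juxtaposition and none", {
  human <- make_bundle(seq_len = 100000L, genes = data.frame(
    gene_id = c("PSG1", "pc1"),
    biotype = c("pseudogene", "protein_coding"),
    exon_starts = c("20000", "50000"),
    exon_ends = c("21000", "51000")))
  linc <- function(s, e) {
    g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e))
    S4Vectors::mcols(g)$linc_id <- "L"
    g
  }
  r <- pseudogene_relation(linc(20500, 21500), human)
  expect_equal(r$relation, "overlap")
  expect_equal(r$distance, 0L)
  expect_equal(r$nearest_pseudogene, "PSG1")
  # boundary-inclusive juxtaposition: gap of exactly juxtaposition_bp
  r2 <- pseudogene_relation(linc(22001, 22500), human, juxtaposition_bp = 1000L)
  expect_equal(r2$relation, "juxtaposed")
  r3 <- pseudogene_relation(linc(22002, 22500), human, juxtaposition_bp = 1000L)
  expect_equal(r3$relation, "none")
  # no pseudogene anywhere
  human2 <- make_bundle(seq_len = 100000L, genes = data.frame(
    gene_id = "pc1", biotype = "protein_coding",
    exon_starts = "50000", exon_ends = "51000"))
  expect_equal(pseudogene_relation(linc(20500, 21500), human2)$relation,
               "none")
})

test_that("origin hypotheses are exclusive, exhaustive and gated by eligibility", {
  expect_equal(origin_hypothesis(character(0), "overlap"), "unitary_candidate")
  expect_equal(origin_hypothesis(character(0), "juxtaposed"),
               "unitary_candidate")
  expect_equal(origin_hypothesis("HP", "none"), "duplicated_candidate")
  expect_equal(origin_hypothesis("HP", "overlap"), "duplicated_candidate")
  expect_equal(origin_hypothesis(character(0), "none"), "unclassified")
  expect_warning(h <- origin_hypothesis("HP", "overlap", eligible = FALSE),
                 "ineligible")
  expect_equal(h, "unclassified")
})
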