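# layout helper: one human chromosome with coding genes at given starts
# (1 kb single-exon genes) and one lincRNA between them
synteny_human <- function(gene_starts, linc_start, linc_end,
                          seq_len = 3000000L) {
  make_bundle(seq_len = seq_len, genes = data.frame(
    gene_id = paste0("G", seq_along(gene_starts)),
    biotype = "protein_coding",
    exon_starts = as.character(gene_starts),
    exon_ends = as.character(gene_starts + 999L)))
}

test_that("neighbour context uses midpoint distance with a hard boundary", {
  set.seed(8)
  human <- synteny_human(c(1000L, 30000L, 100000L, 810000L), 0, 0)
  linc <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50000, 50600))
  S4Vectors::mcols(linc)$linc_id <- "L1"
  ctx <- neighbor_context(linc, human, window_bp = 750000L)
  expect_equal(ctx$upstream, c("G2", "G1"))      # nearest first
  # G4 midpoint 810499 is 759899 bp downstream of the linc end -> excluded
  expect_equal(ctx$downstream, "G3")
  ctx2 <- neighbor_context(linc, human, window_bp = 760000L)
  expect_equal(ctx2$downstream, c("G3", "G4"))
})

test_that("neighbour context equals a brute-force distance scan", {
  set.seed(13)
  for (rep in 1:10) {
    starts <- sort(sample.int(2000000L, 15L))
    human <- synteny_human(starts, 0, 0)
    ls <- sample.int(2000000L, 1); le <- ls + 500L
    linc <- GenomicRanges::GRanges("chr1", IRanges::IRanges(ls, le))
    S4Vectors::mcols(linc)$linc_id <- "L"
    w <- 300000L
    ctx <- neighbor_context(linc, human, w)
    mids <- floor((starts + starts + 999) / 2)
    ids <- paste0("G", seq_along(starts))
    up <- ids[mids < ls & ls - mids <= w][order((ls - mids)[mids < ls & ls - mids <= w])]
    dn <- ids[mids > le & mids - le <= w][order((mids - le)[mids > le & mids - le <= w])]
    expect_equal(ctx$upstream, up)
    expect_equal(ctx$downstream, dn)
  }
})

# builds a target species bundle and an orthology map where target gene
# "t<i>" at the given start is the ortholog of human gene hs[i]
synteny_target <- function(t_starts, hs, seq_len = 3000000L) {
  b <- make_bundle(seq_len = seq_len, species = "sp1", genes = data.frame(
    gene_id = paste0("t", seq_along(t_starts)),
    biotype = "protein_coding",
    exon_starts = as.character(t_starts),
    exon_ends = as.character(t_starts + 999L)))
  m <- orthology_map(data.frame(
    species_a = "human", gene_a = hs,
    species_b = "sp1", gene_b = paste0("t", seq_along(t_starts))))
  list(bundle = b, orth = m)
}

fake_ctx <- function(up, down, window_bp = 100000L) {
  structure(list(linc_id = "L", upstream = up, downstream = down,
                 window_bp = as.integer(window_bp)),
            class = "neighbor_context")
}

test_that("syntenic windows require same-chromosome anchors within range", {
  set.seed(17)
  tg <- synteny_target(c(50000L, 120000L), c("G1", "G2"))
  ctx <- fake_ctx("G1", "G2", 100000L)
  w <- syntenic_windows(ctx, tg$bundle, tg$orth)
  expect_equal(length(w), 1L)
  expect_equal(GenomicRanges::start(w), 1L)          # clipped at chrom start
  expect_equal(GenomicRanges::end(w), 220999L)
  expect_equal(S4Vectors::mcols(w)$anchor_u, "G1")
  # orthologs too far apart (> 2 * window) produce no window
  tg2 <- synteny_target(c(50000L, 2500000L), c("G1", "G2"))
  expect_equal(length(syntenic_windows(ctx, tg2$bundle, tg2$orth)), 0L)
  # orthologs on different chromosomes: no window (simulate by dropping the
  # downstream ortholog from the map)
  tg3 <- synteny_target(50000L, "G1")
  expect_equal(length(syntenic_windows(ctx, tg3$bundle, tg3$orth)), 0L)
})

test_that("multi-anchor window set equals exhaustive pair enumeration", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 6L
    t_starts <- sort(sample.int(1500000L, n))
    hs <- paste0("G", seq_len(n))
    tg <- synteny_target(t_starts, hs)
    up <- sample(hs, 2); down <- sample(setdiff(hs, up), 2)
    w_bp <- 200000L
    ctx <- fake_ctx(up, down, w_bp)
    got <- syntenic_windows(ctx, tg$bundle, tg$orth)
    # oracle: enumerate all pairs directly
    want <- list()
    for (u in up) for (d in down) {
      iu <- match(u, hs); id <- match(d, hs)
      su <- t_starts[iu]; eu <- su + 999L
      sd <- t_starts[id]; ed <- sd + 999L
      gap <- max(0L, max(su, sd) - min(eu, ed))
      if (gap > 2 * w_bp) next
      want[[length(want) + 1L]] <- c(max(1L, min(su, sd) - w_bp),
                                     min(3000000L, max(eu, ed) + w_bp))
    }
    expect_equal(length(got), length(want))
    if (length(want)) {
      wm <- do.call(rbind, want)
      expect_setequal(paste(GenomicRanges::start(got), GenomicRanges::end(got)),
                      paste(wm[, 1], wm[, 2]))
    }
  }
})

test_that("candidates demand a flanking anchor pair within the window", {
  set.seed(29)
  linc_seq <- random_seq(500)
  # target chromosome: t1 ... plant ... t2, plus a decoy plant beyond both
  left <- 40000L; right <- 90000L; decoy <- 140000L
  genome <- random_seq(200000L)
  insert <- function(g, s, frag) paste0(substr(g, 1, s - 1), frag,
                                        substr(g, s + nchar(frag), nchar(g)))
  genome <- insert(genome, 60000L, mutate_sequence(linc_seq, 0.05))
  genome <- insert(genome, decoy, mutate_sequence(linc_seq, 0.05))
  b <- make_bundle(seq = genome, species = "sp1", genes = data.frame(
    gene_id = c("t1", "t2"), biotype = "protein_coding",
    exon_starts = as.character(c(left, right)),
    exon_ends = as.character(c(left + 999L, right + 999L))))
  orth <- orthology_map(data.frame(
    species_a = "human", gene_a = c("G1", "G2"),
    species_b = "sp1", gene_b = c("t1", "t2")))
  ctx <- fake_ctx("G1", "G2", 50000L)
  cands <- find_candidates("L", linc_seq, b, ctx, orth)
  # only the flanked plant at 60 kb survives; the decoy sits beyond both
  # anchors on the same side and is rejected
  expect_equal(nrow(cands), 1L)
  expect_lt(abs(cands$start - 60000L), 50L)
  expect_equal(cands$anchor_u, "G1")
  expect_equal(cands$anchor_d, "G2")
})

test_that("selection keeps anchor groups with enough species support", {
  base <- function(sp, ev, au = "G1", ad = "G2", start = 100L) data.frame(
    linc_id = "L", species = sp, chrom = "chr1", start = start,
    end = start + 400L, strand = "+", score = 50L, evalue = ev,
    log10_evalue = log10(ev), anchor_u = au, anchor_d = ad,
    stringsAsFactors = FALSE)
  # locus A in 3 species, locus B in 1 species: B discarded, 3 selections
  cands <- rbind(base("sp1", 1e-20), base("sp2", 1e-18), base("sp3", 1e-15),
                 base("sp1", 1e-30, au = "G5", ad = "G6", start = 9000L))
  sel <- select_putative_orthologs(cands)
  expect_equal(nrow(sel), 3L)
  expect_true(all(sel$anchor_u == "G1"))
  expect_true(all(sel$species_support == 3L))
  # single-species candidates only: empty
  expect_equal(nrow(select_putative_orthologs(base("sp1", 1e-20))), 0L)
  # two groups, both in 2 species; per species the lower-evalue group wins
  cands2 <- rbind(base("sp1", 1e-20), base("sp2", 1e-20),
                  base("sp1", 1e-12, au = "G5", ad = "G6", start = 9000L),
                  base("sp2", 1e-12, au = "G5", ad = "G6", start = 9000L))
  sel2 <- select_putative_orthologs(cands2)
  expect_equal(nrow(sel2), 2L)
  expect_true(all(sel2$evalue == 1e-20))
  # lowering the support threshold can only add selections
  sel_all <- select_putative_orthologs(cands, min_species_support = 1L)
  expect_gte(nrow(sel_all), nrow(sel))
})

test_that("widening the synteny window never removes candidates", {
  sh <- shared_synth()
  sim <- sh$sim
  human <- read_genome_bundle(sh$cfg$human_fasta, sh$cfg$human_gff,
                              sh$cfg$human_repeats, species = "human")
  sp1 <- read_genome_bundle(sh$cfg$species$sp1$fasta, sh$cfg$species$sp1$gff,
                            sh$cfg$species$sp1$repeats, species = "sp1")
  orth <- read_orthology_map(sh$cfg$orthology_tsv)
  lincs <- read_lincrnas(sh$cfg$lincs_gff, sh$cfg$lincs_fasta)
  picks <- S4Vectors::mcols(lincs$spans)$linc_id[c(2, 10, 20)]
  for (lid in picks) {
    span <- lincs$spans[S4Vectors::mcols(lincs$spans)$linc_id == lid]
    cd <- as.character(lincs$cdna[[lid]])
    n_small <- nrow(find_candidates(
      lid, cd, sp1, neighbor_context(span, human, 30000L), orth,
      window_bp = 30000L))
    n_large <- nrow(find_candidates(
      lid, cd, sp1, neighbor_context(span, human, 60000L), orth,
      window_bp = 60000L))
    expect_gte(n_large, n_small)
  }
})
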