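test_that("lambda solves the Karlin-Altschul equation in closed-form cases", {
  expect_equal(solve_ka_lambda(scoring_scheme(match = 1L, mismatch = -1L)),
               log(3), tolerance = 1e-9)
  # scale invariance: doubling all scores halves lambda
  expect_equal(solve_ka_lambda(scoring_scheme(match = 2L, mismatch = -2L)),
               log(3) / 2, tolerance = 1e-9)
  # non-uniform frequencies still satisfy the defining equation
  fr <- c(0.4, 0.1, 0.1, 0.4)
  lam <- solve_ka_lambda(scoring_scheme(), fr)
  pm <- sum(fr^2)
  expect_equal(pm * exp(lam) + (1 - pm) * exp(-lam), 1, tolerance = 1e-9)
  # positive expected score: statistics undefined
  expect_error(solve_ka_lambda(scoring_scheme(), c(1, 0, 0, 0)),
               "non-negative")
})

test_that("simulated K is positive, stable across lengths and fits the tail", {
  sch <- scoring_scheme()
  lam <- log(3)
  k200 <- estimate_ka_K(sch, lambda = lam, n_pairs = 8000, L = 200L, seed = 3L)
  k400 <- estimate_ka_K(sch, lambda = lam, n_pairs = 4000, L = 400L, seed = 4L)
  expect_gt(k200, 0)
  expect_gt(k400, 0)
  expect_lt(abs(k200 - k400) / k200, 0.2)
  # goodness of fit: predicted exceedance counts match observation within
  # Poisson error at a score in the fitting range
  maxes <- lincorigins:::.cpp_sim_max_ungapped(8000L, 200L, 1L, -1L,
                                               rep(0.25, 4), 3L)
  s <- as.integer(quantile(maxes, 0.9))
  pred <- 8000 * (1 - exp(-k200 * 200^2 * exp(-lam * s)))
  obs <- sum(maxes >= s)
  expect_lt(abs(obs - pred), 4 * sqrt(pred))
})

test_that("identity and reverse-complement alignments score full length", {
  set.seed(21)
  q <- random_seq(100)
  sch <- scoring_scheme()
  h <- local_align(q, q, sch)
  expect_equal(h$score[1], 100L)
  expect_equal(h$strand[1], "+")
  expect_equal(c(h$qstart[1], h$qend[1], h$sstart[1], h$send[1]),
               c(1L, 100L, 1L, 100L))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  h2 <- local_align(q, rc, sch)
  expect_equal(h2$score[1], 100L)
  expect_equal(h2$strand[1], "-")
  expect_equal(c(h2$sstart[1], h2$send[1]), c(1L, 100L))
})

test_that("degenerate inputs: empty sequences, no shared words, N never matches", {
  sch <- scoring_scheme()
  expect_equal(nrow(local_align("", "ACGTACGTACGT", sch)), 0L)
  expect_equal(nrow(local_align("ACGTACGTACGT", "", sch)), 0L)
  # poly-A query vs poly-C subject shares no 7-mer
  expect_equal(nrow(local_align(strrep("A", 50), strrep("C", 50), sch,
                                both_strands = FALSE)), 0L)
  # N runs cannot seed or extend into matches
  nn <- strrep("N", 60)
  expect_equal(nrow(local_align(nn, nn, sch)), 0L)
  expect_error(local_align("ACGTRCGTACGTA", "ACGTACGTACGTA", sch),
               "outside")
})

test_that("best local score is symmetric in query and subject", {
  set.seed(31)
  for (i in 1:20) {
    block <- random_seq(40)
    a <- paste0(random_seq(sample(30:80, 1)), block,
                random_seq(sample(30:80, 1)))
    b <- paste0(random_seq(sample(30:80, 1)), block,
                random_seq(sample(30:80, 1)))
    ha <- local_align(a, b, both_strands = FALSE)
    hb <- local_align(b, a, both_strands = FALSE)
    expect_equal(max(ha$score), max(hb$score))
  }
})

test_that("E-values decrease in score and increase in search space", {
  sch <- scoring_scheme()
  ka <- ka_params(sch)
  e <- function(s, n) lincorigins:::.evalue_cols(s, 500, n, ka)$log10_evalue
  expect_true(all(diff(e(seq(20, 60, 5), 1e5)) < 0))
  expect_true(all(diff(e(40, c(1e4, 1e5, 1e6))) > 0))
})

test_that("random shuffled pairs never reach the homology threshold", {
  # calibration: in 1000 random length-500 pairs no hit approaches E < 1e-10
  sch <- scoring_scheme()
  ka <- ka_params(sch)
  set.seed(77)
  n_sig <- 0L
  for (i in 1:1000) {
    h <- local_align(random_seq(500), random_seq(500), sch, ka = ka)
    if (nrow(h) && min(h$log10_evalue) < -10) n_sig <- n_sig + 1L
  }
  expect_equal(n_sig, 0L)
})

test_that("window search honours the cutoff and maps coordinates back", {
  set.seed(55)
  plant <- random_seq(300)
  linc <- paste0(random_seq(100), plant, random_seq(100))
  genome <- paste0(random_seq(4000), mutate_sequence(plant, 0.1),
                   random_seq(4000))
  b <- make_bundle(seq = genome, genes = data.frame(
    gene_id = "g1", biotype = "protein_coding",
    exon_starts = "100", exon_ends = "200"))
  w <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, nchar(genome)))
  hits <- search_windows(linc, b, w)
  expect_equal(nrow(hits), 1L)
  # the retained hit covers >= 80% of the planted homolog
  ov <- min(hits$end, 4000 + 300) - max(hits$start, 4001) + 1
  expect_gte(ov / 300, 0.8)
  # an infinite cutoff returns a superset
  all_hits <- search_windows(linc, b, w, evalue_cutoff = Inf)
  expect_gte(nrow(all_hits), nrow(hits))
  # absurd query with no shared 7-mer: empty
  expect_equal(nrow(search_windows(strrep("AC", 100), b,
                                   GenomicRanges::GRanges(
                                     "chr1", IRanges::IRanges(1, 50)))), 0L)
})
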