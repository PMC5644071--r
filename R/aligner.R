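# Seed-and-extend local DNA alignment with Karlin-Altschul E-values.
# The scorer mirrors a short-word blastn parameterization (word size 7,
# reward +1, penalty -1); gap costs approximate NCBI defaults for +1/-1
# since the source analysis names only word size, reward and penalty.

#' Alignment scoring scheme
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch penalty (< 0).
#' @param gap_open,gap_extend Affine gap costs (non-negative); a gap of
#'   length g costs `gap_open + g * gap_extend`.
#' @param word_size Exact-match seed length (>= 4).
#' @param xdrop X-drop threshold for the ungapped extension stage.
#' @param band Total band width of the gapped extension (odd).
#' @param gapped_trigger Minimum ungapped-extension score that triggers the
#'   banded gapped stage.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -1L,
                           gap_open = 2L, gap_extend = 1L,
                           word_size = 7L, xdrop = 20L, band = 31L,
                           gapped_trigger = 18L) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            word_size >= 4, band %% 2 == 1, xdrop > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 word_size = as.integer(word_size),
                 xdrop = as.integer(xdrop), band = as.integer(band),
                 gapped_trigger = as.integer(gapped_trigger)),
            class = "scoring_scheme")
}

#' Solve the Karlin-Altschul lambda for a match/mismatch scheme
#'
#' Finds the unique positive root of
#' \deqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1}
#' by bracketed root finding.  For +1/-1 scoring with uniform base
#' frequencies the root is `log(3)` in closed form.
#'
#' @param scheme A [scoring_scheme()].
#' @param freqs Background base frequencies (A, C, G, T), summing to 1.
#' @return The positive real lambda (residual below 1e-9).
#' @export
solve_ka_lambda <- function(scheme, freqs = rep(0.25, 4)) {
  stopifnot(inherits(scheme, "scoring_scheme"),
            length(freqs) == 4, abs(sum(freqs) - 1) < 1e-8, all(freqs >= 0))
  p_match <- sum(freqs^2)
  exp_score <- p_match * scheme$match + (1 - p_match) * scheme$mismatch
  if (exp_score >= 0)
    stop("expected score per aligned pair is non-negative; ",
         "Karlin-Altschul statistics undefined")
  f <- function(l) p_match * exp(l * scheme$match) +
    (1 - p_match) * exp(l * scheme$mismatch) - 1
  hi <- 1
  while (f(hi) <= 0) hi <- hi * 2
  root <- uniroot(f, c(1e-12, hi), tol = 1e-14)$root
  if (abs(f(root)) > 1e-9) stop("lambda root finding failed to converge")
  root
}

#' Estimate the Karlin-Altschul K by simulation
#'
#' Simulates i.i.d. random sequence pairs under `freqs`, records the maximum
#' ungapped local-segment score of each pair, and fits
#' \eqn{P(M < S) \approx \exp(-K m n e^{-\lambda S})} over the upper score
#' range.  Finite-length edge effects are not corrected, so the estimate is
#' an effective K for the window sizes the pipeline scans (accurate well
#' within a factor of 2 of the asymptotic value, which is all the E-value
#' threshold requires).
#'
#' @inheritParams solve_ka_lambda
#' @param lambda The Karlin-Altschul lambda for `scheme`/`freqs`.
#' @param n_pairs Number of simulated pairs.
#' @param L Sequence length of each simulated pair.
#' @param seed Seed of the internal (C++-side) random stream; fixed by
#'   default so E-values do not depend on the caller's RNG state.
#' @return Positive real K.
#' @export
estimate_ka_K <- function(scheme, freqs = rep(0.25, 4), lambda = NULL,
                          n_pairs = 1e5, L = 100L, seed = 1L) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  lambda <- lambda %||% solve_ka_lambda(scheme, freqs)
  maxes <- .cpp_sim_max_ungapped(as.integer(n_pairs), as.integer(L),
                                 scheme$match, scheme$mismatch,
                                 as.numeric(freqs), as.integer(seed))
  s_lo <- as.integer(quantile(maxes, 0.5))
  s_hi <- as.integer(quantile(maxes, 0.99))
  svals <- seq(max(s_lo, 2L), max(s_hi, s_lo + 1L))
  k_at <- vapply(svals, function(s) {
    p_below <- mean(maxes < s)
    if (p_below <= 0 || p_below >= 1) return(NA_real_)
    -log(p_below) * exp(lambda * s) / (as.numeric(L)^2)
  }, numeric(1))
  k <- median(k_at, na.rm = TRUE)
  if (!is.finite(k) || k <= 0) stop("K estimation failed")
  k
}

#' Karlin-Altschul parameters for a scheme (cached)
#'
#' @inheritParams solve_ka_lambda
#' @return List with elements `lambda`, `K` and `freqs`.
#' @export
ka_params <- function(scheme, freqs = rep(0.25, 4)) {
  key <- paste(c(unlist(scheme), signif(freqs, 10)), collapse = "|")
  hit <- .lincorigins_cache[[key]]
  if (!is.null(hit)) return(hit)
  lambda <- solve_ka_lambda(scheme, freqs)
  K <- estimate_ka_K(scheme, freqs, lambda)
  out <- list(lambda = lambda, K = K, freqs = freqs)
  .lincorigins_cache[[key]] <- out
  out
}

.evalue_cols <- function(score, m, n, ka) {
  ln_e <- log(ka$K) + log(as.numeric(m)) + log(as.numeric(n)) -
    ka$lambda * score
  list(evalue = exp(pmax(ln_e, log(.Machine$double.xmin))),
       log10_evalue = ln_e / log(10))
}

#' Local alignment of two DNA sequences
#'
#' Seed-and-extend local alignment: exact `word_size`-mer seeds on both
#' strands (the subject is reverse-complemented for the minus strand),
#' ungapped X-drop extension, then banded affine-gap extension around each
#' surviving anchor.  Overlapping hits are merged keeping the maximum score.
#' E-values follow \eqn{E = K m n e^{-\lambda S}} with m the query length
#' and n the (effective) subject length.  `N` never matches; letters
#' outside \{A,C,G,T,N\} are rejected.
#'
#' @param query,subject DNA sequences (character or `DNAString`).
#' @param scheme A [scoring_scheme()].
#' @param ka Karlin-Altschul parameters from [ka_params()] (computed and
#'   cached when `NULL`).
#' @param both_strands Also search the reverse complement of the subject.
#' @param search_n Effective subject search-space length for the E-value
#'   (defaults to the subject length).
#' @param min_score Discard hits below this raw score.
#' @return data.frame with columns `qstart`, `qend`, `sstart`, `send`
#'   (1-based, inclusive, on the forward subject), `strand`, `score`,
#'   `evalue`, `log10_evalue`, sorted by score (decreasing).  Empty
#'   sequences yield an empty hit list.
#' @export
local_align <- function(query, subject, scheme = scoring_scheme(),
                        ka = NULL, both_strands = TRUE, search_n = NULL,
                        min_score = 1L) {
  query <- as.character(query); subject <- as.character(subject)
  empty <- data.frame(qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      strand = character(0), score = integer(0),
                      evalue = numeric(0), log10_evalue = numeric(0))
  if (!nzchar(query) || !nzchar(subject)) return(empty)
  ka <- ka %||% ka_params(scheme)
  q <- encode_dna(query)
  s_fwd <- encode_dna(subject)
  n_sub <- length(s_fwd)
  run1 <- function(s_enc, strand) {
    h <- .cpp_seed_extend(q, s_enc, scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend,
                          scheme$word_size, scheme$xdrop, scheme$band,
                          scheme$gapped_trigger, as.integer(min_score))
    if (nrow(h) == 0L) return(NULL)
    if (strand == "-") {
      ss <- n_sub - h$send + 1L
      se <- n_sub - h$sstart + 1L
      h$sstart <- ss; h$send <- se
    }
    h$strand <- strand
    h
  }
  hits <- rbind(run1(s_fwd, "+"),
                if (both_strands) run1(encode_dna(revcomp_dna(subject)), "-"))
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  ev <- .evalue_cols(hits$score, length(q), search_n %||% n_sub, ka)
  hits$evalue <- ev$evalue
  hits$log10_evalue <- ev$log10_evalue
  hits <- hits[order(-hits$score, hits$sstart, hits$strand), ]
  rownames(hits) <- NULL
  hits
}

#' Search a lincRNA cDNA against genomic windows
#'
#' Runs [local_align()] of the query against each window's genomic
#' sequence and maps hits back to genome coordinates.  Per window, the
#' E-value search space n is that window's length.  Hits are filtered to
#' `evalue < evalue_cutoff` (compared in log space, so extremely strong
#' hits whose E-value underflows are retained).
#'
#' @param cdna Query sequence (character or `DNAString`).
#' @param bundle Target-species [genome_bundle()].
#' @param windows `GRanges` of genomic windows to search.
#' @param scheme A [scoring_scheme()].
#' @param ka Cached [ka_params()] (optional).
#' @param evalue_cutoff Retain hits with E-value strictly below this
#'   (default 1e-10); `Inf` disables the filter.
#' @return data.frame with columns `chrom`, `start`, `end` (1-based
#'   genomic), `strand`, `qstart`, `qend`, `score`, `evalue`,
#'   `log10_evalue`, `window`.
#' @export
search_windows <- function(cdna, bundle, windows, scheme = scoring_scheme(),
                           ka = NULL, evalue_cutoff = 1e-10) {
  stopifnot(inherits(bundle, "genome_bundle"), is(windows, "GRanges"))
  ka <- ka %||% ka_params(scheme)
  out <- list()
  for (i in seq_along(windows)) {
    w <- windows[i]
    chrom <- as.character(GenomicRanges::seqnames(w))
    seq_w <- as.character(Biostrings::subseq(bundle$seqs[[chrom]],
                                             GenomicRanges::start(w),
                                             GenomicRanges::end(w)))
    h <- local_align(cdna, seq_w, scheme, ka = ka,
                     search_n = GenomicRanges::width(w))
    if (nrow(h) == 0L) next
    h$chrom <- chrom
    h$start <- GenomicRanges::start(w) + h$sstart - 1L
    h$end <- GenomicRanges::start(w) + h$send - 1L
    h$window <- i
    out[[length(out) + 1L]] <- h
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(qstart = integer(0), qend = integer(0), sstart = integer(0),
               send = integer(0), strand = character(0), score = integer(0),
               evalue = numeric(0), log10_evalue = numeric(0),
               chrom = character(0), start = integer(0), end = integer(0),
               window = integer(0))
  if (is.finite(evalue_cutoff))
    res <- res[res$log10_evalue < log10(evalue_cutoff), , drop = FALSE]
  res <- res[order(res$log10_evalue, res$chrom, res$start),
             c("chrom", "start", "end", "strand", "qstart", "qend",
               "score", "evalue", "log10_evalue", "window")]
  rownames(res) <- NULL
  res
}
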