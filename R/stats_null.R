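# The two resampling procedures: a dinucleotide-preserving sequence
# shuffle (Altschul-Erickson Eulerian-walk construction) used to build an
# alignment-significance null, and the bootstrap enrichment p-value for
# ceRNA-mRNA pairs.

#' Dinucleotide-preserving sequence shuffle
#'
#' Returns a uniformly random arrangement of the input with identical
#' dinucleotide counts (hence identical mononucleotide counts and first and
#' last base), via the Altschul-Erickson construction: each vertex of the
#' dinucleotide multigraph reserves a random last out-edge, the reserved
#' edges are rejected until they form an arborescence into the final base,
#' then the remaining out-edges are permuted and the Eulerian walk read
#' off.  Every valid arrangement is equally likely.
#'
#' Uses the caller's RNG stream (seed with [set.seed()] for
#' reproducibility).
#'
#' @param seq DNA sequence over \{A,C,G,T\}, length >= 2.  Sequences
#'   containing `N` are rejected: hard-mask or split at N runs first.
#' @return Shuffled sequence (character scalar).
#' @export
dinuc_shuffle <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n < 2L) stop("sequence must have length >= 2")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("dinuc_shuffle requires an N-free {A,C,G,T} sequence")
  first <- chars[1L]; last <- chars[n]
  # out-edge multisets per vertex
  edges <- split(chars[-1L], chars[-n])
  verts <- names(edges)
  if (length(verts) == 1L) return(seq)  # e.g. "AAAA": single arrangement

  repeat {
    last_edge <- vapply(verts, function(v)
      edges[[v]][sample.int(length(edges[[v]]), 1L)], character(1))
    # reserved last edges must lead every vertex (except the final base)
    # into the final base
    ok <- TRUE
    for (v in setdiff(verts, last)) {
      seen <- character(0); cur <- v
      while (cur != last) {
        if (cur %in% seen || !(cur %in% verts)) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }

  walk_edges <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (v == last) {
      sample(e)
    } else {
      i <- match(last_edge[[v]], e)
      rest <- e[-i]
      c(if (length(rest)) sample(rest), e[i])
    }
  })
  names(walk_edges) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1L] <- first
  cur <- first
  for (i in seq(2L, n)) {
    nxt <- walk_edges[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

# shuffle with N handling: split at N runs, shuffle each N-free segment of
# length >= 2, and reassemble (N runs kept in place)
.dinuc_shuffle_masked <- function(seq) {
  seq <- toupper(as.character(seq))
  if (!grepl("N", seq, fixed = TRUE)) return(dinuc_shuffle(seq))
  parts <- regmatches(seq, gregexpr("N+|[^N]+", seq))[[1]]
  paste(vapply(parts, function(p) {
    if (startsWith(p, "N") || nchar(p) < 2L) p else dinuc_shuffle(p)
  }, character(1)), collapse = "")
}

#' Shuffle null distribution of best alignment E-values
#'
#' Shuffles the lincRNA cDNA `n_shuffles` times with dinucleotide
#' composition preserved, aligns each shuffle against the lincRNA's
#' syntenic windows with the same scoring scheme as the real search, and
#' records the minimum E-value per shuffle (`Inf` when a shuffle produces
#' no hit).  The exceedance is the fraction of shuffles reaching an
#' E-value below `evalue_cutoff`.
#'
#' @param linc_id Identifier carried through to the result.
#' @param cdna lincRNA cDNA.  Internal `N` runs are left in place and the
#'   N-free segments shuffled independently.
#' @param bundle Target-species [genome_bundle()].
#' @param windows `GRanges` of syntenic windows (as from
#'   [syntenic_windows()]; no windows means every shuffle scores `Inf`).
#' @param scheme A [scoring_scheme()].
#' @param ka Cached [ka_params()] (optional).
#' @param n_shuffles Number of shuffles (default 5000; must be >= 1).
#' @param evalue_cutoff Threshold for the exceedance (default 1e-10).
#' @return Object of class `shuffle_null`: `linc_id`, `n_shuffles`,
#'   `best_evalues`, `best_log10_evalues`, `exceedance`, `evalue_cutoff`.
#' @export
shuffle_null_distribution <- function(linc_id, cdna, bundle, windows,
                                      scheme = scoring_scheme(), ka = NULL,
                                      n_shuffles = 5000L,
                                      evalue_cutoff = 1e-10) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  ka <- ka %||% ka_params(scheme)
  windows <- if (length(windows)) GenomicRanges::reduce(
    GenomicRanges::granges(windows)) else windows
  best_ev <- numeric(n_shuffles)
  best_l10 <- numeric(n_shuffles)
  for (k in seq_len(n_shuffles)) {
    sh <- .dinuc_shuffle_masked(cdna)
    if (length(windows)) {
      h <- search_windows(sh, bundle, windows, scheme, ka,
                          evalue_cutoff = Inf)
    } else h <- NULL
    if (is.null(h) || nrow(h) == 0L) {
      best_ev[k] <- Inf; best_l10[k] <- Inf
    } else {
      i <- which.min(h$log10_evalue)
      best_ev[k] <- h$evalue[i]; best_l10[k] <- h$log10_evalue[i]
    }
  }
  structure(list(linc_id = linc_id, n_shuffles = as.integer(n_shuffles),
                 best_evalues = best_ev, best_log10_evalues = best_l10,
                 exceedance = mean(best_l10 < log10(evalue_cutoff)),
                 evalue_cutoff = evalue_cutoff),
            class = "shuffle_null")
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat("shuffle_null:", x$linc_id, "|", x$n_shuffles, "shuffles, exceedance",
      x$exceedance, "at E <", format(x$evalue_cutoff), "\n")
  invisible(x)
}

#' Bootstrap enrichment p-value for ceRNA-mRNA pairs
#'
#' Tests whether the observed lincRNA-paralog pairs are enriched for
#' annotated ceRNA-mRNA pairs.  `N_obv` is the number of observed pairs
#' present in the ceRNA table.  Each of `B` replicates draws
#' `n = nrow(observed_pairs)` pairs uniformly with replacement from the
#' universe and counts ceRNA members `N_k` (multiset count).  The p-value
#' is the strict-exceedance proportion
#' \deqn{P(N_{obv}) = \frac{1}{B}\sum_{k=1}^{B} I(N_k > N_{obv}).}
#' With `add_one = TRUE` the conservative estimator
#' `(1 + #exceed) / (1 + B)` is returned instead, which cannot be zero.
#'
#' Uses the caller's RNG stream (seed with [set.seed()]).
#'
#' @param observed_pairs data.frame with columns `lnc_id`, `gene_id` (the
#'   identified lincRNA-paralog pairs; at least one row).
#' @param cerna ceRNA pair table (data.frame `lnc_id`, `gene_id`).
#' @param universe data.frame of all constructible (lincRNA,
#'   protein-coding gene) pairs to sample from; must be non-empty.
#' @param B Number of bootstrap replicates (default 10,000).
#' @param add_one Use the add-one conservative estimator.
#' @return Object of class `bootstrap_result`: `N_obv`, `B`,
#'   `null_counts`, `p_value`, `add_one`.
#' @export
cerna_bootstrap_p <- function(observed_pairs, cerna, universe, B = 10000L,
                              add_one = FALSE) {
  stopifnot(nrow(observed_pairs) >= 1L)
  if (is.null(universe) || nrow(universe) == 0L) stop("empty universe")
  key <- function(df) paste(df$lnc_id, df$gene_id, sep = "\r")
  cerna_keys <- unique(key(cerna))
  n_obv <- sum(key(observed_pairs) %in% cerna_keys)
  n <- nrow(observed_pairs)
  uni_in <- key(universe) %in% cerna_keys
  null_counts <- integer(B)
  chunk <- max(1L, floor(2e6 / n))
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    draw <- matrix(sample.int(length(uni_in), n * b, replace = TRUE),
                   nrow = n)
    null_counts[done + seq_len(b)] <- colSums(matrix(uni_in[draw], nrow = n))
    done <- done + b
  }
  exceed <- sum(null_counts > n_obv)
  p <- if (add_one) (1 + exceed) / (1 + B) else exceed / B
  structure(list(N_obv = n_obv, B = as.integer(B),
                 null_counts = null_counts, p_value = p,
                 add_one = add_one),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("bootstrap_result: N_obv =", x$N_obv, "| B =", x$B,
      "| p =", format(x$p_value), if (x$add_one) "(add-one)" else "", "\n")
  invisible(x)
}
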