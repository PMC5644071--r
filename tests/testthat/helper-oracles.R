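# Independent reference implementations used as oracles.  These are kept
# deliberately naive (full dynamic programming, brute-force scans,
# exhaustive enumeration) and share no code with the package internals.

# Full O(mn) Smith-Waterman with affine gaps: a gap of length g costs
# gap_open + g * gap_extend.  Returns the optimal local score.
sw_score <- function(a, b, match = 1, mismatch = -1, gap_open = 2,
                     gap_extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     F[i - 1, j] - gap_extend)
      s <- if (av[i - 1] == bv[j - 1] && av[i - 1] != "N") match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# brute-force 1-bp overlap test between one interval and a set
brute_overlaps <- function(chrom, start, end, df) {
  which(df$chrom == chrom & df$start <= end & df$end >= start)
}

# all distinct arrangements of a sequence with identical dinucleotide
# counts (exhaustive Eulerian-walk enumeration over the edge multiset)
enumerate_dinuc_arrangements <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  edges <- split(chars[-1], chars[-n])
  out <- character(0)
  walk <- function(cur, remaining, acc) {
    if (sum(lengths(remaining)) == 0L) {
      out[[length(out) + 1L]] <<- paste(acc, collapse = "")
      return(invisible(NULL))
    }
    nexts <- unique(remaining[[cur]])
    for (nx in nexts) {
      rem2 <- remaining
      rem2[[cur]] <- rem2[[cur]][-match(nx, rem2[[cur]])]
      walk(nx, rem2, c(acc, nx))
    }
  }
  walk(chars[1], edges, chars[1])
  sort(unique(out))
}

# naive application of the cross-species selection cascade, written as a
# direct transcription of the rules with explicit loops
naive_select <- function(cands, min_support = 2L) {
  picked <- list()
  for (linc in sort(unique(cands$linc_id))) {
    cc <- cands[cands$linc_id == linc, , drop = FALSE]
    grp <- paste(cc$anchor_u, cc$anchor_d, sep = "|")
    sup <- sapply(unique(grp), function(g)
      length(unique(cc$species[grp == g])))
    keep <- grp %in% names(sup)[sup >= min_support]
    cc <- cc[keep, , drop = FALSE]; grp <- grp[keep]
    for (sp in sort(unique(cc$species))) {
      rows <- which(cc$species == sp)
      best <- NULL
      for (r in rows) {
        cand <- list(row = r, sup = sup[[grp[r]]], ev = cc$log10_evalue[r],
                     chrom = cc$chrom[r], start = cc$start[r])
        better <- is.null(best) ||
          cand$sup > best$sup ||
          (cand$sup == best$sup && cand$ev < best$ev) ||
          (cand$sup == best$sup && cand$ev == best$ev &&
             (cand$chrom < best$chrom ||
                (cand$chrom == best$chrom && cand$start < best$start)))
        if (better) best <- cand
      }
      picked[[length(picked) + 1L]] <- cc[best$row, , drop = FALSE]
    }
  }
  if (!length(picked)) return(NULL)
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

# dinucleotide count vector (16 entries) of a sequence
dinuc_counts <- function(x) {
  pairs <- substring(x, 1:(nchar(x) - 1), 2:nchar(x))
  all16 <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           paste0))
  table(factor(pairs, levels = all16))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
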