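# Synthetic comparative-genome generator with planted ground truth.  One
# human chromosome carries a backbone of orthologous protein-coding genes
# with lincRNAs in the intergenic slots; each target species carries the
# orthologous backbone in the same order, with the lincRNA homolog planted
# according to its scenario (intergenic copy, inside a new exon, inside an
# intron, under a non-coding annotation, absent, or the two
# pseudogenization scenarios).  All emitted files use the exact formats the
# pipeline reads, and every plant is recorded in a machine-readable truth
# set.

.SCENARIOS <- c("intergenic_homolog", "exonic_homolog", "intronic_homolog",
                "noncoding_homolog", "no_homolog", "unitary_scenario",
                "duplicated_scenario")

#' Configuration of the synthetic comparative dataset
#'
#' Defaults describe the study conditions the test-suite exercises: three
#' target species at 5% per-site divergence from human with five lincRNAs
#' per scenario, on a small chromosome whose synteny window is scaled to
#' the gene spacing.
#'
#' @param rng_seed Seed for the generator (all randomness flows from it).
#' @param n_species Number of target species (>= 2 when any homolog
#'   scenario is requested).
#' @param divergence Per-site substitution probability per target species
#'   (scalar recycled, or vector of length `n_species`); must be in
#'   [0, 0.3].
#' @param n_lincs Named integer vector of lincRNAs per scenario (names
#'   from `intergenic_homolog`, `exonic_homolog`, `intronic_homolog`,
#'   `noncoding_homolog`, `no_homolog`, `unitary_scenario`,
#'   `duplicated_scenario`).
#' @param n_extra_genes Additional background human coding genes appended
#'   after the backbone (they enlarge the ceRNA sampling universe).
#' @param te_library Named character vector of TE consensus sequences
#'   (names `name#class/family`); generated internally when `NULL`.
#' @param te_density Fraction of each intronic-scenario homolog covered by
#'   a planted TE fragment.
#' @param p_te_gap Probability that an intergenic gap hosts a background TE
#'   insertion.
#' @param exon_count_range,exon_len_range,intron_len_range Gene-structure
#'   distributions for backbone genes.
#' @param linc_len_range lincRNA length range (>= 200 nt by definition).
#' @param gap_len Intergenic gap length between consecutive features.
#' @param window_bp Synteny window matched to this genome scale (recorded
#'   in the manifest so a pipeline run uses the same scale).
#' @param paralog_divergence Divergence of the planted human paralog gene
#'   from its lincRNA (duplicated-pseudogene scenario).
#' @param cerna_frac Fraction of planted (lincRNA, paralog) pairs annotated
#'   in the emitted ceRNA table.
#' @param n_cerna_decoys Random non-planted ceRNA pairs added as decoys.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L, n_species = 3L, divergence = 0.05,
                       n_lincs = c(intergenic_homolog = 5L,
                                   exonic_homolog = 5L,
                                   intronic_homolog = 5L,
                                   noncoding_homolog = 5L,
                                   no_homolog = 5L,
                                   unitary_scenario = 5L,
                                   duplicated_scenario = 5L),
                       n_extra_genes = 4L, te_library = NULL,
                       te_density = 0.2, p_te_gap = 0.3,
                       exon_count_range = c(2L, 4L),
                       exon_len_range = c(150L, 400L),
                       intron_len_range = c(300L, 900L),
                       linc_len_range = c(400L, 800L),
                       gap_len = 6000L, window_bp = 50000L,
                       paralog_divergence = 0.05,
                       cerna_frac = 0.6, n_cerna_decoys = 50L) {
  full <- setNames(rep(0L, length(.SCENARIOS)), .SCENARIOS)
  stopifnot(all(names(n_lincs) %in% .SCENARIOS), all(n_lincs >= 0))
  full[names(n_lincs)] <- as.integer(n_lincs)
  stopifnot(all(divergence >= 0), all(divergence <= 0.3),
            te_density >= 0, te_density <= 1,
            linc_len_range[1] >= 200L, n_species >= 1L)
  homolog_req <- sum(full[setdiff(.SCENARIOS, "no_homolog")]) > 0
  if (homolog_req && n_species < 2L)
    stop("homolog scenarios need at least 2 target species")
  divergence <- rep_len(divergence, n_species)
  structure(list(rng_seed = as.integer(rng_seed),
                 n_species = as.integer(n_species), divergence = divergence,
                 n_lincs = full, n_extra_genes = as.integer(n_extra_genes),
                 te_library = te_library, te_density = te_density,
                 p_te_gap = p_te_gap,
                 exon_count_range = as.integer(exon_count_range),
                 exon_len_range = as.integer(exon_len_range),
                 intron_len_range = as.integer(intron_len_range),
                 linc_len_range = as.integer(linc_len_range),
                 gap_len = as.integer(gap_len),
                 window_bp = as.integer(window_bp),
                 paralog_divergence = paralog_divergence,
                 cerna_frac = cerna_frac,
                 n_cerna_decoys = as.integer(n_cerna_decoys)),
            class = "sim_config")
}

#' Mutate a DNA sequence under a uniform substitution model
#'
#' Each site is substituted with probability `divergence` to a uniformly
#' chosen different base (Jukes-Cantor-like, no rate heterogeneity).  With
#' `indels = TRUE`, small insertions/deletions (lengths 1-5) are added at
#' rate `divergence / 10` per site.
#'
#' @param seq DNA sequence over \{A,C,G,T\}.
#' @param divergence Per-site substitution probability in [0, 1).
#' @param indels Also apply small indels.
#' @return Mutated sequence (character scalar).
#' @export
mutate_sequence <- function(seq, divergence, indels = FALSE) {
  stopifnot(divergence >= 0, divergence < 1)
  chars <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (divergence > 0 && n > 0) {
    hit <- which(runif(n) < divergence)
    if (length(hit)) {
      bases <- c("A", "C", "G", "T")
      repl <- vapply(chars[hit], function(b)
        sample(setdiff(bases, b), 1L), character(1))
      chars[hit] <- repl
    }
  }
  if (indels && n > 0) {
    rate <- divergence / 10
    ev <- which(runif(n) < rate)
    if (length(ev)) {
      out <- character(0); prev <- 1L
      for (i in ev) {
        out <- c(out, chars[seq(prev, i)])
        len <- sample.int(5L, 1L)
        if (runif(1) < 0.5) {
          out <- c(out, sample(c("A", "C", "G", "T"), len, replace = TRUE))
          prev <- i + 1L
        } else {
          prev <- min(n + 1L, i + 1L + len)
        }
        if (prev > n) break
      }
      if (prev <= n) out <- c(out, chars[seq(prev, n)])
      chars <- out
    }
  }
  paste(chars, collapse = "")
}

# --- internal assembly machinery ----------------------------------------

.new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$pieces <- list(); env$len <- 0L
  env$genes <- list(); env$exons <- list(); env$repeats <- list()
  env
}

.b_append <- function(b, seq) {
  start <- b$len + 1L
  b$pieces[[length(b$pieces) + 1L]] <- seq
  b$len <- b$len + nchar(seq)
  start
}

.b_gene <- function(b, id, biotype, subtype, start, exon_offsets) {
  b$genes[[length(b$genes) + 1L]] <- data.frame(
    gene_id = id, biotype = biotype, pseudogene_subtype = subtype,
    start = start + exon_offsets$start[1L] - 1L,
    end = start + exon_offsets$end[nrow(exon_offsets)] - 1L,
    stringsAsFactors = FALSE)
  b$exons[[length(b$exons) + 1L]] <- data.frame(
    gene_id = id, start = start + exon_offsets$start - 1L,
    end = start + exon_offsets$end - 1L, stringsAsFactors = FALSE)
}

.b_repeat <- function(b, name, class, start, end) {
  b$repeats[[length(b$repeats) + 1L]] <- data.frame(
    repeat_name = name, repeat_class = class, start = start, end = end,
    stringsAsFactors = FALSE)
}

# gene template: interleaved exon/intron sequences with exon offsets
.make_gene_template <- function(cfg) {
  n_ex <- sample(seq(cfg$exon_count_range[1], cfg$exon_count_range[2]), 1L)
  ex_len <- sample(seq(cfg$exon_len_range[1], cfg$exon_len_range[2]), n_ex,
                   replace = TRUE)
  in_len <- if (n_ex > 1L)
    sample(seq(cfg$intron_len_range[1], cfg$intron_len_range[2]), n_ex - 1L,
           replace = TRUE) else integer(0)
  seqs <- character(0); offs <- data.frame(start = integer(0), end = integer(0))
  pos <- 1L
  for (i in seq_len(n_ex)) {
    seqs <- c(seqs, random_dna(ex_len[i]))
    offs <- rbind(offs, data.frame(start = pos, end = pos + ex_len[i] - 1L))
    pos <- pos + ex_len[i]
    if (i < n_ex) { seqs <- c(seqs, random_dna(in_len[i])); pos <- pos + in_len[i] }
  }
  list(seq = paste(seqs, collapse = ""), exon_offsets = offs)
}

# exon offsets for a sequence assembled as e1 i1 e2 ... given lengths
.offsets_from_lengths <- function(ex_lens, in_lens) {
  pos <- 1L; st <- integer(0); en <- integer(0)
  for (i in seq_along(ex_lens)) {
    st <- c(st, pos); en <- c(en, pos + ex_lens[i] - 1L)
    pos <- pos + ex_lens[i] + if (i <= length(in_lens)) in_lens[i] else 0L
  }
  data.frame(start = st, end = en)
}

.default_te_library <- function() {
  c("SIM_L1#LINE/L1" = random_dna(350L),
    "SIM_Alu#SINE/Alu" = random_dna(280L),
    "SIM_ERV#LTR/ERVL" = random_dna(300L))
}

.b_gap <- function(b, cfg, te_library) {
  half <- cfg$gap_len %/% 2L
  .b_append(b, random_dna(half))
  if (runif(1) < cfg$p_te_gap) {
    i <- sample.int(length(te_library), 1L)
    cons <- te_library[[i]]
    frag_len <- sample(seq(80L, nchar(cons)), 1L)
    frag <- mutate_sequence(substr(cons, 1L, frag_len), 0.1)
    s <- .b_append(b, frag)
    nm <- strsplit(names(te_library)[i], "#", fixed = TRUE)[[1]]
    .b_repeat(b, nm[1], nm[2], s, s + nchar(frag) - 1L)
  }
  .b_append(b, random_dna(cfg$gap_len - half))
  invisible(NULL)
}

# --- writers --------------------------------------------------------------

.write_gff3 <- function(genes, exons, path, chrom = "chr1") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    attrs <- sprintf("ID=%s;biotype=%s", genes$gene_id[i], genes$biotype[i])
    if (!is.na(genes$pseudogene_subtype[i]))
      attrs <- paste0(attrs, ";pseudogene_subtype=", genes$pseudogene_subtype[i])
    writeLines(sprintf("%s\tlincorigins_sim\tgene\t%d\t%d\t.\t+\t.\t%s",
                       chrom, genes$start[i], genes$end[i], attrs), con)
    ex <- exons[exons$gene_id == genes$gene_id[i], , drop = FALSE]
    for (j in seq_len(nrow(ex)))
      writeLines(sprintf("%s\tlincorigins_sim\texon\t%d\t%d\t.\t+\t.\tParent=%s",
                         chrom, ex$start[j], ex$end[j], genes$gene_id[i]), con)
  }
  invisible(path)
}

.write_repeat_bed <- function(repeats, path, chrom = "chr1") {
  if (nrow(repeats) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(chrom = chrom, start = repeats$start - 1L,
                   end = repeats$end,
                   name = paste0(repeats$repeat_name, "#", repeats$repeat_class),
                   score = 0L, strand = "+")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

# --- generator ------------------------------------------------------------

#' Generate a synthetic comparative-genome dataset with ground truth
#'
#' Writes per-species FASTA + GFF3 + repeat BED, the human lincRNA GFF3 +
#' cDNA FASTA, the orthology TSV, the ceRNA pair TSV, a truth JSON and a
#' manifest JSON into `dir`.  Identical seeds produce byte-identical
#' bundles.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `files` (named paths), `truth`
#'   (per-lincRNA plant records), `species` and `config`.
#' @export
generate_comparative_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$rng_seed)
  chrom <- "chr1"
  species <- paste0("sp", seq_len(cfg$n_species))
  te_library <- cfg$te_library %||% .default_te_library()

  # lincRNA plan, interleaved so scenarios are spread along the chromosome
  scen_vec <- sample(rep(.SCENARIOS, times = cfg$n_lincs))
  n_linc <- length(scen_vec)
  n_backbone <- n_linc + 1L
  if (n_backbone < 2L) stop("config yields no lincRNA slots")
  lincs <- lapply(seq_len(n_linc), function(i) {
    scen <- scen_vec[i]
    len <- sample(seq(cfg$linc_len_range[1], cfg$linc_len_range[2]), 1L)
    te <- NULL
    if (scen == "intronic_homolog" && cfg$te_density > 0) {
      te_len <- min(len - 20L, round(cfg$te_density * len))
      j <- sample.int(length(te_library), 1L)
      cons <- te_library[[j]]
      frag <- substr(paste(rep(cons, ceiling(te_len / nchar(cons))),
                           collapse = ""), 1L, te_len)
      pre <- (len - te_len) %/% 2L
      seq <- paste0(random_dna(pre), mutate_sequence(frag, 0.05),
                    random_dna(len - pre - te_len))
      nm <- strsplit(names(te_library)[j], "#", fixed = TRUE)[[1]]
      te <- list(offset = pre + 1L, len = te_len, name = nm[1], class = nm[2])
    } else {
      seq <- random_dna(len)
    }
    list(linc_id = sprintf("LINC_%s_%d", sub("_homolog|_scenario", "", scen), i),
         scenario = scen, seq = seq, len = len, te = te)
  })

  backbone <- lapply(seq_len(n_backbone), function(k) .make_gene_template(cfg))
  names(backbone) <- sprintf("G%03d", seq_len(n_backbone))

  orth_edges <- list()
  add_edge <- function(sa, ga, sb, gb) {
    orth_edges[[length(orth_edges) + 1L]] <<- data.frame(
      species_a = sa, gene_a = ga, species_b = sb, gene_b = gb,
      stringsAsFactors = FALSE)
  }

  truth <- lapply(lincs, function(l) {
    list(linc_id = l$linc_id, scenario = l$scenario, species = list())
  })
  names(truth) <- vapply(lincs, `[[`, character(1), "linc_id")

  # ---- human chromosome ----
  hb <- .new_builder()
  linc_rows <- list()
  for (k in seq_len(n_backbone)) {
    if (k > 1L) {
      li <- k - 1L; l <- lincs[[li]]
      .b_gap(hb, cfg, te_library)
      .b_append(hb, random_dna(300L))
      s <- .b_append(hb, l$seq)
      .b_append(hb, random_dna(450L))
      linc_rows[[li]] <- data.frame(linc_id = l$linc_id, start = s,
                                    end = s + l$len - 1L,
                                    stringsAsFactors = FALSE)
      truth[[l$linc_id]]$human_start <- s
      truth[[l$linc_id]]$human_end <- s + l$len - 1L
      truth[[l$linc_id]]$anchors <- c(sprintf("G%03d", k - 1L),
                                      sprintf("G%03d", k))
      if (l$scenario == "unitary_scenario") {
        pg_id <- paste0("PSG_", l$linc_id)
        off <- l$len %/% 2L
        .b_gene(hb, pg_id, "pseudogene", "unitary", s + off,
                data.frame(start = 1L, end = l$len))
        truth[[l$linc_id]]$pseudogene_id <- pg_id
      }
      .b_gap(hb, cfg, te_library)
    }
    gid <- sprintf("G%03d", k)
    gs <- .b_append(hb, backbone[[k]]$seq)
    .b_gene(hb, gid, "protein_coding", NA_character_, gs,
            backbone[[k]]$exon_offsets)
  }
  # paralog genes of the duplicated scenario, beyond the synteny window
  .b_append(hb, random_dna(3L * cfg$window_bp))
  paralog_seqs <- list()
  for (l in lincs) {
    if (l$scenario != "duplicated_scenario") next
    .b_gap(hb, cfg, te_library)
    hid <- paste0("HPAR_", l$linc_id)
    gseq <- paste0(random_dna(150L),
                   mutate_sequence(l$seq, cfg$paralog_divergence),
                   random_dna(150L))
    gs <- .b_append(hb, gseq)
    .b_gene(hb, hid, "protein_coding", NA_character_, gs,
            data.frame(start = 1L, end = nchar(gseq)))
    truth[[l$linc_id]]$paralog_id <- hid
    paralog_seqs[[l$linc_id]] <- hid
  }
  for (j in seq_len(cfg$n_extra_genes)) {
    .b_gap(hb, cfg, te_library)
    tpl <- .make_gene_template(cfg)
    gs <- .b_append(hb, tpl$seq)
    .b_gene(hb, sprintf("GX%02d", j), "protein_coding", NA_character_, gs,
            tpl$exon_offsets)
  }
  .b_append(hb, random_dna(cfg$gap_len))
  human <- hb

  # ---- target species chromosomes ----
  sp_builders <- list()
  for (si in seq_len(cfg$n_species)) {
    sp <- species[si]; d <- cfg$divergence[si]
    sb <- .new_builder()
    for (k in seq_len(n_backbone)) {
      if (k > 1L) {
        li <- k - 1L; l <- lincs[[li]]
        .b_gap(sb, cfg, te_library)
        scen <- l$scenario
        plant <- mutate_sequence(l$seq, d)
        rec <- NULL
        if (scen == "intergenic_homolog") {
          .b_append(sb, random_dna(400L))
          s <- .b_append(sb, plant)
          .b_append(sb, random_dna(400L))
          rec <- list(start = s, end = s + nchar(plant) - 1L, te_bp = 0L)
        } else if (scen %in% c("exonic_homolog", "unitary_scenario",
                               "duplicated_scenario")) {
          ex1 <- paste0(random_dna(200L), plant, random_dna(200L))
          intr <- random_dna(400L); ex2 <- random_dna(250L)
          gid <- sprintf("SC_%s_%s", sp, l$linc_id)
          gs <- .b_append(sb, paste0(ex1, intr, ex2))
          .b_gene(sb, gid, "protein_coding", NA_character_, gs,
                  .offsets_from_lengths(c(nchar(ex1), 250L), 400L))
          rec <- list(start = gs + 200L, end = gs + 200L + nchar(plant) - 1L,
                      te_bp = 0L, scenario_gene = gid)
        } else if (scen == "intronic_homolog") {
          ex1 <- random_dna(250L)
          pre <- random_dna(300L); post <- random_dna(300L)
          intr <- paste0(pre, plant, post)
          ex2 <- random_dna(250L)
          gid <- sprintf("SC_%s_%s", sp, l$linc_id)
          gs <- .b_append(sb, paste0(ex1, intr, ex2))
          .b_gene(sb, gid, "protein_coding", NA_character_, gs,
                  .offsets_from_lengths(c(250L, 250L), nchar(intr)))
          p_start <- gs + 250L + 300L
          rec <- list(start = p_start, end = p_start + nchar(plant) - 1L,
                      te_bp = 0L, scenario_gene = gid)
          if (!is.null(l$te)) {
            t_start <- p_start + l$te$offset - 1L
            .b_repeat(sb, l$te$name, l$te$class, t_start,
                      t_start + l$te$len - 1L)
            rec$te_bp <- l$te$len
          }
        } else if (scen == "noncoding_homolog") {
          .b_append(sb, random_dna(300L))
          s <- .b_append(sb, plant)
          .b_append(sb, random_dna(300L))
          gid <- sprintf("NC_%s_%s", sp, l$linc_id)
          .b_gene(sb, gid, "lincRNA", NA_character_, s - 50L,
                  data.frame(start = 1L, end = nchar(plant) + 100L))
          rec <- list(start = s, end = s + nchar(plant) - 1L, te_bp = 0L)
        } else { # no_homolog
          .b_append(sb, random_dna(600L))
        }
        if (!is.null(rec)) {
          rec$chrom <- chrom
          truth[[l$linc_id]]$species[[sp]] <- rec
        }
        .b_gap(sb, cfg, te_library)
      }
      gid_h <- sprintf("G%03d", k)
      gid_s <- paste0(sp, "_", gid_h)
      gs <- .b_append(sb, mutate_sequence(backbone[[k]]$seq, d))
      .b_gene(sb, gid_s, "protein_coding", NA_character_, gs,
              backbone[[k]]$exon_offsets)
      add_edge("human", gid_h, sp, gid_s)
    }
    .b_append(sb, random_dna(cfg$gap_len))
    sp_builders[[sp]] <- sb
  }

  # backbone orthology across target species, and scenario-gene orthology
  for (k in seq_len(n_backbone)) {
    gid_h <- sprintf("G%03d", k)
    if (cfg$n_species >= 2L)
      for (a in seq_len(cfg$n_species - 1L)) for (b2 in seq(a + 1L, cfg$n_species))
        add_edge(species[a], paste0(species[a], "_", gid_h),
                 species[b2], paste0(species[b2], "_", gid_h))
  }
  for (l in lincs) {
    coding_scen <- l$scenario %in% c("exonic_homolog", "intronic_homolog",
                                     "unitary_scenario", "duplicated_scenario")
    if (!coding_scen) next
    ids <- vapply(species, function(sp) sprintf("SC_%s_%s", sp, l$linc_id),
                  character(1))
    if (length(ids) >= 2L)
      for (a in seq_len(length(ids) - 1L)) for (b2 in seq(a + 1L, length(ids)))
        add_edge(species[a], ids[a], species[b2], ids[b2])
    if (l$scenario == "duplicated_scenario")
      for (a in seq_along(ids))
        add_edge("human", paste0("HPAR_", l$linc_id), species[a], ids[a])
  }

  # expected classification per scenario
  exp_map <- list(
    intergenic_homolog = c("intergenic", "mixed"),
    exonic_homolog = c("protein_coding", "exonic"),
    intronic_homolog = c("protein_coding", "intronic"),
    noncoding_homolog = c("non_coding", "mixed"),
    unitary_scenario = c("protein_coding", "exonic"),
    duplicated_scenario = c("protein_coding", "exonic"))
  for (l in lincs) {
    if (l$scenario == "no_homolog") next
    truth[[l$linc_id]]$expected_class <- exp_map[[l$scenario]][1]
    truth[[l$linc_id]]$expected_structural_label <- exp_map[[l$scenario]][2]
  }

  # ceRNA table: a fraction of the planted (lincRNA, paralog) pairs plus decoys
  dup_lincs <- vapply(Filter(function(l) l$scenario == "duplicated_scenario",
                             lincs), `[[`, character(1), "linc_id")
  planted_pairs <- data.frame(lnc_id = dup_lincs,
                              gene_id = paste0("HPAR_", dup_lincs),
                              stringsAsFactors = FALSE)
  n_annot <- round(cfg$cerna_frac * nrow(planted_pairs))
  annotated <- if (n_annot > 0)
    planted_pairs[sample.int(nrow(planted_pairs), n_annot), , drop = FALSE]
  else planted_pairs[0, , drop = FALSE]
  human_genes_df <- do.call(rbind, human$genes)
  coding_ids <- human_genes_df$gene_id[human_genes_df$biotype == "protein_coding"]
  all_linc_ids <- vapply(lincs, `[[`, character(1), "linc_id")
  decoys <- data.frame(
    lnc_id = sample(all_linc_ids, cfg$n_cerna_decoys, replace = TRUE),
    gene_id = sample(coding_ids, cfg$n_cerna_decoys, replace = TRUE),
    stringsAsFactors = FALSE)
  cerna <- unique(rbind(annotated, decoys))
  cerna <- cerna[!duplicated(paste(cerna$lnc_id, cerna$gene_id)), ]
  cerna <- cerna[order(cerna$lnc_id, cerna$gene_id), , drop = FALSE]
  for (l in lincs)
    if (l$scenario == "duplicated_scenario")
      truth[[l$linc_id]]$cerna_annotated <-
        l$linc_id %in% annotated$lnc_id

  # ---- write files ----
  files <- list()
  finalize <- function(b, sp) {
    seq <- Biostrings::DNAStringSet(paste(unlist(b$pieces), collapse = ""))
    names(seq) <- chrom
    fa <- file.path(dir, paste0(sp, ".fa"))
    Biostrings::writeXStringSet(seq, fa, width = 80L)
    genes <- do.call(rbind, b$genes)
    genes <- genes[order(genes$start, genes$gene_id), , drop = FALSE]
    exons <- do.call(rbind, b$exons)
    gff <- file.path(dir, paste0(sp, ".genes.gff3"))
    .write_gff3(genes, exons, gff, chrom)
    reps <- if (length(b$repeats)) do.call(rbind, b$repeats) else
      data.frame(repeat_name = character(0), repeat_class = character(0),
                 start = integer(0), end = integer(0))
    reps <- reps[order(reps$start), , drop = FALSE]
    bed <- file.path(dir, paste0(sp, ".repeats.bed"))
    .write_repeat_bed(reps, bed, chrom)
    list(fasta = fa, gff = gff, repeats = bed)
  }
  files$human <- finalize(human, "human")
  for (sp in species) files[[sp]] <- finalize(sp_builders[[sp]], sp)

  linc_df <- do.call(rbind, linc_rows)
  linc_gff <- file.path(dir, "lincRNAs.gff3")
  con <- file(linc_gff, "w")
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(linc_df)))
    writeLines(sprintf(
      "%s\tlincorigins_sim\tgene\t%d\t%d\t.\t+\t.\tID=%s;biotype=lincRNA",
      chrom, linc_df$start[i], linc_df$end[i], linc_df$linc_id[i]), con)
  close(con)
  cdna <- Biostrings::DNAStringSet(vapply(lincs, `[[`, character(1), "seq"))
  names(cdna) <- all_linc_ids
  linc_fa <- file.path(dir, "lincRNAs.fa")
  Biostrings::writeXStringSet(cdna, linc_fa, width = 80L)
  files$lincs <- list(gff = linc_gff, fasta = linc_fa)

  orth_df <- unique(do.call(rbind, orth_edges))
  orth_path <- file.path(dir, "orthology.tsv")
  write.table(orth_df, orth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  files$orthology <- orth_path

  cerna_path <- file.path(dir, "cerna_pairs.tsv")
  write.table(cerna, cerna_path, sep = "\t", quote = FALSE, row.names = FALSE)
  files$cerna <- cerna_path

  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, pretty = TRUE)
  files$truth <- truth_path

  manifest <- list(rng_seed = cfg$rng_seed, species = species,
                   divergence = cfg$divergence, window_bp = cfg$window_bp,
                   n_lincs = as.list(cfg$n_lincs), chrom = chrom)
  manifest_path <- file.path(dir, "sim_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  files$manifest <- manifest_path

  invisible(list(dir = dir, files = files, truth = truth, species = species,
                 config = cfg))
}
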