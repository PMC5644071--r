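# End-to-end orchestration: filter -> neighbour context -> syntenic
# windows -> alignment -> candidates -> cross-species selection ->
# classification -> coverage -> TE -> pseudogene/paralog -> ceRNA
# bootstrap -> (optional) shuffle null.  Defaults: word size 7, reward +1,
# penalty -1, E < 1e-10, +/-750 kb synteny windows, TE > 10 bp, B = 10,000,
# 5000 shuffles, >= 2 supporting species.

#' Pipeline configuration
#'
#' @param human_fasta,human_gff,human_repeats Human genome inputs.
#' @param species Named list (by species label) of lists with elements
#'   `fasta`, `gff`, `repeats` for each target species.
#' @param lincs_gff,lincs_fasta Human lincRNA spans and spliced cDNA.
#' @param orthology_tsv Cross-species gene orthology table.
#' @param cerna_tsv ceRNA-mRNA pair table (`NULL` skips the bootstrap).
#' @param word_size,reward,penalty,gap_open,gap_extend Aligner settings.
#' @param evalue_cutoff Homology significance threshold.
#' @param window_bp Synteny window each side of the lincRNA.
#' @param min_te_bp TE-derived threshold (`te_bp > min_te_bp`).
#' @param juxtaposition_bp Pseudogene juxtaposition distance.
#' @param B Bootstrap replicates for the ceRNA test.
#' @param n_shuffles Shuffles for the homology null (when run).
#' @param min_species_support Minimum species support for a candidate
#'   locus group.
#' @param run_shuffle_null Run the dinucleotide-shuffle null for selected
#'   lincRNAs.
#' @param n_shuffle_lincs Restrict the shuffle null to this many lincRNAs
#'   (`NULL` = all with selections).
#' @param rng_seed Seed for the resampling stages.
#' @param out_dir Output directory (`NULL` = no files written).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(human_fasta, human_gff, human_repeats = NULL,
                            species, lincs_gff, lincs_fasta, orthology_tsv,
                            cerna_tsv = NULL,
                            word_size = 7L, reward = 1L, penalty = -1L,
                            gap_open = 2L, gap_extend = 1L,
                            evalue_cutoff = 1e-10, window_bp = 750000L,
                            min_te_bp = 10L, juxtaposition_bp = 10000L,
                            B = 10000L, n_shuffles = 5000L,
                            min_species_support = 2L,
                            run_shuffle_null = FALSE, n_shuffle_lincs = NULL,
                            rng_seed = 1L, out_dir = NULL) {
  structure(list(human_fasta = human_fasta, human_gff = human_gff,
                 human_repeats = human_repeats, species = species,
                 lincs_gff = lincs_gff, lincs_fasta = lincs_fasta,
                 orthology_tsv = orthology_tsv, cerna_tsv = cerna_tsv,
                 word_size = as.integer(word_size),
                 reward = as.integer(reward), penalty = as.integer(penalty),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 evalue_cutoff = evalue_cutoff,
                 window_bp = as.integer(window_bp),
                 min_te_bp = as.integer(min_te_bp),
                 juxtaposition_bp = as.integer(juxtaposition_bp),
                 B = as.integer(B), n_shuffles = as.integer(n_shuffles),
                 min_species_support = as.integer(min_species_support),
                 run_shuffle_null = isTRUE(run_shuffle_null),
                 n_shuffle_lincs = n_shuffle_lincs,
                 rng_seed = as.integer(rng_seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Pipeline configuration for a synthetic dataset directory
#'
#' Reads the simulator manifest and wires up all file paths; the synteny
#' window is taken from the manifest so the search scale matches the
#' simulated genome scale.
#'
#' @param dir Directory written by [generate_comparative_dataset()].
#' @param ... Overrides passed on to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_sim <- function(dir, ...) {
  manifest <- jsonlite::read_json(file.path(dir, "sim_manifest.json"),
                                  simplifyVector = TRUE)
  sp <- lapply(manifest$species, function(s)
    list(fasta = file.path(dir, paste0(s, ".fa")),
         gff = file.path(dir, paste0(s, ".genes.gff3")),
         repeats = file.path(dir, paste0(s, ".repeats.bed"))))
  names(sp) <- manifest$species
  args <- list(human_fasta = file.path(dir, "human.fa"),
               human_gff = file.path(dir, "human.genes.gff3"),
               human_repeats = file.path(dir, "human.repeats.bed"),
               species = sp,
               lincs_gff = file.path(dir, "lincRNAs.gff3"),
               lincs_fasta = file.path(dir, "lincRNAs.fa"),
               orthology_tsv = file.path(dir, "orthology.tsv"),
               cerna_tsv = file.path(dir, "cerna_pairs.tsv"),
               window_bp = manifest$window_bp)
  override <- list(...)
  args[names(override)] <- override
  do.call(pipeline_config, args)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full lincRNA-origin pipeline
#'
#' Executes every stage in order and returns (and optionally writes) the
#' putative-ortholog table, the origin-call table, the ceRNA bootstrap
#' result, per-species class tallies and a machine-readable run manifest.
#'
#' @param cfg A [pipeline_config()].
#' @param verbose Log per-stage counts.
#' @return List of class `pipeline_result` with elements `orthologs`,
#'   `origin_calls`, `observed_pairs`, `bootstrap`, `shuffle_nulls`,
#'   `summary`, `funnel` and `manifest`.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (verbose) message("[lincorigins] ", ...)
  set.seed(cfg$rng_seed)
  scheme <- scoring_scheme(match = cfg$reward, mismatch = cfg$penalty,
                           gap_open = cfg$gap_open,
                           gap_extend = cfg$gap_extend,
                           word_size = cfg$word_size)
  ka <- ka_params(scheme)

  human <- .stage("load_human", read_genome_bundle(
    cfg$human_fasta, cfg$human_gff, cfg$human_repeats, species = "human"))
  bundles <- .stage("load_species", {
    out <- lapply(names(cfg$species), function(sp) {
      s <- cfg$species[[sp]]
      read_genome_bundle(s$fasta, s$gff, s$repeats, species = sp)
    })
    names(out) <- names(cfg$species)
    out
  })
  lincs <- .stage("load_lincs", read_lincrnas(cfg$lincs_gff, cfg$lincs_fasta))
  orth <- .stage("load_orthology", read_orthology_map(cfg$orthology_tsv))
  cerna <- if (!is.null(cfg$cerna_tsv))
    .stage("load_cerna", read_cerna_pairs(cfg$cerna_tsv)) else NULL
  say(length(lincs$spans), " lincRNAs loaded, ", length(bundles),
      " target species")

  n_in <- length(lincs$spans)
  lincs <- .stage("filter_lincrnas", filter_lincrnas(lincs, human))
  say(length(lincs$spans), "/", n_in,
      " lincRNAs retained after coding-overlap filter")

  candidates <- .stage("candidates", {
    rows <- list()
    for (i in seq_along(lincs$spans)) {
      span <- lincs$spans[i]
      lid <- mcols(span)$linc_id
      ctx <- neighbor_context(span, human, cfg$window_bp)
      for (sp in names(bundles)) {
        cc <- find_candidates(lid, as.character(lincs$cdna[[lid]]),
                              bundles[[sp]], ctx, orth, scheme, ka,
                              window_bp = cfg$window_bp,
                              evalue_cutoff = cfg$evalue_cutoff)
        if (nrow(cc)) rows[[length(rows) + 1L]] <- cc
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })
  say(if (is.null(candidates)) 0L else nrow(candidates),
      " synteny-anchored candidates")

  selected <- .stage("select", select_putative_orthologs(
    candidates %||% data.frame(), cfg$min_species_support))
  say(nrow(selected), " putative orthologs selected (",
      length(unique(selected$linc_id)), " lincRNAs)")

  orthologs <- .stage("classify_coverage", {
    if (nrow(selected)) {
      extra <- lapply(seq_len(nrow(selected)), function(r) {
        b <- bundles[[selected$species[r]]]
        region <- gr1(selected$chrom[r], selected$start[r], selected$end[r])
        cls <- classify_ortholog(region, b)
        cov <- coverage_profile(region, b)
        te <- te_coverage(region, b, cfg$min_te_bp)
        data.frame(class = cls, exon_cov = cov$exon_cov,
                   intron_cov = cov$intron_cov,
                   intergenic_cov = cov$intergenic_cov,
                   structural_label = cov$structural_label,
                   te_cov = te$te_cov, te_derived = te$te_derived,
                   stringsAsFactors = FALSE)
      })
      cbind(selected, do.call(rbind, extra))
    } else cbind(selected, data.frame(
      class = character(0), exon_cov = numeric(0), intron_cov = numeric(0),
      intergenic_cov = numeric(0), structural_label = character(0),
      te_cov = numeric(0), te_derived = logical(0)))
  })

  origin_calls <- .stage("pseudogene_paralog", {
    rows <- list()
    for (lid in unique(orthologs$linc_id)) {
      oo <- orthologs[orthologs$linc_id == lid, , drop = FALSE]
      exonic <- oo[oo$structural_label == "exonic" &
                     oo$class == "protein_coding", , drop = FALSE]
      if (nrow(exonic) == 0L) next
      eligible <- all(exonic$te_cov == 0)
      prot <- aligned_proteins(oo, bundles)
      orth_ok <- aligned_protein_orthology_check(prot, orth)
      paralogs <- if (eligible && nrow(prot))
        putative_paralogs(as.character(lincs$cdna[[lid]]), prot, orth,
                          human, scheme, ka,
                          evalue_cutoff = cfg$evalue_cutoff)
      else character(0)
      span <- lincs$spans[mcols(lincs$spans)$linc_id == lid]
      rel <- pseudogene_relation(span, human, cfg$juxtaposition_bp)
      hyp <- if (eligible)
        origin_hypothesis(paralogs, rel$relation) else "unclassified"
      rows[[length(rows) + 1L]] <- data.frame(
        linc_id = lid, eligible = eligible,
        n_aligned_proteins = nrow(prot),
        aligned_proteins_orthologous = orth_ok,
        paralogs = paste(paralogs, collapse = ","),
        pseudogene_relation = rel$relation,
        nearest_pseudogene = rel$nearest_pseudogene,
        pseudogene_distance = rel$distance,
        hypothesis = hyp, stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else data.frame(
      linc_id = character(0), eligible = logical(0),
      n_aligned_proteins = integer(0),
      aligned_proteins_orthologous = logical(0), paralogs = character(0),
      pseudogene_relation = character(0), nearest_pseudogene = character(0),
      pseudogene_distance = integer(0), hypothesis = character(0))
  })
  say(nrow(origin_calls), " lincRNAs with exonic orthologs typed (",
      sum(origin_calls$hypothesis == "unitary_candidate"), " unitary, ",
      sum(origin_calls$hypothesis == "duplicated_candidate"),
      " duplicated candidates)")

  observed_pairs <- .stage("paralog_pairs", {
    with_par <- origin_calls[nzchar(origin_calls$paralogs), , drop = FALSE]
    if (nrow(with_par)) {
      do.call(rbind, lapply(seq_len(nrow(with_par)), function(r)
        data.frame(lnc_id = with_par$linc_id[r],
                   gene_id = strsplit(with_par$paralogs[r], ",")[[1]],
                   stringsAsFactors = FALSE)))
    } else data.frame(lnc_id = character(0), gene_id = character(0))
  })

  bootstrap <- NULL
  if (!is.null(cerna) && nrow(observed_pairs) >= 1L) {
    bootstrap <- .stage("cerna_bootstrap", {
      coding_ids <- mcols(human$genes)$gene_id[
        mcols(human$genes)$biotype == "protein_coding"]
      linc_ids <- mcols(lincs$spans)$linc_id
      universe <- data.frame(
        lnc_id = rep(linc_ids, each = length(coding_ids)),
        gene_id = rep(coding_ids, times = length(linc_ids)),
        stringsAsFactors = FALSE)
      cerna_bootstrap_p(observed_pairs, cerna, universe, B = cfg$B)
    })
    say("ceRNA bootstrap: N_obv = ", bootstrap$N_obv, ", p = ",
        format(bootstrap$p_value))
  }

  shuffle_nulls <- NULL
  if (cfg$run_shuffle_null && nrow(orthologs)) {
    shuffle_nulls <- .stage("shuffle_null", {
      lids <- unique(orthologs$linc_id)
      if (!is.null(cfg$n_shuffle_lincs))
        lids <- head(lids, cfg$n_shuffle_lincs)
      out <- lapply(lids, function(lid) {
        span <- lincs$spans[mcols(lincs$spans)$linc_id == lid]
        ctx <- neighbor_context(span, human, cfg$window_bp)
        per_sp <- orthologs[orthologs$linc_id == lid, "species"]
        sp <- per_sp[1L]
        wins <- syntenic_windows(ctx, bundles[[sp]], orth,
                                 window_bp = cfg$window_bp)
        shuffle_null_distribution(lid, as.character(lincs$cdna[[lid]]),
                                  bundles[[sp]], wins, scheme, ka,
                                  n_shuffles = cfg$n_shuffles,
                                  evalue_cutoff = cfg$evalue_cutoff)
      })
      names(out) <- lids
      out
    })
  }

  summary_tab <- .stage("summary", {
    if (nrow(orthologs)) {
      tab <- as.data.frame(table(species = orthologs$species,
                                 class = orthologs$class),
                           stringsAsFactors = FALSE)
      names(tab)[3] <- "n"
      tab[tab$n > 0 | TRUE, , drop = FALSE]
    } else data.frame(species = character(0), class = character(0),
                      n = integer(0))
  })
  funnel <- list(lincs_in = n_in, lincs_filtered = length(lincs$spans),
                 candidates = if (is.null(candidates)) 0L else nrow(candidates),
                 selected = nrow(orthologs),
                 lincs_with_ortholog = length(unique(orthologs$linc_id)))

  manifest <- list(
    package_version = as.character(utils::packageVersion("lincorigins")),
    rng_seed = cfg$rng_seed,
    parameters = cfg[c("word_size", "reward", "penalty", "gap_open",
                       "gap_extend", "evalue_cutoff", "window_bp",
                       "min_te_bp", "juxtaposition_bp", "B", "n_shuffles",
                       "min_species_support")],
    ka = list(lambda = ka$lambda, K = ka$K),
    inputs = cfg[c("human_fasta", "human_gff", "human_repeats",
                   "lincs_gff", "lincs_fasta", "orthology_tsv", "cerna_tsv")],
    funnel = funnel)

  result <- structure(list(candidates = candidates,
                           orthologs = orthologs, origin_calls = origin_calls,
                           observed_pairs = observed_pairs,
                           bootstrap = bootstrap,
                           shuffle_nulls = shuffle_nulls,
                           summary = summary_tab, funnel = funnel,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(cfg$out_dir)) .write_pipeline_outputs(result, cfg)
  result
}

.write_pipeline_outputs <- function(result, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_ortholog_table(result$orthologs,
                       file.path(cfg$out_dir, "putative_orthologs.tsv"))
  write.table(result$origin_calls,
              file.path(cfg$out_dir, "origin_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$summary, file.path(cfg$out_dir, "class_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$bootstrap)) {
    bs <- result$bootstrap
    jsonlite::write_json(
      list(N_obv = bs$N_obv, B = bs$B, p_value = bs$p_value,
           add_one = bs$add_one, rng_seed = cfg$rng_seed),
      file.path(cfg$out_dir, "cerna_bootstrap.json"), auto_unbox = TRUE,
      pretty = TRUE)
  }
  jsonlite::write_json(result$manifest,
                       file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", x$funnel$selected, "putative orthologs for",
      x$funnel$lincs_with_ortholog, "lincRNAs\n")
  if (!is.null(x$bootstrap))
    cat("  ceRNA bootstrap: N_obv =", x$bootstrap$N_obv, ", p =",
        format(x$bootstrap$p_value), "\n")
  invisible(x)
}

#' Compare pipeline output against a synthetic truth set
#'
#' For every planted homolog, checks whether a putative ortholog was
#' selected at the planted locus (same chromosome, covering at least
#' `min_cover` of the plant) with the planted class and structural label,
#' and tallies recovery per scenario.  Also counts selections for
#' no-homolog lincRNAs and scores the origin hypotheses against the
#' planted pseudogenization scenarios.
#'
#' @param result A `pipeline_result`.
#' @param truth Truth records from [generate_comparative_dataset()].
#' @param min_cover Minimum fraction of the planted region the selected
#'   region must cover.
#' @return List with `per_scenario` (data.frame: scenario, planted,
#'   recovered, rate), `no_homolog_selections`, `origin` (data.frame:
#'   scenario, planted, correct, rate).
#' @export
score_recovery <- function(result, truth, min_cover = 0.8) {
  orth <- result$orthologs
  scen_rows <- list(); correct_origin <- list()
  no_hom_sel <- 0L
  for (t in truth) {
    if (t$scenario == "no_homolog") {
      no_hom_sel <- no_hom_sel + sum(orth$linc_id == t$linc_id)
      next
    }
    for (sp in names(t$species)) {
      plant <- t$species[[sp]]
      sel <- orth[orth$linc_id == t$linc_id & orth$species == sp, ,
                  drop = FALSE]
      ok <- FALSE
      if (nrow(sel) == 1L && sel$chrom == plant$chrom) {
        ov <- min(sel$end, plant$end) - max(sel$start, plant$start) + 1L
        cov <- ov / (plant$end - plant$start + 1L)
        ok <- ov > 0 && cov >= min_cover &&
          sel$class == t$expected_class &&
          sel$structural_label == t$expected_structural_label
      }
      scen_rows[[length(scen_rows) + 1L]] <- data.frame(
        scenario = t$scenario, ok = ok, stringsAsFactors = FALSE)
    }
    if (t$scenario %in% c("unitary_scenario", "duplicated_scenario")) {
      want <- if (t$scenario == "unitary_scenario") "unitary_candidate"
              else "duplicated_candidate"
      got <- result$origin_calls$hypothesis[
        result$origin_calls$linc_id == t$linc_id]
      correct_origin[[length(correct_origin) + 1L]] <- data.frame(
        scenario = t$scenario, ok = length(got) == 1L && got == want,
        stringsAsFactors = FALSE)
    }
  }
  agg <- function(rows) {
    if (!length(rows)) return(data.frame(scenario = character(0),
                                         planted = integer(0),
                                         recovered = integer(0),
                                         rate = numeric(0)))
    df <- do.call(rbind, rows)
    out <- do.call(rbind, lapply(split(df, df$scenario), function(g)
      data.frame(scenario = g$scenario[1], planted = nrow(g),
                 recovered = sum(g$ok), rate = mean(g$ok))))
    rownames(out) <- NULL
    out
  }
  list(per_scenario = agg(scen_rows),
       no_homolog_selections = no_hom_sel,
       origin = agg(correct_origin))
}
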