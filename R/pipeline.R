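# End-to-end orchestration of the synthetic study: simulate -> coordinate
# maps & CpG pairing -> methylation divergence -> chromatin divergence ->
# lineage/insertion analyses -> annotation context -> interaction model.
# Every stage reads the bundle files it would read in a real analysis, so
# the full I/O surface is exercised.

#' Pipeline configuration
#'
#' Stage thresholds default to the values the divergence analysis was
#' defined with: per-site depth at least 6, pair depth at most 100,
#' discordance alpha 5e-7, concordance band 0.20, 100 permutations, 500-bp
#' windows with 100-bp profile offsets, 2-kb promoter/proximity windows,
#' remodelling thresholds 0.4 / 0.6, and 1-kb flanks for the paired test.
#'
#' @param sim A [sim_config()] for the synthetic bundle.
#' @param alpha Fisher discordance cutoff.
#' @param delta Concordance band.
#' @param n_perm Permutations for the concordance null.
#' @param window Chromatin window size (bp).
#' @param profile_offset Profile window step (bp).
#' @param min_depth_per_site,max_total_depth Pair depth filters.
#' @param min_species_depth Combined depth filter per species.
#' @param proximity Remodelling proximity to an insertion (bp).
#' @param low_threshold,min_gain Remodelling level thresholds.
#' @param flank_radius Paired flank-test radius (bp).
#' @param promoter_halfwidth Promoter half-window (bp).
#' @param seed Master seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            alpha = 5e-7,
                            delta = 0.20,
                            n_perm = 100,
                            window = 500,
                            profile_offset = 100,
                            min_depth_per_site = 6,
                            max_total_depth = 100,
                            min_species_depth = 5,
                            proximity = 2000,
                            low_threshold = 0.4,
                            min_gain = 0.6,
                            flank_radius = 1000,
                            promoter_halfwidth = 2000,
                            seed = 1) {
  cfg <- as.list(environment())
  cfg$sim$seed <- seed
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic study pipeline
#'
#' Generates the bundle, then runs every analysis stage from the written
#' files, saving per-stage tables under `out_dir` and a machine-readable
#' `summary.json`. Reruns with the same configuration produce a
#' byte-identical summary.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `summary` and the per-stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[paradiverge] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  ## simulate
  say("simulating bundle (seed %d)", config$seed)
  bundle <- stage("simulate",
                  simulate_dataset(config$sim, file.path(out_dir, "data")))
  paths <- bundle$paths

  ## duplication maps and CpG pairing
  aln <- stage("dupmap", parse_duplication_alignments(paths$alignments))
  genome <- Biostrings::readDNAStringSet(paths$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  pairs <- stage("dupmap", find_paralogous_cpg_pairs(aln, genome))
  say("parsed %d alignments; %d paralogous CpG pairs", length(aln), nrow(pairs))

  ## methylation divergence
  res <- stage("methdiv", {
    cov_base <- combine_strand_counts(read_coverage(paths$coverage_base))
    flags <- data.table::fread(paths$site_flags, data.table = FALSE)
    snps <- read_bed(paths$snps)
    p <- attach_pair_counts(pairs, cov_base)
    p <- attach_site_flags(p, flags)
    filt <- filter_pairs(p, filter_policy(
      min_depth_per_site = config$min_depth_per_site,
      max_total_depth = config$max_total_depth, snps = snps))
    tested <- classify_discordant(test_discordance(filt$pairs),
                                  alpha = config$alpha)
    conc <- concordance_summary(tested, delta = config$delta)
    perm <- permutation_null(tested, n_perm = config$n_perm,
                             delta = config$delta, seed = config$seed + 1L)
    disc <- tested[tested$discordant, , drop = FALSE]
    deduped <- dedupe_within_1kb(disc, seed = config$seed + 2L)
    seqdiv <- sequence_divergence_association(tested, aln)
    list(filt = filt, tested = tested, conc = conc, perm = perm,
         disc = disc, deduped = deduped, seqdiv = seqdiv,
         cov_base = cov_base)
  })
  say("retained %d/%d pairs; %d discordant (%d after 1-kb dedupe); permutation p = %.4g",
      nrow(res$tested), res$filt$n_input, nrow(res$disc), nrow(res$deduped),
      res$perm$p_value)

  ## chromatin divergence
  chrom <- stage("chromdiv", {
    mapp <- read_bed(paths$mappability)
    marks <- config$sim$marks
    per_mark <- lapply(marks, function(mark) {
      reads <- read_bed(paths[[paste0("reads_", mark)]])
      wins <- do.call(rbind, lapply(aln, function(a) {
        wp <- make_window_pairs(a, mapp, size = config$window)
        count_window_reads(wp, reads)
      }))
      classify_discordant_windows(test_window_discordance(wins))
    })
    names(per_mark) <- marks
    sp1 <- read_bed(paths$reads_SP1)
    fl <- flanking_read_profile(res$disc, sp1, flank = config$window)
    list(per_mark = per_mark, sp1_flank = fl)
  })
  for (mark in names(chrom$per_mark)) {
    say("%s: %d/%d windows discordant", mark,
        sum(chrom$per_mark[[mark]]$discordant),
        sum(!is.na(chrom$per_mark[[mark]]$p_value)))
  }

  ## lineage: ancestral state, insertions, flanking methylation, expression
  lin <- stage("lineage", {
    chain1 <- read_chain(paths$chain_outgroup1)
    chain2 <- read_chain(paths$chain_outgroup2)
    synteny <- data.table::fread(paths$synteny, data.table = FALSE)
    inter <- res$tested[res$tested$chrom_a != res$tested$chrom_b, , drop = FALSE]
    anc <- if (nrow(inter)) {
      assign_ancestral_derived(inter, chain1, synteny)
    } else {
      character(0)
    }
    repeats <- read_bed(paths$repeats)
    events <- detect_lineage_specific_insertions(repeats, chain1, chain2)
    covh <- combine_strand_counts(read_coverage(paths$coverage_brain_human))
    covo <- combine_strand_counts(read_coverage(paths$coverage_brain_outgroup))
    ortho <- match_orthologous_cpgs(covh, covo, chain1,
                                    min_depth = config$min_species_depth)
    profile <- flanking_methylation_profile(events, ortho,
                                            window = config$window,
                                            offset = config$profile_offset)
    ptest <- paired_flank_test(events, ortho, radius = config$flank_radius)
    remod <- select_remodeled_sites(ortho, events,
                                    proximity = config$proximity,
                                    low_threshold = config$low_threshold,
                                    min_gain = config$min_gain)
    genes <- data.table::fread(paths$genes, data.table = FALSE)
    exprs <- data.table::fread(paths$expression, data.table = FALSE)
    link <- expression_linkage(genes, remod$foreground, exprs,
                               promoter_halfwidth = config$promoter_halfwidth)
    list(inter = inter, ancestral = anc, events = events, ortho = ortho,
         profile = profile, ptest = ptest, remod = remod, link = link)
  })
  say("%d lineage-specific insertions; paired flank t p = %.3g; %d remodelled sites",
      nrow(lin$events), lin$ptest$p_value, nrow(lin$remod$foreground))

  ## annotation context
  ann <- stage("annotate", {
    islands <- read_bed(paths$islands)
    genes <- data.table::fread(paths$genes, data.table = FALSE)
    duplicons <- read_bed(paths$duplicons)
    repeats <- read_bed(paths$repeats)
    disc_sites <- data.frame(chrom = c(res$disc$chrom_a, res$disc$chrom_b),
                             pos = c(res$disc$pos_a, res$disc$pos_b))
    classes <- classify_island_shore(disc_sites$chrom, disc_sites$pos, islands)
    tsstab <- tss_distance_table(res$tested, genes)
    conc_pairs <- res$tested[!res$tested$discordant, , drop = FALSE]
    conc_sites <- data.frame(chrom = c(conc_pairs$chrom_a, conc_pairs$chrom_b),
                             pos = c(conc_pairs$pos_a, conc_pairs$pos_b))
    jct <- junction_distance_test(disc_sites, conc_sites, duplicons)
    rpt <- repeat_proximity_test(res$deduped, repeats)
    fasta_paths <- if (nrow(res$deduped)) {
      hyper_is_a <- res$deduped$hyper_copy == "a"
      sites <- data.frame(
        chrom = c(ifelse(hyper_is_a, res$deduped$chrom_a, res$deduped$chrom_b),
                  ifelse(hyper_is_a, res$deduped$chrom_b, res$deduped$chrom_a)),
        pos = c(ifelse(hyper_is_a, res$deduped$pos_a, res$deduped$pos_b),
                ifelse(hyper_is_a, res$deduped$pos_b, res$deduped$pos_a)),
        group = rep(c("hyper", "hypo"), each = nrow(res$deduped)))
      export_flank_fasta(sites, genome, flank = config$window,
                         out_dir = out_dir, prefix = "discordant_flanks")
    } else {
      character(0)
    }
    list(classes = classes, tss = tsstab, junction = jct, repeat_prox = rpt,
         fasta = fasta_paths)
  })

  ## differentiation interaction model
  mod <- stage("diffmodel", {
    cov_diff <- combine_strand_counts(read_coverage(paths$coverage_diff))
    keyd <- paste0(cov_diff$chrom, ":", cov_diff$pos)
    idx <- match(paste0(res$tested$chrom_a, ":", res$tested$pos_a), keyd)
    lvl_diff <- methylation_level(cov_diff$methylated_reads[idx],
                                  cov_diff$unmethylated_reads[idx])
    dat <- data.frame(x1 = res$tested$level_a,
                      x2 = lvl_diff - res$tested$level_a,
                      y = res$tested$abs_diff)
    fit <- fit_interaction_model(dat)
    bins <- binned_divergence_summary(dat)
    list(data = dat, fit = fit, bins = bins)
  })
  say("interaction model: R^2 = %.3f over %d sites", mod$fit$r_squared, mod$fit$n)

  ## persist stage outputs
  utils::write.table(res$tested, file.path(out_dir, "pair_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(res$disc)) {
    write_bed(data.frame(chrom = c(res$disc$chrom_a, res$disc$chrom_b),
                         start = c(res$disc$pos_a, res$disc$pos_b),
                         end = c(res$disc$pos_a, res$disc$pos_b) + 2L),
              file.path(out_dir, "discordant_sites.bed"))
  }
  for (mark in names(chrom$per_mark)) {
    utils::write.table(chrom$per_mark[[mark]],
                       file.path(out_dir, paste0("windows_", mark, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (nrow(lin$events)) {
    write_bed(lin$events[, c("chrom", "start", "end")],
              file.path(out_dir, "insertion_events.bed"))
  }
  utils::write.table(lin$profile, file.path(out_dir, "flanking_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (set in c("background", "foreground")) {
    s <- lin$remod[[set]]
    if (nrow(s)) {
      write_bed(data.frame(chrom = s$chrom, start = s$pos, end = s$pos + 2L),
                file.path(out_dir, paste0("remodeled_", set, ".bed")))
    }
  }

  anc_tab <- table(factor(lin$ancestral, levels = c("a", "b", "undetermined")))
  summary <- list(
    seed = config$seed,
    n_alignments = length(aln),
    n_pairs_input = res$filt$n_input,
    n_pairs_retained = nrow(res$tested),
    rejected = as.list(res$filt$rejected),
    concordance_proportion = res$conc$proportion_within_delta,
    spearman_rho = res$conc$spearman_rho,
    permutation_p = res$perm$p_value,
    n_discordant = nrow(res$disc),
    n_discordant_deduped = nrow(res$deduped),
    seqdiv_kruskal_p = res$seqdiv$kruskal_p,
    discordant_windows = lapply(chrom$per_mark, function(w) {
      list(tested = sum(!is.na(w$p_value)), discordant = sum(w$discordant))
    }),
    sp1_flank_p = chrom$sp1_flank$p_value,
    ancestral_assignment = as.list(anc_tab),
    n_insertions = nrow(lin$events),
    paired_flank_p = lin$ptest$p_value,
    paired_flank_mean_diff = lin$ptest$mean_diff,
    n_ortho_sites = nrow(lin$ortho),
    n_remodeled_background = nrow(lin$remod$background),
    n_remodeled_foreground = nrow(lin$remod$foreground),
    expression_lower = lin$link$n_lower,
    expression_higher = lin$link$n_higher,
    expression_sign_p = lin$link$p_value,
    discordant_island_fraction = mean(ann$classes == "island"),
    discordant_shore_fraction = mean(ann$classes == "shore"),
    fraction_discordant_distal_tss = ann$tss$fraction_discordant_distal,
    junction_p = ann$junction$p_value,
    model_r_squared = mod$fit$r_squared,
    model_coefficients = as.list(mod$fit$coefficients)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  say("summary written to %s", file.path(out_dir, "summary.json"))
  invisible(list(summary = summary, bundle = bundle, methdiv = res,
                 chromdiv = chrom, lineage = lin, annotate = ann, model = mod))
}
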