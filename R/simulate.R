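# Synthetic-data generator. Emits a complete study bundle -- genome,
# duplication alignments, bisulfite coverage for two cell types and two
# "brain" species, chromatin read tracks, annotation BEDs, outgroup
# alignment chains, gene expression -- with planted ground truth, so every
# downstream stage of the workflow can be tested without any external
# download.

#' Simulation configuration
#'
#' Defaults describe the study conditions the workflow is exercised under:
#' duplicons longer than 1 kb at >90% identity, read depths around 30x
#' with mild overdispersion, a bimodal methylation landscape, planted
#' discordant pairs at an absolute methylation difference of 0.9, and an
#' exponentially decaying methylation elevation around lineage-specific
#' Alu insertions.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_duplicons Number of segmental duplications.
#' @param duplicon_length_range Min/max duplicon length in bp (min > 1000).
#' @param sequence_identity Expected identity between copies, in (0.9, 1].
#' @param p_inverted Probability a duplication is inverted.
#' @param p_interchromosomal Probability the derived copy lands on another
#'   chromosome.
#' @param cpg_density CpG sites per kb inside duplicons.
#' @param depth_mean,depth_dispersion Negative-binomial read-depth model
#'   (dispersion 0 gives Poisson depths).
#' @param bb_dispersion Beta-binomial overdispersion of methylation counts
#'   (0 gives binomial counts).
#' @param meth_mixture_weights,meth_mixture_means Two-component mixture of
#'   low/high baseline methylation.
#' @param n_planted_discordant Number of planted discordant CpG pairs.
#' @param planted_discordance_delta Absolute methylation difference
#'   planted at discordant pairs.
#' @param n_planted_insertions Lineage-specific Alu insertions per lineage.
#' @param insertion_max_elevation,insertion_decay_bp Maximum methylation
#'   elevation at an insertion breakpoint and its exponential decay length.
#' @param model_coefficients Named beta0..beta3 for the differentiation
#'   interaction model generating paralog divergence.
#' @param noise_sd Gaussian noise on the model-generated divergence.
#' @param marks Chromatin mark names to simulate read tracks for.
#' @param n_planted_windows Windows per mark with complete one-copy loss.
#' @param n_shared_repeats Repeat elements present in all genomes.
#' @param n_remodeled Insertions with strongly remodelled flanking sites.
#' @param n_background_cpg CpG sites outside duplicated regions.
#' @param n_flank_cpg_per_insertion CpG sites planted around each
#'   insertion breakpoint.
#' @param n_genes Genes in the expression table.
#' @param n_snp_pairs,n_alt_pairs,n_nocyto_pairs Pairs planted to fail the
#'   SNP / alternative-allele / cytosine-evidence filters.
#' @param seed Integer seed; a fixed seed makes the bundle byte-identical.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length = 700000,
                       n_duplicons = 30,
                       duplicon_length_range = c(1500, 4000),
                       sequence_identity = 0.97,
                       p_inverted = 0.25,
                       p_interchromosomal = 0.4,
                       cpg_density = 8,
                       depth_mean = 30,
                       depth_dispersion = 0.05,
                       bb_dispersion = 0.02,
                       meth_mixture_weights = c(0.35, 0.65),
                       meth_mixture_means = c(0.08, 0.88),
                       n_planted_discordant = 25,
                       planted_discordance_delta = 0.9,
                       n_planted_insertions = 20,
                       insertion_max_elevation = 0.2,
                       insertion_decay_bp = 300,
                       model_coefficients = c(beta0 = 0.03, beta1 = 0.02,
                                              beta2 = 0.5, beta3 = -1.0),
                       noise_sd = 0.05,
                       marks = c("H3K4me3", "DNase"),
                       n_planted_windows = 6,
                       n_shared_repeats = 20,
                       n_remodeled = 8,
                       n_background_cpg = 3000,
                       n_flank_cpg_per_insertion = 25,
                       n_genes = 60,
                       n_snp_pairs = 5,
                       n_alt_pairs = 3,
                       n_nocyto_pairs = 3,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$duplicon_length_range[1] > 1000,
    cfg$sequence_identity > 0.9, cfg$sequence_identity <= 1,
    cfg$p_inverted >= 0, cfg$p_inverted <= 1,
    cfg$bb_dispersion >= 0, cfg$bb_dispersion < 1,
    abs(sum(cfg$meth_mixture_weights) - 1) < 1e-8,
    all(cfg$meth_mixture_means >= 0 & cfg$meth_mixture_means <= 1),
    cfg$planted_discordance_delta >= 0, cfg$planted_discordance_delta <= 1,
    cfg$insertion_max_elevation >= 0, cfg$insertion_max_elevation <= 1,
    cfg$noise_sd >= 0
  )
  structure(cfg, class = "sim_config")
}

# beta-binomial counts; rho = 0 degrades to binomial
rbetabinom <- function(n, size, mu, rho) {
  mu <- pmin(pmax(mu, 0), 1)
  if (rho <= 0) return(rbinom(n, size, mu))
  conc <- 1 / rho - 1
  p <- rbeta(n, pmax(mu * conc, 1e-8), pmax((1 - mu) * conc, 1e-8))
  p[mu == 0] <- 0
  p[mu == 1] <- 1
  rbinom(n, size, p)
}

#' Simulate bisulfite read counts for CpG sites
#'
#' Depths are drawn from a negative binomial (Poisson when
#' `depth_dispersion = 0`); methylated counts are beta-binomial around the
#' true level (`bb_dispersion = 0` gives plain binomial sampling). A
#' zero depth yields the empty site (0, 0).
#'
#' @param true_level True methylation level per site (vector, in \[0, 1\]).
#' @param depth_mean Mean read depth.
#' @param depth_dispersion Negative-binomial dispersion of depth.
#' @param bb_dispersion Beta-binomial overdispersion of the counts.
#' @param depth Optional fixed depth vector overriding the depth model.
#' @return Data frame with `methylated_reads` and `unmethylated_reads`.
#' @export
simulate_bisulfite_counts <- function(true_level, depth_mean = 30,
                                      depth_dispersion = 0,
                                      bb_dispersion = 0,
                                      depth = NULL) {
  stopifnot(all(true_level >= 0 & true_level <= 1))
  n <- length(true_level)
  if (is.null(depth)) {
    depth <- if (depth_dispersion <= 0) {
      rpois(n, depth_mean)
    } else {
      rnbinom(n, mu = depth_mean, size = 1 / depth_dispersion)
    }
  } else {
    depth <- rep_len(depth, n)
  }
  m <- rbetabinom(n, depth, true_level, bb_dispersion)
  data.frame(methylated_reads = as.integer(m),
             unmethylated_reads = as.integer(depth - m))
}

# two-component baseline methylation mixture
draw_mixture_levels <- function(n, weights, means, conc = 30) {
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  mu <- means[comp]
  pmin(pmax(rbeta(n, mu * conc + 0.5, (1 - mu) * conc + 0.5), 0.001), 0.999)
}

#' Simulate paralogous pair counts without a genome
#'
#' Lightweight generator for calibration studies: draws per-pair true
#' levels (shared between the copies, independent under
#' `independent_levels = TRUE`, or separated by `delta` for the first
#' `n_discordant` planted pairs) and samples read counts per copy.
#'
#' @param n_pairs Number of pairs.
#' @param n_discordant Planted discordant pairs (levels `delta` apart).
#' @param delta Planted absolute level difference.
#' @param depth_mean,depth_dispersion,bb_dispersion Count model, as in
#'   [simulate_bisulfite_counts()].
#' @param independent_levels Draw the two copies' levels independently
#'   (a paralog-free null).
#' @param meth_mixture_weights,meth_mixture_means Baseline mixture.
#' @param seed Integer seed.
#' @return Pair table with coordinates on synthetic chromosomes, counts
#'   and a logical `planted_discordant` column; planted ids are in
#'   attribute `planted_ids`.
#' @export
simulate_pair_counts <- function(n_pairs, n_discordant = 0, delta = 0.9,
                                 depth_mean = 30, depth_dispersion = 0.05,
                                 bb_dispersion = 0.02,
                                 independent_levels = FALSE,
                                 meth_mixture_weights = c(0.35, 0.65),
                                 meth_mixture_means = c(0.08, 0.88),
                                 seed = 1) {
  stopifnot(n_discordant <= n_pairs)
  set.seed(seed)
  la <- draw_mixture_levels(n_pairs, meth_mixture_weights, meth_mixture_means)
  lb <- if (independent_levels) {
    draw_mixture_levels(n_pairs, meth_mixture_weights, meth_mixture_means)
  } else {
    pmin(pmax(la + rnorm(n_pairs, 0, 0.02), 0), 1)
  }
  planted <- seq_len(n_discordant)
  if (n_discordant > 0) {
    la[planted] <- 0.5 + delta / 2
    lb[planted] <- 0.5 - delta / 2
  }
  ca <- simulate_bisulfite_counts(la, depth_mean, depth_dispersion, bb_dispersion)
  cb <- simulate_bisulfite_counts(lb, depth_mean, depth_dispersion, bb_dispersion)
  out <- data.frame(
    alignment_id = sprintf("aln%04d", seq_len(n_pairs)),
    chrom_a = "chrA", pos_a = seq_len(n_pairs) * 10L,
    chrom_b = "chrB", pos_b = seq_len(n_pairs) * 10L,
    true_level_a = la, true_level_b = lb,
    meth_a = ca$methylated_reads, unmeth_a = ca$unmethylated_reads,
    meth_b = cb$methylated_reads, unmeth_b = cb$unmethylated_reads,
    planted_discordant = seq_len(n_pairs) %in% planted
  )
  out$pair_id <- cpg_pair_id(out$chrom_a, out$pos_a, out$chrom_b, out$pos_b)
  attr(out, "planted_ids") <- out$pair_id[planted]
  out
}

#' Simulate interaction-model input rows
#'
#' Draws methylation levels and differentiation changes and generates the
#' divergence response exactly from the interaction model plus Gaussian
#' noise, for parameter-recovery studies.
#'
#' @param n Number of rows.
#' @param beta Named coefficients beta0..beta3.
#' @param noise_sd Gaussian noise standard deviation (0 = noiseless).
#' @param seed Integer seed.
#' @return Data frame with `x1`, `x2`, `y`.
#' @export
simulate_divergence_model_input <- function(n,
                                            beta = c(beta0 = 0.1, beta1 = 0.2,
                                                     beta2 = -0.3, beta3 = 0.15),
                                            noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  x1 <- runif(n)
  x2 <- runif(n, -0.5, 0.5)
  y <- beta[["beta0"]] + beta[["beta1"]] * x1 + beta[["beta2"]] * x2 +
    beta[["beta3"]] * x1 * x2 + rnorm(n, 0, noise_sd)
  data.frame(x1 = x1, x2 = x2, y = y)
}

## ---- internal placement helpers ------------------------------------------

# scrub CG dinucleotides from a character vector (G -> A); no new CG can arise
scrub_cg <- function(ch) {
  i <- which(ch[-length(ch)] == "C" & ch[-1] == "G")
  if (length(i)) ch[i + 1] <- "A"
  ch
}

revcomp_chars <- function(ch) {
  rev(c(A = "T", C = "G", G = "C", T = "A")[ch])
}

# registry of reserved genomic intervals to keep planted features apart
new_registry <- function(chroms, lengths) {
  env <- new.env()
  env$occ <- data.frame(chrom = character(), start = numeric(), end = numeric())
  env$chroms <- chroms
  env$lengths <- setNames(lengths, chroms)
  env
}

reserve <- function(reg, chrom, start, end) {
  reg$occ <- rbind(reg$occ, data.frame(chrom = chrom, start = start, end = end))
}

place_interval <- function(reg, len, margin, chrom = NULL, max_tries = 2000) {
  for (i in seq_len(max_tries)) {
    cc <- if (is.null(chrom)) sample(reg$chroms, 1) else chrom
    s <- floor(runif(1, margin, reg$lengths[[cc]] - len - margin))
    occ <- reg$occ[reg$occ$chrom == cc, , drop = FALSE]
    if (!nrow(occ) || all(s - margin >= occ$end | s + len + margin <= occ$start)) {
      reserve(reg, cc, s, s + len)
      return(list(chrom = cc, start = s, end = s + len))
    }
  }
  stop("could not place an interval of ", len, " bp; genome too crowded")
}

# free positions on a chromosome (complement of occupied intervals + margin)
free_positions <- function(reg, chrom, margin = 50) {
  occ <- reg$occ[reg$occ$chrom == chrom, , drop = FALSE]
  len <- reg$lengths[[chrom]]
  keep <- rep(TRUE, len)
  if (nrow(occ)) {
    for (i in seq_len(nrow(occ))) {
      a <- max(1, occ$start[i] - margin + 1)
      b <- min(len, occ$end[i] + margin)
      keep[a:b] <- FALSE
    }
  }
  keep[c(1:margin, (len - margin):len)] <- FALSE
  which(keep) - 1L
}

# chain block construction: deletions are reference spans absent from the
# outgroup (dt gaps); insertions are outgroup-only sequence at a reference
# breakpoint (dq gaps)
build_chain_blocks <- function(chrom_len, deletions, insertions) {
  ev <- rbind(
    if (nrow(deletions)) data.frame(pos = deletions$start, dt = deletions$end - deletions$start, dq = 0) else NULL,
    if (nrow(insertions)) data.frame(pos = insertions$pos, dt = 0, dq = insertions$len) else NULL
  )
  if (is.null(ev) || !nrow(ev)) {
    return(list(blocks = data.frame(size = chrom_len, dt = NA, dq = NA),
                q_len = chrom_len))
  }
  ev <- ev[order(ev$pos), , drop = FALSE]
  blocks <- NULL
  cur <- 0
  for (i in seq_len(nrow(ev))) {
    size <- ev$pos[i] - cur
    stopifnot(size > 0)
    blocks <- rbind(blocks, data.frame(size = size, dt = ev$dt[i], dq = ev$dq[i]))
    cur <- ev$pos[i] + ev$dt[i]
  }
  blocks <- rbind(blocks, data.frame(size = chrom_len - cur, dt = NA, dq = NA))
  list(blocks = blocks,
       q_len = chrom_len - sum(ev$dt) + sum(ev$dq))
}

# reference -> outgroup coordinate conversion implied by the blocks
make_h2q <- function(deletions, insertions) {
  force(deletions)
  force(insertions)
  function(pos) {
    shift_del <- vapply(pos, function(p) {
      sum(pmin(pmax(p - deletions$start, 0), deletions$end - deletions$start))
    }, numeric(1))
    shift_ins <- vapply(pos, function(p) sum(insertions$len[insertions$pos <= p]),
                        numeric(1))
    pos - shift_del + shift_ins
  }
}

write_chain_file <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    writeLines(sprintf("chain 1000 %s %d + %d %d %s %d + %d %d %d",
                       ch$t_chrom, ch$t_size, ch$t_start, ch$t_end,
                       ch$q_chrom, ch$q_size, ch$q_start, ch$q_end, i), con)
    b <- ch$blocks
    for (j in seq_len(nrow(b))) {
      if (j < nrow(b)) {
        writeLines(sprintf("%d %d %d", b$size[j], b$dt[j], b$dq[j]), con)
      } else {
        writeLines(sprintf("%d", b$size[j]), con)
      }
    }
    writeLines("", con)
  }
  invisible(path)
}

## ---- the bundle generator -------------------------------------------------

#' Generate a complete synthetic study bundle
#'
#' Writes a genome, duplication alignments, per-CpG bisulfite coverage for
#' a base and a differentiated cell type, chromatin read tracks with
#' planted one-copy losses, mappability/SNP/island/TSS/repeat annotations,
#' chains to two outgroup genomes with planted lineage-specific Alu
#' insertions, cross-species "brain" methylation coverage with an
#' exponentially decaying elevation around insertion breakpoints, a gene
#' expression table coupled to promoter remodelling, and a ground-truth
#' JSON.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, per-file `paths`, and the `truth`
#'   list (also written to `truth.json`).
#' @export
simulate_dataset <- function(config = sim_config(), out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  lens <- rep(config$chrom_length, config$n_chromosomes)

  ## genome scaffold without CpGs
  seqs <- lapply(lens, function(L) {
    scrub_cg(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                    prob = c(0.3, 0.2, 0.2, 0.3)))
  })
  names(seqs) <- chroms
  reg <- new_registry(chroms, lens)

  ## duplicons: source (ancestral) copy with planted CpGs, mutated target copy
  alignments <- vector("list", config$n_duplicons)
  anc_truth <- NULL
  duplicon_bed <- NULL
  for (i in seq_len(config$n_duplicons)) {
    len <- round(runif(1, config$duplicon_length_range[1],
                       config$duplicon_length_range[2]))
    src <- place_interval(reg, len, margin = 1300)
    tgt_chrom <- if (runif(1) < config$p_interchromosomal && length(chroms) > 1) {
      sample(setdiff(chroms, src$chrom), 1)
    } else {
      src$chrom
    }
    tgt <- place_interval(reg, len, margin = 1300, chrom = tgt_chrom)
    inverted <- runif(1) < config$p_inverted

    n_cpg <- max(2L, round(len / 1000 * config$cpg_density))
    cand <- seq(src$start + 5L, src$end - 7L, by = 4L)
    cpg_at <- sort(sample(cand, min(n_cpg, length(cand))))
    sc <- seqs[[src$chrom]]
    sc[cpg_at + 1L] <- "C"
    sc[cpg_at + 2L] <- "G"
    seqs[[src$chrom]] <- sc

    src_chars <- seqs[[src$chrom]][(src$start + 1L):src$end]
    mut <- src_chars
    n_mut <- rbinom(1, len, 1 - config$sequence_identity)
    if (n_mut > 0) {
      at <- sample.int(len, n_mut)
      mut[at] <- vapply(mut[at], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    tgt_plus <- if (inverted) revcomp_chars(mut) else mut
    seqs[[tgt$chrom]][(tgt$start + 1L):tgt$end] <- tgt_plus

    src_is_a <- runif(1) < 0.5
    strand_b <- if (inverted) "-" else "+"
    id <- sprintf("aln%04d", i)
    aln <- if (src_is_a) {
      duplicon_alignment(src$chrom, src$start, src$end,
                         tgt$chrom, tgt$start, tgt$end, strand_b,
                         paste(src_chars, collapse = ""),
                         paste(if (inverted) revcomp_chars(tgt_plus) else tgt_plus,
                               collapse = ""),
                         id = id)
    } else {
      duplicon_alignment(tgt$chrom, tgt$start, tgt$end,
                         src$chrom, src$start, src$end, strand_b,
                         paste(tgt_plus, collapse = ""),
                         paste(if (inverted) revcomp_chars(src_chars) else src_chars,
                               collapse = ""),
                         id = id)
    }
    alignments[[i]] <- aln
    anc_truth <- rbind(anc_truth, data.frame(
      alignment_id = id,
      ancestral = if (src_is_a) "a" else "b",
      interchromosomal = src$chrom != tgt$chrom,
      inverted = inverted,
      src_chrom = src$chrom, src_start = src$start, src_end = src$end,
      tgt_chrom = tgt$chrom, tgt_start = tgt$start, tgt_end = tgt$end
    ))
    duplicon_bed <- rbind(duplicon_bed,
      data.frame(chrom = c(src$chrom, tgt$chrom),
                 start = c(src$start, tgt$start),
                 end = c(src$end, tgt$end),
                 name = paste0(id, c("_src", "_tgt"))))
  }

  ## lineage-specific insertions and shared repeats (annotation intervals)
  alu_families <- c("AluY", "AluYa5", "AluYb8")
  ins_human <- NULL
  for (i in seq_len(config$n_planted_insertions)) {
    iv <- place_interval(reg, 300, margin = 2600)
    ins_human <- rbind(ins_human, data.frame(
      chrom = iv$chrom, start = iv$start, end = iv$end,
      name = sample(alu_families, 1, prob = c(0.5, 0.3, 0.2))))
  }
  ins_outgroup <- NULL
  for (i in seq_len(config$n_planted_insertions)) {
    iv <- place_interval(reg, 300, margin = 2600)  # reserves a breakpoint area
    ins_outgroup <- rbind(ins_outgroup, data.frame(
      chrom = iv$chrom, pos = iv$start, len = 300L,
      name = sample(alu_families, 1, prob = c(0.5, 0.3, 0.2))))
  }
  shared_repeats <- NULL
  shared_classes <- c("AluSx", "L1", "LTR", "Simple_repeat")
  for (i in seq_len(config$n_shared_repeats)) {
    cls <- shared_classes[1 + (i %% length(shared_classes))]
    w <- c(AluSx = 300, L1 = 1000, LTR = 500, Simple_repeat = 80)[[cls]]
    iv <- place_interval(reg, w, margin = 500)
    shared_repeats <- rbind(shared_repeats, data.frame(
      chrom = iv$chrom, start = iv$start, end = iv$end, name = cls))
  }

  ## paralogous CpG pairs and their methylation truth
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
  names(genome) <- chroms
  pairs <- find_paralogous_cpg_pairs(alignments, genome)
  np <- nrow(pairs)
  needed <- config$n_planted_discordant + config$n_snp_pairs +
    config$n_alt_pairs + config$n_nocyto_pairs
  if (needed > np) {
    stop("planted pair counts (", needed, ") exceed available CpG pairs (", np, ")")
  }
  beta <- config$model_coefficients
  x1 <- draw_mixture_levels(np, config$meth_mixture_weights, config$meth_mixture_means)
  big_change <- runif(np) < 0.3
  x2 <- ifelse(big_change,
               sample(c(-1, 1), np, replace = TRUE) * runif(np, 0.2, 0.6),
               rnorm(np, 0, 0.05))
  x2 <- pmin(pmax(x2, -x1), 1 - x1)   # differentiated level stays in [0, 1]
  y <- beta[["beta0"]] + beta[["beta1"]] * x1 + beta[["beta2"]] * x2 +
    beta[["beta3"]] * x1 * x2 + rnorm(np, 0, config$noise_sd)
  y <- pmin(pmax(y, 0), 1)
  dir_b <- ifelse(x2 == 0, sample(c(-1, 1), np, replace = TRUE), sign(x2))
  level_a <- x1
  level_b <- pmin(pmax(x1 + dir_b * y, 0), 1)

  take <- sample.int(np, needed)
  planted_disc <- take[seq_len(config$n_planted_discordant)]
  snp_sel <- take[config$n_planted_discordant + seq_len(config$n_snp_pairs)]
  alt_sel <- take[config$n_planted_discordant + config$n_snp_pairs +
                    seq_len(config$n_alt_pairs)]
  cyt_sel <- take[config$n_planted_discordant + config$n_snp_pairs +
                    config$n_alt_pairs + seq_len(config$n_nocyto_pairs)]
  hi <- 0.5 + config$planted_discordance_delta / 2
  lo <- 0.5 - config$planted_discordance_delta / 2
  hyper_a <- runif(length(planted_disc)) < 0.5
  level_a[planted_disc] <- ifelse(hyper_a, hi, lo)
  level_b[planted_disc] <- ifelse(hyper_a, lo, hi)

  x2b <- pmin(pmax(x2 + rnorm(np, 0, 0.03), -level_b), 1 - level_b)
  diff_a <- pmin(pmax(level_a + x2, 0), 1)
  diff_b <- pmin(pmax(level_b + x2b, 0), 1)

  emit_cov <- function(chrom, pos, level) {
    n <- length(pos)
    depth <- rnbinom(n, mu = config$depth_mean, size = 1 / max(config$depth_dispersion, 1e-9))
    d_plus <- rbinom(n, depth, 0.5)
    cp <- simulate_bisulfite_counts(level, depth = d_plus,
                                    bb_dispersion = config$bb_dispersion)
    cm <- simulate_bisulfite_counts(level, depth = depth - d_plus,
                                    bb_dispersion = config$bb_dispersion)
    rbind(
      data.frame(chrom = chrom, pos = pos, strand = "+",
                 methylated_reads = cp$methylated_reads,
                 unmethylated_reads = cp$unmethylated_reads),
      data.frame(chrom = chrom, pos = pos + 1L, strand = "-",
                 methylated_reads = cm$methylated_reads,
                 unmethylated_reads = cm$unmethylated_reads)
    )
  }
  cov_base <- rbind(emit_cov(pairs$chrom_a, pairs$pos_a, level_a),
                    emit_cov(pairs$chrom_b, pairs$pos_b, level_b))
  cov_diff <- rbind(emit_cov(pairs$chrom_a, pairs$pos_a, diff_a),
                    emit_cov(pairs$chrom_b, pairs$pos_b, diff_b))

  ## SNPs and site flags
  snp_bed <- data.frame(chrom = pairs$chrom_a[snp_sel],
                        start = pairs$pos_a[snp_sel],
                        end = pairs$pos_a[snp_sel] + 1L)
  for (i in seq_len(20)) {
    cc <- sample(chroms, 1)
    fp <- free_positions(reg, cc, margin = 20)
    p <- sample(fp, 1)
    snp_bed <- rbind(snp_bed, data.frame(chrom = cc, start = p, end = p + 1L))
  }
  flags <- rbind(
    data.frame(chrom = pairs$chrom_b[alt_sel], pos = pairs$pos_b[alt_sel],
               alt_allele = TRUE, cytosine_evidence = TRUE),
    data.frame(chrom = pairs$chrom_a[cyt_sel], pos = pairs$pos_a[cyt_sel],
               alt_allele = FALSE, cytosine_evidence = FALSE)
  )

  ## Alu elements annotated near the hypermethylated copies of planted pairs
  near_hyper <- data.frame(
    chrom = ifelse(hyper_a, pairs$chrom_a[planted_disc], pairs$chrom_b[planted_disc]),
    pos = ifelse(hyper_a, pairs$pos_a[planted_disc], pairs$pos_b[planted_disc])
  )
  hyper_alu <- data.frame(chrom = near_hyper$chrom,
                          start = near_hyper$pos + 60L,
                          end = near_hyper$pos + 360L,
                          name = "AluSx")
  repeats <- rbind(ins_human,
                   shared_repeats,
                   hyper_alu)
  repeats <- repeats[order(repeats$chrom, repeats$start), ]

  ## chromatin read tracks with planted one-copy losses
  window <- 500L
  read_len <- 35L
  reads_by_mark <- list()
  planted_windows <- NULL
  window_geometry <- function(aln) {
    n_win <- (aln$end_a - aln$start_a) %/% window
    if (n_win == 0) return(NULL)
    data.frame(window_id = sprintf("%s:%d:w%03d", aln$chrom_a, aln$start_a,
                                   seq_len(n_win) - 1L),
               start_a = aln$start_a + (seq_len(n_win) - 1L) * window)
  }
  for (mark in config$marks) {
    reads <- NULL
    geoms <- lapply(alignments, window_geometry)
    all_windows <- do.call(rbind, Map(function(g, k) {
      if (is.null(g)) return(NULL)
      g$aln <- k
      g
    }, geoms, seq_along(geoms)))
    plant_idx <- sample.int(nrow(all_windows), config$n_planted_windows)
    for (w in seq_len(nrow(all_windows))) {
      aln <- alignments[[all_windows$aln[w]]]
      s_a <- all_windows$start_a[w]
      planted_here <- w %in% plant_idx
      lam <- if (planted_here) 25 else runif(1, 4, 15)
      offs_a <- sample.int(window, rpois(1, lam), replace = TRUE) - 1L
      pos_a <- s_a + offs_a
      n_b <- if (planted_here) 0L else rpois(1, lam)
      offs_b <- if (n_b > 0) sample.int(window, n_b, replace = TRUE) - 1L else integer(0)
      rel <- (s_a - aln$start_a) + offs_b
      pos_b <- if (aln$strand_b == "+") {
        aln$start_b + rel
      } else {
        aln$end_b - 1L - rel
      }
      reads <- rbind(reads,
        if (length(pos_a)) data.frame(chrom = aln$chrom_a, start = pos_a,
                                      end = pos_a + read_len, strand = "+") else NULL,
        if (length(pos_b)) data.frame(chrom = aln$chrom_b, start = pos_b,
                                      end = pos_b + read_len, strand = "+") else NULL)
      if (planted_here) {
        planted_windows <- rbind(planted_windows, data.frame(
          mark = mark, window_id = all_windows$window_id[w], zero_copy = "b"))
      }
    }
    reads_by_mark[[mark]] <- reads[order(reads$chrom, reads$start), ]
  }
  ## SP1-like track: enrichment at the hypomethylated copies of planted pairs
  hypo <- data.frame(
    chrom = ifelse(hyper_a, pairs$chrom_b[planted_disc], pairs$chrom_a[planted_disc]),
    pos = ifelse(hyper_a, pairs$pos_b[planted_disc], pairs$pos_a[planted_disc])
  )
  sp1 <- rbind(
    do.call(rbind, lapply(seq_len(nrow(hypo)), function(i) {
      p <- hypo$pos[i] + sample(-400:400, 12, replace = TRUE)
      data.frame(chrom = hypo$chrom[i], start = p, end = p + read_len, strand = "+")
    })),
    do.call(rbind, lapply(seq_len(nrow(near_hyper)), function(i) {
      p <- near_hyper$pos[i] + sample(-400:400, 1)
      data.frame(chrom = near_hyper$chrom[i], start = p, end = p + read_len, strand = "+")
    }))
  )
  reads_by_mark[["SP1"]] <- sp1[order(sp1$chrom, sp1$start), ]

  ## mappability: whole genome minus a few masked patches
  masked <- NULL
  for (i in seq_len(5)) {
    cc <- sample(chroms, 1)
    fp <- free_positions(reg, cc, margin = 60)
    p <- sample(fp, 1)
    masked <- rbind(masked, data.frame(chrom = cc, start = p, end = p + 50L))
  }
  mappable <- do.call(rbind, lapply(chroms, function(cc) {
    mk <- masked[masked$chrom == cc, , drop = FALSE]
    mk <- mk[order(mk$start), , drop = FALSE]
    starts <- c(0L, mk$end)
    ends <- c(mk$start, lens[match(cc, chroms)])
    data.frame(chrom = cc, start = starts, end = ends)[ends > starts, ]
  }))

  ## outgroup chains
  derived_spans <- data.frame(chrom = anc_truth$tgt_chrom,
                              start = anc_truth$tgt_start,
                              end = anc_truth$tgt_end)
  h2q1 <- list()
  chains1 <- list()
  chains2 <- list()
  for (cc in chroms) {
    dels <- rbind(ins_human[ins_human$chrom == cc, c("start", "end")],
                  derived_spans[derived_spans$chrom == cc, c("start", "end")])
    dels <- dels[order(dels$start), , drop = FALSE]
    inss <- ins_outgroup[ins_outgroup$chrom == cc, c("pos", "len"), drop = FALSE]
    L <- lens[match(cc, chroms)]
    b1 <- build_chain_blocks(L, dels, inss)
    chains1[[cc]] <- list(t_chrom = cc, t_size = L, t_start = 0, t_end = L,
                          q_chrom = paste0("pan", cc), q_size = b1$q_len,
                          q_start = 0, q_end = b1$q_len, blocks = b1$blocks)
    h2q1[[cc]] <- make_h2q(dels, inss)
    b2 <- build_chain_blocks(L, dels, inss[0, , drop = FALSE])
    chains2[[cc]] <- list(t_chrom = cc, t_size = L, t_start = 0, t_end = L,
                          q_chrom = paste0("pon", cc), q_size = b2$q_len,
                          q_start = 0, q_end = b2$q_len, blocks = b2$blocks)
  }
  ## paralogy chains: the derived copy aligns to the ancestral outgroup locus
  for (i in seq_len(nrow(anc_truth))) {
    a <- anc_truth[i, ]
    if (a$inverted) next  # inverted derived copies stay unmapped
    qs <- h2q1[[a$src_chrom]](a$src_start)
    qe <- h2q1[[a$src_chrom]](a$src_end)
    span <- a$tgt_end - a$tgt_start
    chains1[[length(chains1) + 1]] <- list(
      t_chrom = a$tgt_chrom, t_size = lens[match(a$tgt_chrom, chroms)],
      t_start = a$tgt_start, t_end = a$tgt_end,
      q_chrom = paste0("pan", a$src_chrom),
      q_size = chains1[[a$src_chrom]]$q_size,
      q_start = qs, q_end = qe,
      blocks = data.frame(size = span, dt = NA, dq = NA))
  }

  ## cross-species brain methylation around insertion breakpoints
  flank_pos <- NULL
  remodeled_ins <- sample.int(nrow(ins_human), min(config$n_remodeled, nrow(ins_human)))
  remodeled_sites <- NULL
  for (i in seq_len(nrow(ins_human))) {
    e <- ins_human[i, ]
    d <- sample(30:1450, config$n_flank_cpg_per_insertion)
    side <- sample(c(-1, 1), length(d), replace = TRUE)
    p <- ifelse(side < 0, e$start - d, e$end + d)
    p <- p[p > 10 & p < lens[match(e$chrom, chroms)] - 10]
    flank_pos <- rbind(flank_pos, data.frame(chrom = e$chrom, pos = p, ins = i))
    if (i %in% remodeled_ins) {
      rp <- c(e$start - sample(40:900, 1), e$end + sample(40:900, 1))
      remodeled_sites <- rbind(remodeled_sites,
                               data.frame(chrom = e$chrom, pos = rp, ins = i))
    }
  }
  bg_pos <- do.call(rbind, lapply(chroms, function(cc) {
    fp <- free_positions(reg, cc, margin = 50)
    fp <- fp[fp %% 4L == 0L]   # enforce spacing
    data.frame(chrom = cc,
               pos = sort(sample(fp, min(length(fp),
                                         config$n_background_cpg %/% length(chroms)))),
               ins = NA_integer_)
  }))
  ortho_sites <- rbind(flank_pos, remodeled_sites, bg_pos)
  ortho_sites <- ortho_sites[order(ortho_sites$chrom, ortho_sites$pos), ]
  ortho_sites <- ortho_sites[!duplicated(paste0(ortho_sites$chrom, ":", ortho_sites$pos)), ]
  # enforce dinucleotide spacing so planted CGs never overlap
  spaced <- unlist(lapply(split(ortho_sites$pos, ortho_sites$chrom), function(p) {
    keep <- rep(TRUE, length(p))
    last <- -10
    for (i in seq_along(p)) {
      if (p[i] - last < 3) keep[i] <- FALSE else last <- p[i]
    }
    keep
  }))
  ortho_sites <- ortho_sites[spaced, , drop = FALSE]
  ## plant the CpG dinucleotides
  for (cc in chroms) {
    p <- ortho_sites$pos[ortho_sites$chrom == cc]
    sc <- seqs[[cc]]
    sc[p + 1L] <- "C"
    sc[p + 2L] <- "G"
    seqs[[cc]] <- sc
  }
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
  names(genome) <- chroms

  dist_to <- function(chrom, pos, events) {
    vapply(seq_along(pos), function(i) {
      ev <- events[events$chrom == chrom[i], , drop = FALSE]
      if (!nrow(ev)) return(Inf)
      min(abs(pos[i] - ev$start), abs(pos[i] - ev$end))
    }, numeric(1))
  }
  base_lvl <- draw_mixture_levels(nrow(ortho_sites), config$meth_mixture_weights,
                                  config$meth_mixture_means)
  d_h <- dist_to(ortho_sites$chrom, ortho_sites$pos, ins_human)
  og_events <- data.frame(chrom = ins_outgroup$chrom, start = ins_outgroup$pos,
                          end = ins_outgroup$pos)
  d_c <- dist_to(ortho_sites$chrom, ortho_sites$pos, og_events)
  elev <- function(d) config$insertion_max_elevation * exp(-d / config$insertion_decay_bp)
  lvl_human <- pmin(base_lvl + elev(d_h), 0.999)
  lvl_outg <- pmin(base_lvl + elev(d_c), 0.999)
  is_remod <- paste0(ortho_sites$chrom, ":", ortho_sites$pos) %in%
    paste0(remodeled_sites$chrom, ":", remodeled_sites$pos)
  lvl_human[is_remod] <- 0.85
  lvl_outg[is_remod] <- 0.10
  cov_brain_h <- emit_cov(ortho_sites$chrom, ortho_sites$pos, lvl_human)
  q_pos <- integer(nrow(ortho_sites))
  for (cc in chroms) {
    sel <- ortho_sites$chrom == cc
    q_pos[sel] <- as.integer(h2q1[[cc]](ortho_sites$pos[sel]))
  }
  cov_brain_o <- emit_cov(paste0("pan", ortho_sites$chrom), q_pos, lvl_outg)

  ## genes and expression
  genes <- NULL
  exprs <- NULL
  remod_truth_genes <- character(0)
  gid <- 0
  for (i in remodeled_ins) {
    gid <- gid + 1
    e <- ins_human[i, ]
    g <- sprintf("GENE%03d", gid)
    tss <- e$end + sample(250:1200, 1)
    ey <- exp(rnorm(1, 2, 0.5))
    lower <- runif(1) < 0.85
    genes <- rbind(genes, data.frame(gene_id = g, chrom = e$chrom, tss = tss,
                                     strand = "+"))
    exprs <- rbind(exprs, data.frame(gene_id = g,
                                     expr_x = if (lower) ey * 0.3 else ey * 1.5,
                                     expr_y = ey))
    remod_truth_genes <- c(remod_truth_genes, g)
  }
  planted_site_pos <- c(pairs$pos_a[planted_disc], pairs$pos_b[planted_disc])
  planted_site_chrom <- c(pairs$chrom_a[planted_disc], pairs$chrom_b[planted_disc])
  while (gid < config$n_genes) {
    gid <- gid + 1
    g <- sprintf("GENE%03d", gid)
    cc <- sample(chroms, 1)
    fp <- free_positions(reg, cc, margin = 20)
    tss <- sample(fp, 1)
    near_disc <- any(planted_site_chrom == cc & abs(planted_site_pos - tss) <= 1200)
    if (near_disc) { gid <- gid - 1; next }
    ey <- exp(rnorm(1, 2, 0.5))
    genes <- rbind(genes, data.frame(gene_id = g, chrom = cc, tss = tss, strand = "+"))
    exprs <- rbind(exprs, data.frame(gene_id = g,
                                     expr_x = ey * exp(rnorm(1, 0, 0.2)),
                                     expr_y = ey))
  }

  ## CpG islands around the first duplicon copies
  islands <- NULL
  for (i in seq_len(min(10, length(alignments)))) {
    aln <- alignments[[i]]
    mid <- (aln$start_a + aln$end_a) %/% 2L
    islands <- rbind(islands, data.frame(chrom = aln$chrom_a,
                                         start = mid - 150L, end = mid + 150L))
  }

  ## write the bundle
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    alignments = file.path(out_dir, "duplicon_alignments.txt"),
    coverage_base = file.path(out_dir, "coverage_base.tsv"),
    coverage_diff = file.path(out_dir, "coverage_diff.tsv"),
    coverage_brain_human = file.path(out_dir, "coverage_brain_human.tsv"),
    coverage_brain_outgroup = file.path(out_dir, "coverage_brain_outgroup.tsv"),
    mappability = file.path(out_dir, "mappability.bed"),
    snps = file.path(out_dir, "snps.bed"),
    site_flags = file.path(out_dir, "site_flags.tsv"),
    repeats = file.path(out_dir, "repeats.bed"),
    islands = file.path(out_dir, "cpg_islands.bed"),
    duplicons = file.path(out_dir, "duplicons.bed"),
    genes = file.path(out_dir, "genes.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    synteny = file.path(out_dir, "synteny.tsv"),
    chain_outgroup1 = file.path(out_dir, "outgroup1.chain"),
    chain_outgroup2 = file.path(out_dir, "outgroup2.chain"),
    truth = file.path(out_dir, "truth.json")
  )
  Biostrings::writeXStringSet(genome, paths$genome)
  write_duplication_alignments(alignments, paths$alignments)
  write_coverage(cov_base[order(cov_base$chrom, cov_base$pos), ], paths$coverage_base)
  write_coverage(cov_diff[order(cov_diff$chrom, cov_diff$pos), ], paths$coverage_diff)
  write_coverage(cov_brain_h[order(cov_brain_h$chrom, cov_brain_h$pos), ],
                 paths$coverage_brain_human)
  write_coverage(cov_brain_o[order(cov_brain_o$chrom, cov_brain_o$pos), ],
                 paths$coverage_brain_outgroup)
  write_bed(mappable, paths$mappability)
  write_bed(snp_bed[order(snp_bed$chrom, snp_bed$start), ], paths$snps)
  data.table::fwrite(flags, paths$site_flags, sep = "\t")
  write_bed(repeats, paths$repeats)
  write_bed(islands[order(islands$chrom, islands$start), ], paths$islands)
  write_bed(duplicon_bed[order(duplicon_bed$chrom, duplicon_bed$start), ],
            paths$duplicons)
  data.table::fwrite(genes, paths$genes, sep = "\t")
  data.table::fwrite(exprs, paths$expression, sep = "\t")
  data.table::fwrite(data.frame(chrom = chroms,
                                outgroup_chrom = paste0("pan", chroms)),
                     paths$synteny, sep = "\t")
  write_chain_file(chains1, paths$chain_outgroup1)
  write_chain_file(chains2, paths$chain_outgroup2)
  for (mark in names(reads_by_mark)) {
    paths[[paste0("reads_", mark)]] <- file.path(out_dir,
                                                 paste0("reads_", mark, ".bed"))
    write_bed(reads_by_mark[[mark]], paths[[paste0("reads_", mark)]])
  }

  truth <- list(
    seed = config$seed,
    n_duplicons = config$n_duplicons,
    n_pairs = np,
    discordant_pair_ids = pairs$pair_id[planted_disc],
    discordant_hyper_copy = ifelse(hyper_a, "a", "b"),
    snp_pair_ids = pairs$pair_id[snp_sel],
    alt_allele_pair_ids = pairs$pair_id[alt_sel],
    no_cytosine_pair_ids = pairs$pair_id[cyt_sel],
    pair_truth = data.frame(pair_id = pairs$pair_id,
                            level_a = level_a, level_b = level_b,
                            x1 = x1, x2 = x2, y = y),
    ancestral = anc_truth,
    insertions_human = ins_human,
    insertions_outgroup = ins_outgroup,
    remodeled_site_ids = paste0(ortho_sites$chrom, ":", ortho_sites$pos)[is_remod],
    remodeled_gene_ids = remod_truth_genes,
    planted_windows = planted_windows,
    model_coefficients = as.list(config$model_coefficients),
    insertion_max_elevation = config$insertion_max_elevation,
    insertion_decay_bp = config$insertion_decay_bp
  )
  write_truth(truth, paths$truth)
  invisible(list(dir = out_dir, paths = paths, truth = truth,
                 alignments = alignments, genome = genome))
}
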