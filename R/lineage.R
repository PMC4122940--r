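# Cross-species analyses: ancestral/derived assignment of interchromosomal
# duplicons through an outgroup genome, lineage-specific Alu insertion
# detection from alignment chains, flanking methylation profiles around
# insertion sites, and linkage of promoter remodelling to expression.

#' Assign ancestral/derived status to interchromosomal CpG pairs
#'
#' Both members of each pair are projected into the outgroup genome
#' through the alignment chain. When both land on the same outgroup
#' chromosome, the copy residing on the human chromosome syntenic with
#' that outgroup chromosome (per the synteny table) is called ancestral;
#' any failed or ambiguous projection, or disagreeing outgroup
#' chromosomes, yields "undetermined". The rule only applies to
#' interchromosomal duplications, so intrachromosomal input is an error.
#'
#' @param pairs Pair table with `chrom_a`, `pos_a`, `chrom_b`, `pos_b`.
#' @param chain Outgroup chain from [read_chain()].
#' @param synteny Data frame with columns `chrom` (reference) and
#'   `outgroup_chrom` listing syntenic chromosome pairs.
#' @return Character vector over pairs: `"a"`, `"b"` or `"undetermined"`.
#' @export
assign_ancestral_derived <- function(pairs, chain, synteny) {
  if (any(pairs$chrom_a == pairs$chrom_b)) {
    stop("ancestral/derived assignment applies to interchromosomal pairs only")
  }
  lift_a <- project_positions(chain, pairs$chrom_a, pairs$pos_a)
  lift_b <- project_positions(chain, pairs$chrom_b, pairs$pos_b)
  syn <- setNames(synteny$chrom, synteny$outgroup_chrom)
  vapply(seq_len(nrow(pairs)), function(i) {
    oa <- lift_a$chrom[i]
    ob <- lift_b$chrom[i]
    if (is.na(oa) || is.na(ob) || oa != ob) return("undetermined")
    anc_chrom <- syn[oa]
    if (is.na(anc_chrom)) return("undetermined")
    if (anc_chrom == pairs$chrom_a[i]) return("a")
    if (anc_chrom == pairs$chrom_b[i]) return("b")
    "undetermined"
  }, character(1))
}

#' Detect lineage-specific repeat insertions
#'
#' An annotated repeat element is called lineage-specific when the
#' fraction of its span covered by alignment blocks is below
#' `min_absent_fraction` in *both* outgroup chains (absent from the
#' orthologous region) while both 200-bp flanks align in both outgroups
#' (so the locus itself is syntenic and the gap reflects an insertion
#' rather than unalignable sequence).
#'
#' @param repeats Repeat annotation data frame (`chrom`, `start`, `end`,
#'   `name` = family label).
#' @param chain1,chain2 Chains to the two outgroup genomes.
#' @param min_absent_fraction Maximum covered fraction still counted as
#'   absent (default 0.1, tolerating alignment edge slop).
#' @param flank Flank width checked for synteny (bp).
#' @param min_flank_fraction Minimum covered fraction of each flank.
#' @return Data frame of insertion events: `chrom`, `start`, `end`,
#'   `family`, `lineage = "reference"`.
#' @export
detect_lineage_specific_insertions <- function(repeats, chain1, chain2,
                                               min_absent_fraction = 0.1,
                                               flank = 200,
                                               min_flank_fraction = 0.5) {
  if (!nrow(repeats)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      family = character(), lineage = character()))
  }
  body1 <- chain_covered_fraction(chain1, repeats)
  body2 <- chain_covered_fraction(chain2, repeats)
  left <- data.frame(chrom = repeats$chrom,
                     start = repeats$start - flank, end = repeats$start)
  right <- data.frame(chrom = repeats$chrom,
                      start = repeats$end, end = repeats$end + flank)
  fl1 <- pmin(chain_covered_fraction(chain1, left), chain_covered_fraction(chain1, right))
  fl2 <- pmin(chain_covered_fraction(chain2, left), chain_covered_fraction(chain2, right))
  specific <- body1 < min_absent_fraction & body2 < min_absent_fraction &
    fl1 >= min_flank_fraction & fl2 >= min_flank_fraction
  out <- repeats[specific, c("chrom", "start", "end"), drop = FALSE]
  out$family <- if ("name" %in% names(repeats)) {
    repeats$name[specific]
  } else {
    rep(NA_character_, nrow(out))
  }
  out$lineage <- rep("reference", nrow(out))
  rownames(out) <- NULL
  out
}

#' Match orthologous CpG sites across two genomes
#'
#' Projects reference CpG sites through the chain and joins the outgroup
#' coverage at the projected position. Sites failing to project, missing
#' from the outgroup table, or with combined depth below `min_depth` in
#' either species are dropped.
#'
#' @param cov_x Combined coverage in the reference genome
#'   ([combine_strand_counts()]).
#' @param cov_y Combined coverage in the outgroup genome.
#' @param chain Reference-to-outgroup chain.
#' @param min_depth Minimum combined depth per species (default 5).
#' @return Data frame with `chrom`, `pos`, `pos_y`, counts and `level_x`,
#'   `level_y`.
#' @export
match_orthologous_cpgs <- function(cov_x, cov_y, chain, min_depth = 5) {
  proj <- project_positions(chain, cov_x$chrom, cov_x$pos)
  keyy <- paste0(cov_y$chrom, ":", cov_y$pos)
  idx <- match(paste0(proj$chrom, ":", proj$pos), keyy)
  ok <- !is.na(idx)
  out <- data.frame(
    chrom = cov_x$chrom[ok], pos = cov_x$pos[ok],
    chrom_y = proj$chrom[ok], pos_y = proj$pos[ok],
    meth_x = cov_x$methylated_reads[ok],
    unmeth_x = cov_x$unmethylated_reads[ok],
    meth_y = cov_y$methylated_reads[idx[ok]],
    unmeth_y = cov_y$unmethylated_reads[idx[ok]],
    stringsAsFactors = FALSE
  )
  deep <- (out$meth_x + out$unmeth_x) >= min_depth &
    (out$meth_y + out$unmeth_y) >= min_depth
  out <- out[deep, , drop = FALSE]
  out$level_x <- methylation_level(out$meth_x, out$unmeth_x)
  out$level_y <- methylation_level(out$meth_y, out$unmeth_y)
  rownames(out) <- NULL
  out
}

# distance (bp) from each site to the nearest insertion breakpoint;
# Inf when the chromosome carries no event
distance_to_events <- function(chrom, pos, events) {
  vapply(seq_along(pos), function(i) {
    ev <- events[events$chrom == chrom[i], , drop = FALSE]
    if (!nrow(ev)) return(Inf)
    min(abs(pos[i] - ev$start), abs(pos[i] - ev$end))
  }, numeric(1))
}

#' Sliding-window methylation profile around insertion sites
#'
#' Groups orthologous CpG sites by distance to the nearest insertion
#' breakpoint into sliding windows of `window` bp advanced by `offset` bp,
#' and reports the mean methylation level with a normal-approximation 95%
#' confidence interval per window and species.
#'
#' @param events Insertion events ([detect_lineage_specific_insertions()]).
#' @param ortho Orthologous site table ([match_orthologous_cpgs()]).
#' @param window Window width in bp.
#' @param offset Step between window starts in bp.
#' @param max_dist Largest distance profiled (windows start at 0 and end
#'   at or before `max_dist`).
#' @return Data frame with one row per window: `dist_start`, `dist_end`,
#'   `n`, and mean/CI columns for each species (`NA` for empty windows).
#' @export
flanking_methylation_profile <- function(events, ortho, window = 500,
                                         offset = 100, max_dist = 2000) {
  if (max_dist < window) {
    starts <- 0
  } else {
    starts <- seq(0, max_dist - window, by = offset)
  }
  d <- distance_to_events(ortho$chrom, ortho$pos, events)
  summarise <- function(x) {
    n <- length(x)
    if (n == 0) return(c(NA_real_, NA_real_, NA_real_))
    m <- mean(x)
    se <- if (n > 1) sd(x) / sqrt(n) else 0
    c(m, m - 1.96 * se, m + 1.96 * se)
  }
  rows <- lapply(starts, function(s) {
    sel <- d >= s & d < s + window
    sx <- summarise(ortho$level_x[sel])
    sy <- summarise(ortho$level_y[sel])
    data.frame(dist_start = s, dist_end = s + window, n = sum(sel),
               mean_x = sx[1], ci_lo_x = sx[2], ci_hi_x = sx[3],
               mean_y = sy[1], ci_lo_y = sy[2], ci_hi_y = sy[3])
  })
  do.call(rbind, rows)
}

#' Paired test of methylation levels flanking insertion sites
#'
#' Paired t-test comparing reference and outgroup methylation levels at
#' orthologous CpG sites within `radius` bp of any insertion event.
#'
#' @param events Insertion events.
#' @param ortho Orthologous site table.
#' @param radius Flank radius in bp (default 1000).
#' @return List with `t`, `p_value`, `mean_diff` and `n` (all NA when
#'   fewer than 2 sites fall in the flanks).
#' @export
paired_flank_test <- function(events, ortho, radius = 1000) {
  d <- distance_to_events(ortho$chrom, ortho$pos, events)
  sel <- d <= radius
  n <- sum(sel)
  if (n < 2) {
    return(list(t = NA_real_, p_value = NA_real_, mean_diff = NA_real_, n = n))
  }
  diffs <- ortho$level_x[sel] - ortho$level_y[sel]
  tt <- if (sd(diffs) == 0) {
    NULL
  } else {
    tryCatch(t.test(ortho$level_x[sel], ortho$level_y[sel], paired = TRUE),
             error = function(e) NULL)
  }
  if (is.null(tt)) {
    # degenerate: (near-)constant difference; no sampling variance
    return(list(t = if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf,
                p_value = if (mean(diffs) == 0) 1 else 0,
                mean_diff = mean(diffs), n = n))
  }
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_diff = unname(tt$estimate), n = n)
}

#' Select remodelled CpG sites near insertions
#'
#' The background set holds orthologous sites of low outgroup methylation
#' (level below `low_threshold`) within `proximity` bp of an insertion
#' event; the foreground subset are those whose reference-genome level
#' exceeds the outgroup level by at least `min_gain` -- sites whose
#' methylation has been substantially remodelled following the insertion.
#' Both sets are intended for export to external enrichment tools.
#'
#' @param ortho Orthologous site table.
#' @param events Insertion events.
#' @param proximity Maximum distance to an insertion breakpoint (bp).
#' @param low_threshold Outgroup level strictly below this is "low".
#' @param min_gain Minimum absolute gain (reference minus outgroup).
#' @return List with `background` and `foreground` data frames.
#' @export
select_remodeled_sites <- function(ortho, events, proximity = 2000,
                                   low_threshold = 0.4, min_gain = 0.6) {
  d <- distance_to_events(ortho$chrom, ortho$pos, events)
  bg <- ortho[ortho$level_y < low_threshold & d <= proximity, , drop = FALSE]
  fg <- bg[(bg$level_x - bg$level_y) >= min_gain, , drop = FALSE]
  rownames(bg) <- rownames(fg) <- NULL
  list(background = bg, foreground = fg)
}

#' Link promoter methylation remodelling to expression differences
#'
#' Genes whose promoter window (TSS +/- `promoter_halfwidth`) contains a
#' remodelled foreground site are tallied by the sign of their
#' reference-minus-outgroup expression difference, with a two-sided exact
#' sign test on the lower/higher counts. Genes lacking expression values
#' are excluded and reported.
#'
#' @param genes Gene table (`gene_id`, `chrom`, `tss`).
#' @param foreground Foreground site table ([select_remodeled_sites()]).
#' @param expression Expression table (`gene_id`, `expr_x`, `expr_y`).
#' @param promoter_halfwidth Promoter half-window around the TSS (bp).
#' @return List with `genes` (selected gene table with expression),
#'   `n_lower`, `n_higher`, `n_tied`, `n_missing_expression`, `p_value`.
#' @export
expression_linkage <- function(genes, foreground, expression,
                               promoter_halfwidth = 2000) {
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    any(foreground$chrom == genes$chrom[i] &
          abs(foreground$pos - genes$tss[i]) <= promoter_halfwidth)
  }, logical(1))
  sel <- genes[hit, , drop = FALSE]
  merged <- merge(sel, expression, by = "gene_id")
  n_missing <- nrow(sel) - nrow(merged)
  if (n_missing > 0) {
    message(n_missing, " selected gene(s) lacked expression values and were excluded")
  }
  d <- merged$expr_x - merged$expr_y
  n_lower <- sum(d < 0)
  n_higher <- sum(d > 0)
  p <- if (n_lower + n_higher > 0) {
    binom_exact_p(n_lower, n_lower + n_higher)
  } else {
    NA_real_
  }
  list(genes = merged, n_lower = n_lower, n_higher = n_higher,
       n_tied = sum(d == 0), n_missing_expression = n_missing, p_value = p)
}
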