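# Methylation divergence between paralogous CpG sites: filtering, Fisher
# discordance calls, concordance summaries and the region-shuffling
# permutation null.

#' Filtering policy for paralogous CpG pairs
#'
#' Defaults reproduce the stringent inclusion rules of the within-sample
#' divergence analysis: each site covered by at least 6 reads, combined
#' coverage of the pair at most 100 (guards against significant but
#' marginal differences at very high depth), no known polymorphism on the
#' cytosine or either flanking base, no reads carrying non-bisulfite
#' alternative alleles, and read-level evidence for a cytosine at the site.
#'
#' @param min_depth_per_site Minimum read depth at each site (inclusive).
#' @param max_total_depth Maximum summed depth across the pair (inclusive).
#' @param snps Optional SNP interval data frame (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @param require_cytosine_evidence Drop pairs where either site lacks a
#'   read supporting the cytosine.
#' @param exclude_alt_allele_sites Drop pairs where either site is flagged
#'   as carrying alternative-allele reads.
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(min_depth_per_site = 6L,
                          max_total_depth = 100L,
                          snps = NULL,
                          require_cytosine_evidence = TRUE,
                          exclude_alt_allele_sites = TRUE) {
  stopifnot(min_depth_per_site >= 1, max_total_depth > 2 * min_depth_per_site)
  structure(list(
    min_depth_per_site = as.integer(min_depth_per_site),
    max_total_depth = as.integer(max_total_depth),
    snps = snps,
    require_cytosine_evidence = require_cytosine_evidence,
    exclude_alt_allele_sites = exclude_alt_allele_sites
  ), class = "filter_policy")
}

# TRUE where [pos-1, pos+2) overlaps any SNP interval on the same chromosome
snp_hits_site <- function(snps, chrom, pos) {
  if (is.null(snps) || !nrow(snps)) return(rep(FALSE, length(pos)))
  site <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos, end = pos + 2L))
  snp <- intervals_to_granges(snps)
  GenomicRanges::countOverlaps(site, snp) > 0
}

#' Filter paralogous CpG pairs
#'
#' Applies [filter_policy()] rules; a pair failing several rules is counted
#' under the first failing rule, in the order: SNP overlap, alternative
#' allele, missing cytosine evidence, low depth, excessive total depth.
#' Optional logical columns `alt_allele_a/b` and `cytosine_evidence_a/b`
#' carry the upstream read-inspection flags; absent columns default to
#' no-alt-allele and evidence-present.
#'
#' @param pairs Pair table with counts ([attach_pair_counts()]).
#' @param policy A [filter_policy()].
#' @return List with `pairs` (retained rows), `rejected` (named counts per
#'   rule) and `n_input`.
#' @export
filter_pairs <- function(pairs, policy = filter_policy()) {
  n <- nrow(pairs)
  flag <- function(col, default) {
    if (col %in% names(pairs)) pairs[[col]] else rep(default, n)
  }
  depth_a <- pairs$meth_a + pairs$unmeth_a
  depth_b <- pairs$meth_b + pairs$unmeth_b
  snp_bad <- snp_hits_site(policy$snps, pairs$chrom_a, pairs$pos_a) |
    snp_hits_site(policy$snps, pairs$chrom_b, pairs$pos_b)
  alt_bad <- policy$exclude_alt_allele_sites &
    (flag("alt_allele_a", FALSE) | flag("alt_allele_b", FALSE))
  cyt_bad <- policy$require_cytosine_evidence &
    (!flag("cytosine_evidence_a", TRUE) | !flag("cytosine_evidence_b", TRUE))
  depth_bad <- depth_a < policy$min_depth_per_site | depth_b < policy$min_depth_per_site
  total_bad <- depth_a + depth_b > policy$max_total_depth
  reason <- rep(NA_character_, n)
  reason[total_bad] <- "high_total_depth"
  reason[depth_bad] <- "low_depth"
  reason[cyt_bad] <- "no_cytosine_evidence"
  reason[alt_bad] <- "alt_allele"
  reason[snp_bad] <- "snp_overlap"
  keep <- is.na(reason)
  rejected <- table(factor(reason[!keep], levels = c(
    "snp_overlap", "alt_allele", "no_cytosine_evidence",
    "low_depth", "high_total_depth"
  )))
  list(
    pairs = pairs[keep, , drop = FALSE],
    rejected = setNames(as.integer(rejected), names(rejected)),
    n_input = n
  )
}

#' Methylation level of a site
#' @param meth,unmeth Read counts.
#' @return Proportion of methylated reads (NA at zero depth).
#' @export
methylation_level <- function(meth, unmeth) {
  depth <- meth + unmeth
  ifelse(depth > 0, meth / depth, NA_real_)
}

#' Test paralogous pairs for methylation discordance
#'
#' Adds methylation levels, the absolute level difference, and the
#' two-sided Fisher exact p-value comparing the 2x2 read-count table of
#' the two copies.
#'
#' @param pairs Filtered pair table.
#' @return The table with `level_a`, `level_b`, `abs_diff` and `p_value`.
#' @export
test_discordance <- function(pairs) {
  pairs$level_a <- methylation_level(pairs$meth_a, pairs$unmeth_a)
  pairs$level_b <- methylation_level(pairs$meth_b, pairs$unmeth_b)
  pairs$abs_diff <- abs(pairs$level_a - pairs$level_b)
  pairs$p_value <- fisher_exact_p(pairs$meth_a, pairs$unmeth_a,
                                  pairs$meth_b, pairs$unmeth_b)
  pairs
}

#' Call discordant pairs at a significance cutoff
#'
#' A pair is discordant when its Fisher p-value is strictly below `alpha`
#' (default 5e-7, approximately Bonferroni 0.05 at the scale of a
#' genome-wide paralogous-pair screen). With `recompute_alpha = TRUE`,
#' `alpha` is set to `0.05 / nrow(pairs)`. Discordant pairs are labelled
#' with their hypermethylated copy.
#'
#' @param pairs Table from [test_discordance()].
#' @param alpha Significance cutoff (strict inequality).
#' @param recompute_alpha Recompute alpha as 0.05 / n pairs.
#' @return The table with logical `discordant` and `hyper_copy`
#'   (`"a"`/`"b"`, NA for concordant pairs); the alpha used is attached as
#'   attribute `alpha`.
#' @export
classify_discordant <- function(pairs, alpha = 5e-7, recompute_alpha = FALSE) {
  if (recompute_alpha) alpha <- 0.05 / nrow(pairs)
  pairs$discordant <- !is.na(pairs$p_value) & pairs$p_value < alpha
  pairs$hyper_copy <- ifelse(pairs$discordant,
                             ifelse(pairs$level_a > pairs$level_b, "a", "b"),
                             NA_character_)
  attr(pairs, "alpha") <- alpha
  pairs
}

#' Concordance summary of paralogous methylation levels
#'
#' @param pairs Table with `level_a` and `level_b`.
#' @param delta Concordance band on the absolute level difference
#'   (inclusive).
#' @return List with `proportion_within_delta`, `spearman_rho` (NA when a
#'   level vector is constant) and `n`.
#' @export
concordance_summary <- function(pairs, delta = 0.20) {
  if (nrow(pairs) < 2) stop("need at least 2 pairs for a concordance summary")
  d <- abs(pairs$level_a - pairs$level_b)
  rho <- if (sd(pairs$level_a) == 0 || sd(pairs$level_b) == 0) {
    NA_real_
  } else {
    cor(pairs$level_a, pairs$level_b, method = "spearman")
  }
  list(
    proportion_within_delta = mean(d <= delta),
    spearman_rho = rho,
    n = nrow(pairs)
  )
}

#' Region-shuffling permutation null for methylation concordance
#'
#' Breaks the paralogous pairing by re-pairing sites at random across all
#' duplicated regions: in each permutation the second member of every pair
#' is replaced by a site drawn without replacement from the pooled set of
#' all paired sites (`scheme = "repool"`, the default) or by shuffling the
#' second members among pairs (`scheme = "shuffle"`). The empirical
#' p-value is `(#{permutation statistic >= observed} + 1) / (n_perm + 1)`.
#'
#' @param pairs Table with `level_a` and `level_b`.
#' @param n_perm Number of permutations (default 100).
#' @param delta Concordance band for the statistic.
#' @param seed Integer seed; fixed seed gives a reproducible null.
#' @param scheme Re-pairing scheme, see Details.
#' @return List with `p_value`, `observed`, `perm_stats` and `n_perm`.
#' @export
permutation_null <- function(pairs, n_perm = 100, delta = 0.20, seed = 1,
                             scheme = c("repool", "shuffle")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be at least 1")
  la <- pairs$level_a
  lb <- pairs$level_b
  observed <- mean(abs(la - lb) <= delta)
  pool <- c(la, lb)
  n <- length(la)
  set.seed(seed)
  perm_stats <- vapply(seq_len(n_perm), function(i) {
    newb <- if (scheme == "repool") sample(pool, n) else sample(lb, n)
    mean(abs(la - newb) <= delta)
  }, numeric(1))
  list(
    p_value = (sum(perm_stats >= observed) + 1) / (n_perm + 1),
    observed = observed,
    perm_stats = perm_stats,
    n_perm = n_perm
  )
}

#' Thin discordant pairs to one per 1-kb locus
#'
#' Motif-discovery export must not count a locus twice, so where several
#' discordant pairs fall within 1 kb of each other (on the corresponding
#' copy), only one -- chosen arbitrarily under a fixed seed -- is kept. A
#' candidate is dropped when its A-copy site lies within `radius` of a
#' retained pair's A-copy site, or its B-copy site within `radius` of a
#' retained B-copy site.
#'
#' @param pairs Table of discordant pairs.
#' @param radius Exclusion radius in bp (default 1000).
#' @param seed Seed fixing the arbitrary within-cluster choice.
#' @return The retained subset of `pairs`.
#' @export
dedupe_within_1kb <- function(pairs, radius = 1000, seed = 1) {
  n <- nrow(pairs)
  if (n <= 1) return(pairs)
  set.seed(seed)
  ord <- sample.int(n)
  kept <- integer(0)
  for (i in ord) {
    clash <- FALSE
    for (j in kept) {
      if ((pairs$chrom_a[i] == pairs$chrom_a[j] &&
           abs(pairs$pos_a[i] - pairs$pos_a[j]) < radius) ||
          (pairs$chrom_b[i] == pairs$chrom_b[j] &&
           abs(pairs$pos_b[i] - pairs$pos_b[j]) < radius)) {
        clash <- TRUE
        break
      }
    }
    if (!clash) kept <- c(kept, i)
  }
  pairs[sort(kept), , drop = FALSE]
}

#' Flanking sequence divergence versus methylation divergence
#'
#' Counts single-base substitutions (mismatched both-aligned columns) in
#' the alignment within `flank` bp either side of each pair's A-copy CpG,
#' truncating at the duplicated region's edge, then tests whether the
#' absolute methylation difference varies across substitution-count groups
#' (Kruskal-Wallis).
#'
#' @param pairs Pair table with `alignment_id`, `pos_a` and `abs_diff`.
#' @param alignments List of `duplicon_alignment` objects (ids matching
#'   `alignment_id`).
#' @param flank Flank size in bp either side of the CpG.
#' @return List with `per_pair` (the table plus `substitutions`) and
#'   `kruskal_p` (NA when fewer than two groups).
#' @export
sequence_divergence_association <- function(pairs, alignments, flank = 500) {
  ids <- vapply(alignments, function(a) a$id, character(1))
  subs <- vapply(seq_len(nrow(pairs)), function(i) {
    aln <- alignments[[match(pairs$alignment_id[i], ids)]]
    cols <- alignment_columns(aln)
    sel <- !is.na(cols$pos_a) &
      cols$pos_a >= pairs$pos_a[i] - flank &
      cols$pos_a <= pairs$pos_a[i] + 1L + flank
    sel <- sel & !is.na(cols$pos_b)
    sum(aln$chars_a[sel] != aln$chars_b[sel])
  }, numeric(1))
  pairs$substitutions <- as.integer(subs)
  grp <- factor(pairs$substitutions)
  kw <- if (nlevels(droplevels(grp)) >= 2) {
    kruskal.test(pairs$abs_diff, grp)$p.value
  } else {
    NA_real_
  }
  list(per_pair = pairs, kruskal_p = kw)
}

#' Attach upstream site-level filter flags to pairs
#'
#' Joins a site-flag table (`chrom`, `pos`, `alt_allele`,
#' `cytosine_evidence`) onto both members of each pair; sites absent from
#' the table default to no alternative allele and cytosine evidence
#' present.
#'
#' @param pairs Pair table.
#' @param flags Site-flag data frame (may be NULL or empty).
#' @return The pair table with `alt_allele_a/b` and
#'   `cytosine_evidence_a/b` columns.
#' @export
attach_site_flags <- function(pairs, flags) {
  n <- nrow(pairs)
  pairs$alt_allele_a <- pairs$alt_allele_b <- rep(FALSE, n)
  pairs$cytosine_evidence_a <- pairs$cytosine_evidence_b <- rep(TRUE, n)
  if (is.null(flags) || !nrow(flags)) return(pairs)
  key <- paste0(flags$chrom, ":", flags$pos)
  ia <- match(paste0(pairs$chrom_a, ":", pairs$pos_a), key)
  ib <- match(paste0(pairs$chrom_b, ":", pairs$pos_b), key)
  set_from <- function(cur, idx, col) {
    ifelse(is.na(idx), cur, flags[[col]][pmax(idx, 1)])
  }
  pairs$alt_allele_a <- set_from(pairs$alt_allele_a, ia, "alt_allele")
  pairs$alt_allele_b <- set_from(pairs$alt_allele_b, ib, "alt_allele")
  pairs$cytosine_evidence_a <- set_from(pairs$cytosine_evidence_a, ia, "cytosine_evidence")
  pairs$cytosine_evidence_b <- set_from(pairs$cytosine_evidence_b, ib, "cytosine_evidence")
  pairs
}
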