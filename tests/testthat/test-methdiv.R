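test_that("depth and annotation filters apply the published inclusion rules", {
  fx <- filter_fixture()
  res <- filter_pairs(fx$pairs, filter_policy(snps = fx$snps))
  expect_setequal(res$pairs$pair, fx$survivors)
  expect_equal(sum(res$rejected) + nrow(res$pairs), res$n_input)
  expect_equal(unname(res$rejected["low_depth"]), 3L)
  expect_equal(unname(res$rejected["high_total_depth"]), 3L)
  expect_equal(unname(res$rejected["snp_overlap"]), 4L)
  expect_equal(unname(res$rejected["alt_allele"]), 2L)
  expect_equal(unname(res$rejected["no_cytosine_evidence"]), 2L)
})

test_that("filters are monotone in the depth threshold", {
  set.seed(2)
  pairs <- simulate_pair_counts(300, seed = 2)
  retained <- vapply(1:15, function(k) {
    nrow(filter_pairs(pairs, filter_policy(min_depth_per_site = k,
                                           max_total_depth = 1000))$pairs)
  }, numeric(1))
  expect_true(all(diff(retained) <= 0))
})

test_that("discordance calls use a strict alpha and label the hyper copy", {
  pairs <- data.frame(
    chrom_a = "c", pos_a = 1:3, chrom_b = "c", pos_b = 1:3,
    meth_a = c(20, 5, 0), unmeth_a = c(0, 5, 20),
    meth_b = c(0, 5, 20), unmeth_b = c(20, 5, 0))
  tested <- test_discordance(pairs)
  # boundary: p exactly at alpha is not discordant
  tested$p_value <- c(4.9e-7, 5e-7, 1e-9)
  cls <- classify_discordant(tested)
  expect_equal(cls$discordant, c(TRUE, FALSE, TRUE))
  expect_equal(cls$hyper_copy, c("a", NA, "b"))
  # recomputed Bonferroni alpha at the published scale
  big <- tested[rep(1, 82692), ]
  cls2 <- classify_discordant(big, recompute_alpha = TRUE)
  expect_equal(attr(cls2, "alpha"), 0.05 / 82692)
  expect_true(abs(attr(cls2, "alpha") - 6.05e-7) < 2e-9)
  empty <- classify_discordant(tested[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("concordance summary reports the within-delta proportion and rho", {
  pairs <- data.frame(level_a = c(0.1, 0.5, 0.9), level_b = c(0.1, 0.5, 0.9))
  s <- concordance_summary(pairs)
  expect_equal(s$proportion_within_delta, 1)
  expect_equal(s$spearman_rho, 1)
  const <- data.frame(level_a = c(0.5, 0.5), level_b = c(0.5, 0.5))
  expect_true(is.na(concordance_summary(const)$spearman_rho))
  expect_error(concordance_summary(pairs[1, , drop = FALSE]), "at least 2")
  # deep sequencing of truly shared levels concentrates inside the band
  deep <- simulate_pair_counts(400, depth_mean = 5000, depth_dispersion = 0,
                               bb_dispersion = 0, seed = 8)
  deep <- test_discordance(deep)
  expect_gt(concordance_summary(deep)$proportion_within_delta, 0.99)
})

test_that("the permutation null is reproducible and extreme when pairing is real", {
  pairs <- test_discordance(simulate_pair_counts(300, depth_mean = 50, seed = 3))
  p1 <- permutation_null(pairs, n_perm = 100, seed = 10)
  p2 <- permutation_null(pairs, n_perm = 100, seed = 10)
  expect_identical(p1$perm_stats, p2$perm_stats)
  expect_equal(p1$p_value, 1 / 101)
  expect_error(permutation_null(pairs, n_perm = 0), "n_perm")
  # the alternative shuffling scheme runs and is also extreme here
  expect_equal(permutation_null(pairs, n_perm = 100, seed = 10,
                                scheme = "shuffle")$p_value, 1 / 101)
})

test_that("1-kb dedupe keeps one pair per clustered locus", {
  mk <- function(pa, pb) data.frame(chrom_a = "chr1", pos_a = pa,
                                    chrom_b = "chr2", pos_b = pb)
  close_pair <- rbind(mk(1000, 1000), mk(1500, 1500))
  expect_equal(nrow(dedupe_within_1kb(close_pair)), 1)
  far_pair <- rbind(mk(1000, 1000), mk(2500, 2500))
  expect_equal(nrow(dedupe_within_1kb(far_pair)), 2)
  # 53 pairs arranged in 32 well-separated clusters
  set.seed(6)
  centers <- seq(10000, by = 5000, length.out = 32)
  sizes <- c(rep(2, 21), rep(1, 11))  # 21*2 + 11 = 53
  pos <- unlist(lapply(seq_along(centers), function(i) {
    centers[i] + seq(0, by = 400, length.out = sizes[i])
  }))
  clustered <- mk(pos, pos)
  expect_equal(nrow(clustered), 53)
  expect_equal(nrow(dedupe_within_1kb(clustered, seed = 2)), 32)
})

test_that("flanking substitutions are counted within a truncated 500-bp window", {
  L <- 2000
  sa <- rep("A", L)
  sb <- sa
  # CpG at position 100 from the start (left flank truncates at the edge);
  # substitutions at +400 (counted) and +600 (outside the window)
  sb[100 + 1 + 400] <- "T"
  sb[100 + 1 + 600] <- "T"
  sb[50] <- "G"     # within the truncated left flank
  aln <- duplicon_alignment("chr1", 0, L, "chr2", 0, L, "+",
                            paste(sa, collapse = ""), paste(sb, collapse = ""),
                            identity = 0.99, id = "alnX")
  pairs <- data.frame(alignment_id = "alnX", chrom_a = "chr1", pos_a = 100L,
                      chrom_b = "chr2", pos_b = 100L, abs_diff = 0.1)
  res <- sequence_divergence_association(pairs, list(aln))
  expect_equal(res$per_pair$substitutions, 2L)
  expect_true(is.na(res$kruskal_p))  # a single group is untestable
  # identical flanks give zero substitutions
  aln0 <- duplicon_alignment("chr1", 0, L, "chr2", 0, L, "+",
                             paste(sa, collapse = ""), paste(sa, collapse = ""),
                             identity = 0.99, id = "alnX")
  expect_equal(sequence_divergence_association(pairs, list(aln0))$per_pair$substitutions, 0L)
})

test_that("site flags join onto both pair members", {
  pairs <- data.frame(chrom_a = "chr1", pos_a = c(10L, 20L),
                      chrom_b = "chr2", pos_b = c(10L, 20L))
  flags <- data.frame(chrom = c("chr1", "chr2"), pos = c(10L, 20L),
                      alt_allele = c(TRUE, FALSE),
                      cytosine_evidence = c(TRUE, FALSE))
  out <- attach_site_flags(pairs, flags)
  expect_equal(out$alt_allele_a, c(TRUE, FALSE))
  expect_equal(out$cytosine_evidence_b, c(TRUE, FALSE))
})
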