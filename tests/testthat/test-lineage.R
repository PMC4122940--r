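# hand-written chains: chr1 [0,10000) maps to out1 except a deletion at
# [4000,4300) (reference-specific insertion); chr2 maps fully
toy_chain <- function() {
  f <- tempfile(fileext = ".chain")
  writeLines(c(
    "chain 1000 chr1 10000 + 0 10000 out1 10000 + 0 9700 1",
    "4000 300 0",
    "5700",
    "",
    "chain 1000 chr2 10000 + 0 10000 out2 10000 + 0 10000 2",
    "10000",
    ""), f)
  read_chain(f)
}

test_that("ancestral assignment follows outgroup synteny", {
  f <- tempfile(fileext = ".chain")
  # chr1 and chr2 both carry a copy; both lift to out1 (chr2's copy through
  # a paralogy chain), so the chr1 copy is ancestral
  writeLines(c(
    "chain 1000 chr1 10000 + 0 10000 out1 10000 + 0 10000 1",
    "10000",
    "",
    "chain 1000 chr2 10000 + 2000 3000 out1 10000 + 2000 3000 2",
    "1000",
    ""), f)
  chain <- read_chain(f)
  synteny <- data.frame(chrom = c("chr1", "chr2"),
                        outgroup_chrom = c("out1", "out2"))
  pairs <- data.frame(chrom_a = "chr1", pos_a = 2500L,
                      chrom_b = "chr2", pos_b = 2500L)
  expect_equal(assign_ancestral_derived(pairs, chain, synteny), "a")
  # swapped labels give the mirrored answer
  sw <- data.frame(chrom_a = "chr2", pos_a = 2500L,
                   chrom_b = "chr1", pos_b = 2500L)
  expect_equal(assign_ancestral_derived(sw, chain, synteny), "b")
  # a copy that fails to lift is undetermined
  off <- data.frame(chrom_a = "chr1", pos_a = 2500L,
                    chrom_b = "chr2", pos_b = 8000L)
  expect_equal(assign_ancestral_derived(off, chain, synteny), "undetermined")
  intra <- data.frame(chrom_a = "chr1", pos_a = 1L, chrom_b = "chr1", pos_b = 2L)
  expect_error(assign_ancestral_derived(intra, chain, synteny),
               "interchromosomal")
})

test_that("ancestral assignment agrees with the generator's truth", {
  dir <- tempfile()
  b <- simulate_dataset(small_sim(seed = 11), dir)
  aln <- parse_duplication_alignments(b$paths$alignments)
  genome <- Biostrings::readDNAStringSet(b$paths$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  pairs <- find_paralogous_cpg_pairs(aln, genome)
  inter <- pairs[pairs$chrom_a != pairs$chrom_b, , drop = FALSE]
  chain <- read_chain(b$paths$chain_outgroup1)
  synteny <- data.table::fread(b$paths$synteny, data.table = FALSE)
  got <- assign_ancestral_derived(inter, chain, synteny)
  truth <- b$truth$ancestral
  want <- truth$ancestral[match(inter$alignment_id, truth$alignment_id)]
  det <- got != "undetermined"
  expect_gt(sum(det), 0)
  expect_gte(mean(got[det] == want[det]), 0.95)
})

test_that("insertion calls require absence in both outgroups plus flank synteny", {
  chain <- toy_chain()
  reps <- data.frame(
    chrom = c("chr1", "chr2"), start = c(4000L, 4000L), end = c(4300L, 4300L),
    name = c("AluY", "AluY"))
  # same chain for both outgroups: chr1 element absent in both, chr2 covered
  ev <- detect_lineage_specific_insertions(reps, chain, chain)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$chrom, "chr1")
  expect_equal(ev$family, "AluY")
  # covered in one outgroup: not lineage specific
  f2 <- tempfile(fileext = ".chain")
  writeLines(c("chain 1000 chr1 10000 + 0 10000 outX 10000 + 0 10000 1",
               "10000", ""), f2)
  full <- read_chain(f2)
  ev2 <- detect_lineage_specific_insertions(reps[1, ], chain, full)
  expect_equal(nrow(ev2), 0)
})

test_that("orthologous CpG matching enforces the per-species depth filter", {
  chain <- toy_chain()
  cov_x <- data.frame(chrom = "chr1", pos = c(1000L, 2000L, 3000L),
                      methylated_reads = c(5L, 2L, 4L),
                      unmethylated_reads = c(5L, 1L, 4L))
  # outgroup coordinates equal reference coordinates left of the deletion
  cov_y <- data.frame(chrom = "out1", pos = c(1000L, 2000L, 3000L),
                      methylated_reads = c(3L, 10L, 1L),
                      unmethylated_reads = c(3L, 10L, 1L))
  ortho <- match_orthologous_cpgs(cov_x, cov_y, chain, min_depth = 5)
  # site 2 fails the reference depth filter; site 3 fails the outgroup filter
  expect_equal(ortho$pos, 1000L)
  expect_equal(ortho$level_x, 0.5)
})

test_that("flanking profiles recover a planted exponential elevation", {
  set.seed(31)
  events <- data.frame(chrom = "chr1", start = seq(10000, by = 20000,
                                                   length.out = 15))
  events$end <- events$start + 300L
  n_per <- 120
  d <- runif(15 * n_per, 0, 2000)
  ev_i <- rep(seq_len(15), each = n_per)
  side <- sample(c(-1, 1), length(d), TRUE)
  pos <- ifelse(side < 0, events$start[ev_i] - d, events$end[ev_i] + d)
  base <- 0.3
  lx <- pmin(base + 0.2 * exp(-d / 300) + rnorm(length(d), 0, 0.03), 1)
  ly <- pmin(pmax(base + rnorm(length(d), 0, 0.03), 0), 1)
  ortho <- data.frame(chrom = "chr1", pos = round(pos),
                      level_x = pmax(lx, 0), level_y = ly)
  prof <- flanking_methylation_profile(events, ortho, window = 500,
                                       offset = 100, max_dist = 2000)
  mid <- (prof$dist_start + prof$dist_end) / 2
  truth_mean <- base + 0.2 * 300 / 500 * (exp(-prof$dist_start / 300) -
                                            exp(-prof$dist_end / 300))
  covered <- prof$ci_lo_x <= truth_mean & truth_mean <= prof$ci_hi_x
  expect_gte(mean(covered), 0.85)
  # elevation decays with distance in the insertion lineage only;
  # expected first-window elevation: 0.2 * (300/500) * (1 - exp(-500/300)) = 0.097
  expect_lt(cor(mid, prof$mean_x - prof$mean_y, method = "spearman"), -0.8)
  expect_gt(prof$mean_x[1] - prof$mean_y[1], 0.06)
  # empty window yields NA
  far <- flanking_methylation_profile(events, ortho[0, ], window = 500)
  expect_true(all(is.na(far$mean_x)))
})

test_that("the paired flank test matches a hand computation", {
  events <- data.frame(chrom = "chr1", start = 5000L, end = 5300L)
  ortho <- data.frame(chrom = "chr1", pos = 5300L + c(100L, 200L, 300L, 400L, 500L),
                      level_x = c(0.50, 0.62, 0.48, 0.71, 0.55),
                      level_y = c(0.41, 0.50, 0.45, 0.52, 0.49))
  res <- paired_flank_test(events, ortho)
  d <- ortho$level_x - ortho$level_y
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$n, 5)
  # identical levels: t = 0, p = 1
  same <- ortho; same$level_y <- same$level_x
  res0 <- paired_flank_test(events, same)
  expect_equal(res0$t, 0)
  expect_equal(res0$p_value, 1)
  # fewer than two flanking sites: NA
  expect_true(is.na(paired_flank_test(events, ortho[1, ])$p_value))
})

test_that("remodelled-site selection applies the low/gain thresholds", {
  events <- data.frame(chrom = "chr1", start = 1000L, end = 1300L)
  ortho <- data.frame(chrom = "chr1", pos = c(1500L, 1600L, 1700L, 9000L),
                      level_x = c(0.99, 0.50, 0.90, 0.99),
                      level_y = c(0.39, 0.39, 0.41, 0.10))
  sel <- select_remodeled_sites(ortho, events)
  expect_setequal(sel$background$pos, c(1500L, 1600L))  # distant site excluded
  expect_equal(sel$foreground$pos, 1500L)               # gain 0.6 satisfied
})

test_that("expression linkage tallies promoter-remodelled genes by sign", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      tss = c(1000L, 5000L, 50000L))
  fg <- data.frame(chrom = "chr1", pos = c(1500L, 4200L))
  expression <- data.frame(gene_id = c("g1", "g2", "g3"),
                           expr_x = c(1, 2, 3), expr_y = c(5, 9, 3))
  res <- expression_linkage(genes, fg, expression)
  expect_equal(res$n_lower, 2)
  expect_equal(res$n_higher, 0)
  expect_equal(res$p_value, 2 * 0.5^2)
  empty <- expression_linkage(genes, fg[0, ], expression)
  expect_equal(nrow(empty$genes), 0)
  expect_true(is.na(empty$p_value))
})
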