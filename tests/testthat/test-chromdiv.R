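gapfree_aln <- function(L = 2000, start_a = 0, start_b = 10000,
                        chrom_a = "chr1", chrom_b = "chr2", strand_b = "+") {
  s <- strrep("A", L)
  duplicon_alignment(chrom_a, start_a, start_a + L,
                     chrom_b, start_b, start_b + L, strand_b, s, s,
                     identity = 0.99, id = "alnW")
}

test_that("window tiling masks positions jointly mappable in both copies", {
  aln <- gapfree_aln()
  full <- data.frame(chrom = c("chr1", "chr2"), start = 0L, end = 100000L)
  wp <- make_window_pairs(aln, full)
  expect_equal(nrow(wp$windows), 4)
  expect_equal(wp$windows$mask_size, rep(500L, 4))

  # a position unmappable only in copy b is dropped from the mask of both
  holed <- rbind(data.frame(chrom = "chr1", start = 0L, end = 100000L),
                 data.frame(chrom = "chr2", start = c(0L, 10100L),
                            end = c(10050L, 100000L)))
  wp2 <- make_window_pairs(aln, holed)
  expect_equal(wp2$windows$mask_size, c(450L, 500L, 500L, 500L))
  expect_false(any(wp2$mask$pos_b %in% 10050:10099))

  # gap columns never enter the mask
  sa <- paste0(strrep("A", 600), strrep("-", 100), strrep("A", 500))
  sb <- paste0(strrep("A", 1050), strrep("-", 50), strrep("A", 100))
  galn <- duplicon_alignment("chr1", 0, 1100, "chr2", 0, 1150, "+", sa, sb,
                             identity = 0.99)
  wp3 <- make_window_pairs(galn, full)
  expect_equal(nrow(wp3$windows), 2)   # trailing partial window dropped
  expect_equal(wp3$windows$mask_size[2], 450L)  # 50 columns gapped in a's window
})

test_that("read counting conserves totals and follows the 5' rule", {
  aln <- gapfree_aln(L = 1000)
  full <- data.frame(chrom = c("chr1", "chr2"), start = 0L, end = 100000L)
  wp <- make_window_pairs(aln, full)
  set.seed(5)
  pos_a <- sample(0:999, 120, replace = TRUE)
  pos_b <- 10000 + sample(0:999, 80, replace = TRUE)
  reads <- rbind(
    data.frame(chrom = "chr1", start = pos_a, end = pos_a + 35L, strand = "+"),
    # minus-strand reads: 5' end is end - 1
    data.frame(chrom = "chr2", start = pos_b - 34L, end = pos_b + 1L, strand = "-"))
  win <- count_window_reads(wp, reads)
  expect_equal(sum(win$count_a), 120)
  expect_equal(sum(win$count_b), 80)
  expect_equal(win$count_a, as.vector(table(cut(pos_a, seq(0, 1000, 500)))))
})

test_that("window discordance needs Bonferroni significance AND a zero copy", {
  win <- data.frame(window_id = sprintf("w%d", 1:4),
                    count_a = c(7L, 10L, 40L, 0L), count_b = c(7L, 0L, 2L, 0L))
  win <- test_window_discordance(win)
  expect_equal(win$p_value[1], 1)
  expect_equal(win$p_value[2], 2 * 0.5^10, tolerance = 1e-12)
  expect_true(is.na(win$p_value[4]))
  cls <- classify_discordant_windows(win)
  # (40, 2) is highly significant but has no zero copy: never discordant
  expect_lt(cls$p_adjusted[3], 0.05)
  expect_false(cls$discordant[3])
  expect_true(cls$discordant[2])
  expect_false(cls$discordant[1])
})

test_that("masking and the binomial p are symmetric under copy swap", {
  aln <- gapfree_aln(L = 1500)
  mapp <- rbind(data.frame(chrom = "chr1", start = c(0L, 300L), end = c(250L, 100000L)),
                data.frame(chrom = "chr2", start = 0L, end = 100000L))
  swapped <- duplicon_alignment("chr2", 10000, 11500, "chr1", 0, 1500, "+",
                                strrep("A", 1500), strrep("A", 1500),
                                identity = 0.99)
  m1 <- make_window_pairs(aln, mapp)
  m2 <- make_window_pairs(swapped, mapp)
  expect_equal(m1$windows$mask_size, m2$windows$mask_size)
  expect_equal(binom_exact_p(13, 20), binom_exact_p(7, 20))
})

test_that("flanking read depth separates hyper and hypo copies when planted", {
  set.seed(12)
  n <- 50
  pairs <- data.frame(
    chrom_a = "chr1", pos_a = seq(5000, by = 3000, length.out = n),
    chrom_b = "chr2", pos_b = seq(5000, by = 3000, length.out = n),
    hyper_copy = "a")
  # 10x enrichment at the hypo copies (copy b)
  reads <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- rpois(1, 10); na <- rpois(1, 1)
    rbind(
      if (na > 0) data.frame(chrom = "chr1",
                             start = pairs$pos_a[i] + sample(-400:400, na, TRUE),
                             end = 0L, strand = "+") else NULL,
      if (nb > 0) data.frame(chrom = "chr2",
                             start = pairs$pos_b[i] + sample(-400:400, nb, TRUE),
                             end = 0L, strand = "+") else NULL)
  }))
  reads$end <- reads$start + 35L
  res <- flanking_read_profile(pairs, reads)
  expect_lt(res$p_value, 0.01)
  expect_gt(mean(res$per_pair$count_hypo), mean(res$per_pair$count_hyper))

  # no reads anywhere: undefined test
  empty <- flanking_read_profile(pairs, reads[0, ])
  expect_true(is.na(empty$p_value))
  # identical placement at both copies: no signal
  same <- data.frame(chrom = rep(c("chr1", "chr2"), each = n),
                     start = c(pairs$pos_a, pairs$pos_b), strand = "+")
  same$end <- same$start + 35L
  expect_equal(flanking_read_profile(pairs, same)$p_value, 1)
})
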