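test_that("point-to-feature distances match a brute-force oracle", {
  track <- data.frame(chrom = "chr1", start = c(500L, 2000L), end = c(600L, 2400L))
  expect_equal(distance_to_nearest("chr1", 550L, track), 0)
  expect_equal(distance_to_nearest("chr1", 400L, track), 100)
  expect_equal(distance_to_nearest("chr1", 700L, track), 101)  # past end 600
  expect_true(is.na(distance_to_nearest("chr2", 100L, track)))
  # fuzz against the quadratic all-pairs oracle
  set.seed(17)
  for (rep in 1:10) {
    trk <- data.frame(chrom = "c",
                      start = sort(sample(0:5000, 15)))
    trk$end <- trk$start + sample(1:100, 15, TRUE)
    pos <- sample(0:5200, 60)
    got <- distance_to_nearest(rep("c", 60), pos, trk)
    want <- vapply(pos, function(p) {
      min(vapply(seq_len(nrow(trk)), function(i) {
        if (p >= trk$start[i] && p < trk$end[i]) 0
        else min(abs(p - trk$start[i]), abs(p - (trk$end[i] - 1)))
      }, numeric(1)))
    }, numeric(1))
    expect_equal(got, want)
  }
})

test_that("island/shore/open-sea classes partition sites with a strict 2-kb bound", {
  islands <- data.frame(chrom = "chr1", start = 10000L, end = 11000L)
  pos <- c(10500L, 11000L + 1998L, 11000L + 1999L, 8001L, 5000L)
  cls <- classify_island_shore("chr1", pos, islands)
  # distance of the last island base (10999) to 12998 is 1999 -> shore;
  # to 12999 is 2000 -> open sea
  expect_equal(cls, c("island", "shore", "open_sea", "shore", "open_sea"))
  expect_true(all(cls %in% c("island", "shore", "open_sea")))
})

test_that("repeat-class proximity testing detects a planted Alu bias", {
  set.seed(23)
  n <- 30
  hyper_pos <- seq(10000, by = 5000, length.out = n)
  pairs <- data.frame(chrom_a = "chr1", pos_a = hyper_pos,
                      chrom_b = "chr2", pos_b = hyper_pos,
                      hyper_copy = "a")
  repeats <- rbind(
    data.frame(chrom = "chr1", start = hyper_pos + 50L,
               end = hyper_pos + 350L, name = "Alu"),            # near hyper
    data.frame(chrom = "chr2", start = hyper_pos + sample(800:2000, n),
               end = hyper_pos + 2400L, name = "Alu"),           # far from hypo
    data.frame(chrom = c("chr1", "chr2"), start = 1L, end = 50L, name = "L1"))
  res <- repeat_proximity_test(pairs, repeats)
  alu <- res[res$class == "Alu", ]
  expect_lt(alu$p_value, 0.05)
  expect_lt(alu$median_hyper, alu$median_hypo)
  # class absent from the track
  res2 <- repeat_proximity_test(pairs, repeats, classes = c("Alu", "LTR"))
  expect_true(is.na(res2$p_value[res2$class == "LTR"]))
  # identical distances at both copies give p = 1
  sym <- repeat_proximity_test(
    pairs,
    rbind(data.frame(chrom = "chr1", start = hyper_pos + 100L,
                     end = hyper_pos + 200L, name = "Alu"),
          data.frame(chrom = "chr2", start = hyper_pos + 100L,
                     end = hyper_pos + 200L, name = "Alu")))
  expect_equal(sym$p_value, 1)
})

test_that("junction distances compare groups with a Mann-Whitney test", {
  dup <- data.frame(chrom = "chr1", start = 1000L, end = 3000L)
  disc <- data.frame(chrom = "chr1", pos = c(1000L, 1500L))
  conc <- data.frame(chrom = "chr1", pos = c(2000L, 2900L, 1100L))
  res <- junction_distance_test(disc, conc, dup)
  expect_equal(res$median_discordant, 250)   # distances 0 and 500
  expect_false(is.na(res$p_value))
  single <- junction_distance_test(disc[1, , drop = FALSE],
                                   conc[1, , drop = FALSE], dup)
  expect_false(is.na(single$p_value))
  empty <- junction_distance_test(disc[0, , drop = FALSE], conc, dup)
  expect_true(is.na(empty$p_value))
})

test_that("TSS distance tables report the distal fraction of discordant pairs", {
  tss <- data.frame(chrom = "chr1", tss = c(10000L, 90000L))
  pairs <- data.frame(chrom_a = "chr1", pos_a = c(10100L, 50000L),
                      chrom_b = "chr1", pos_b = c(10200L, 52000L),
                      discordant = c(FALSE, TRUE))
  res <- tss_distance_table(pairs, tss)
  expect_equal(res$table$dist_a, c(100, 40000))
  expect_equal(res$fraction_discordant_distal, 1)
  empty <- tss_distance_table(pairs[0, ], tss)
  expect_equal(nrow(empty$table), 0)
  expect_true(is.na(empty$fraction_discordant_distal))
})

test_that("flank FASTA export round-trips against the genome", {
  set.seed(41)
  g <- make_genome(chr1 = paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                                collapse = ""))
  sites <- data.frame(chrom = "chr1", pos = c(1500L, 100L),
                      group = c("hyper", "hyper"))
  dir <- tempfile()
  paths <- export_flank_fasta(sites, g, flank = 500, out_dir = dir)
  seqs <- Biostrings::readDNAStringSet(paths[["hyper"]])
  expect_equal(Biostrings::width(seqs), c(1001L, 601L))
  expect_match(names(seqs)[2], "truncated")
  expect_equal(as.character(seqs[[1]]),
               as.character(Biostrings::subseq(g[["chr1"]], 1001, 2001)))
  expect_equal(as.character(seqs[[2]]),
               as.character(Biostrings::subseq(g[["chr1"]], 1, 601)))
})
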