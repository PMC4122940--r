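test_that("parser handles a gap-free identical duplicon pair", {
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  f <- tempfile()
  writeLines(c(">chr1:100-2100 + chr2:5000-7000 + 1.0", s, s), f)
  aln <- parse_duplication_alignments(f)
  expect_length(aln, 1)
  expect_equal(aln[[1]]$empirical_identity, 1.0)
  expect_length(aln[[1]]$chars_a, 2000)
})

test_that("parser enforces the segmental-duplication inclusion rule", {
  s <- strrep("ACGT", 500)  # 2000 bp
  short <- strrep("ACGT", 200)  # 800 bp
  f <- tempfile()
  writeLines(c(
    ">chr1:0-2000 + chr2:0-2000 + 0.95", s, s,
    ">chr1:3000-3800 + chr2:3000-3800 + 0.95", short, short,
    ">chr1:6000-8000 + chr2:6000-8000 + 0.85", s, s
  ), f)
  expect_warning(expect_warning(aln <- parse_duplication_alignments(f),
                                "<= 1000 bp"), "identity")
  expect_length(aln, 1)
})

test_that("gap columns project to NA and offsets project colinearly", {
  # 10-bp gap in copy b
  sa <- strrep("A", 30)
  sb <- paste0(strrep("A", 10), strrep("-", 10), strrep("A", 10))
  aln <- duplicon_alignment("chr1", 100, 130, "chr1", 500, 520, "+", sa, sb,
                            identity = 0.99)
  p <- project_position(aln, 100:129, from = "a")
  expect_true(all(is.na(p[11:20])))
  expect_equal(p[1:10], 500:509)
  expect_equal(p[21:30], 510:519)
  expect_equal(sum(is.na(p)), 10)
  expect_error(project_position(aln, 99, from = "a"), "outside")
})

test_that("inverted gap-free projection follows the reflection formula", {
  L <- 40
  sa <- strrep("A", L)
  sb <- strrep("T", L)
  aln <- duplicon_alignment("chr1", 100, 100 + L, "chr2", 900, 900 + L, "-",
                            sa, sb, identity = 0.99)
  pos <- 100:(100 + L - 1)
  expect_equal(project_position(aln, pos, from = "a"),
               900L + (100L + L - 1L - pos))
})

test_that("projection is an involution and matches the scanning oracle", {
  set.seed(42)
  for (i in 1:20) {
    aln <- random_gapped_alignment(n_cols = 120, inverted = i %% 2 == 0)
    pos_a <- aln$start_a:(aln$end_a - 1)
    fwd <- project_position(aln, pos_a, from = "a")
    ok <- !is.na(fwd)
    back <- project_position(aln, fwd[ok], from = "b")
    expect_equal(back, pos_a[ok])
    # spot-check against the character-scanning oracle
    spots <- sample(pos_a, 10)
    expect_equal(project_position(aln, spots, from = "a"),
                 vapply(spots, function(p) {
                   v <- oracle_project(aln, p, "a")
                   if (is.null(v)) NA_integer_ else as.integer(v)
                 }, integer(1)))
  }
})

test_that("CpG pair enumeration requires the dinucleotide in both copies", {
  pad <- strrep("A", 600)
  core <- "TTCGTTACGTTTTCGAA"  # CpGs at offsets 2, 7, 13
  g <- make_genome(chr1 = paste0(pad, core, pad),
                   chr2 = paste0(pad, core, pad))
  aln <- duplicon_alignment("chr1", 0, nchar(pad) * 2 + nchar(core),
                            "chr2", 0, nchar(pad) * 2 + nchar(core), "+",
                            paste0(pad, core, pad), paste0(pad, core, pad),
                            identity = 0.99, id = "aln0001")
  pairs <- find_paralogous_cpg_pairs(list(aln), g)
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$pos_a, pairs$pos_b)
  expect_setequal(pairs$pos_a, 600 + c(2, 7, 13))

  # C->T in copy b destroys the middle pair
  core_mut <- sub("ACG", "ATG", core)
  g2 <- make_genome(chr1 = paste0(pad, core, pad),
                    chr2 = paste0(pad, core_mut, pad))
  aln2 <- duplicon_alignment("chr1", 0, nchar(pad) * 2 + nchar(core),
                             "chr2", 0, nchar(pad) * 2 + nchar(core), "+",
                             paste0(pad, core, pad), paste0(pad, core_mut, pad),
                             identity = 0.99, id = "aln0001")
  pairs2 <- find_paralogous_cpg_pairs(list(aln2), g2)
  expect_equal(nrow(pairs2), 2)
  expect_false((600 + 7) %in% pairs2$pos_a)
})

test_that("CpG pairing handles inverted copies (CG is its own complement)", {
  core <- "TTTCGTTTTTTACGTTT"
  len <- nchar(core)
  g <- make_genome(chr1 = paste0(core, strrep("A", 300)),
                   chr2 = paste0(strrep("A", 100), rc(core), strrep("A", 300)))
  # copy b is the reverse complement of copy a: the oriented b sequence
  # equals the a sequence, and the relative strand is "-"
  aln <- duplicon_alignment("chr1", 0, len, "chr2", 100, 100 + len, "-",
                            core, core, identity = 0.99, id = "aln0001")
  pairs <- find_paralogous_cpg_pairs(list(aln), g)
  expect_equal(nrow(pairs), 2)
  # every reported b site carries CG on its own plus strand
  for (i in seq_len(nrow(pairs))) {
    din <- substr(as.character(g[["chr2"]]), pairs$pos_b[i] + 1,
                  pairs$pos_b[i] + 2)
    expect_equal(din, "CG")
  }
})

test_that("pair enumeration is symmetric in the two copies", {
  set.seed(9)
  pad1 <- paste(sample(c("A", "T"), 600, TRUE), collapse = "")
  pad2 <- paste(sample(c("A", "T"), 600, TRUE), collapse = "")
  core <- "AACGTTTTCGAA"
  sa <- paste0(pad1, core, pad1)
  sb <- paste0(pad2, core, pad2)
  # align only the identical core, with pads as flanks outside the duplicon
  g <- make_genome(chr1 = sa, chr2 = sb)
  aln_ab <- duplicon_alignment("chr1", 600, 612, "chr2", 600, 612, "+",
                               core, core, identity = 0.99, id = "x")
  aln_ba <- duplicon_alignment("chr2", 600, 612, "chr1", 600, 612, "+",
                               core, core, identity = 0.99, id = "x")
  expect_warning(pa <- find_paralogous_cpg_pairs(list(aln_ab), g), NA)
  pb <- find_paralogous_cpg_pairs(list(aln_ba), g)
  expect_setequal(paste(pa$pos_a, pa$pos_b), paste(pb$pos_b, pb$pos_a))
})

test_that("the synthetic bundle's alignments and pairs round-trip", {
  dir <- tempfile()
  b <- simulate_dataset(small_sim(seed = 5), dir)
  aln <- parse_duplication_alignments(b$paths$alignments)
  expect_length(aln, 10)
  genome <- Biostrings::readDNAStringSet(b$paths$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  pairs <- find_paralogous_cpg_pairs(aln, genome)
  # all truth discordant pairs are recoverable
  expect_true(all(b$truth$discordant_pair_ids %in% pairs$pair_id))
  # empirical identity close to the configured identity
  emp <- vapply(aln, function(a) a$empirical_identity, numeric(1))
  expect_true(all(abs(emp - 0.97) < 0.015))
})
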