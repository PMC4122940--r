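# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written from first principles (explicit enumeration with
# choose(), character scanning) so they share no code path with the
# implementations they check.

## ---- exact-test oracles ---------------------------------------------------

# brute-force two-sided Fisher p: enumerate every table with the observed
# margins, probability from binomial coefficients
oracle_fisher_p <- function(a, b, c, d, tol = 1e-7) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  xs <- max(0, c1 - r2):min(c1, r1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  sum(probs[probs <= probs[xs == a] * (1 + tol)])
}

# brute-force two-sided binomial p at prob 0.5
oracle_binom_p <- function(x, n, tol = 1e-7) {
  probs <- choose(n, 0:n) / 2^n
  sum(probs[probs <= probs[x + 1] * (1 + tol)])
}

## ---- alignment fixtures ---------------------------------------------------

rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# random gapped (optionally inverted) duplicon alignment; coordinates are
# arbitrary but internally consistent
random_gapped_alignment <- function(n_cols = 300, inverted = FALSE,
                                    gap_prob = 0.08, mismatch_prob = 0.05,
                                    start_a = 1000, start_b = 50000,
                                    chrom_a = "chr1", chrom_b = "chr2") {
  state <- sample(c("m", "ga", "gb"), n_cols, replace = TRUE,
                  prob = c(1 - 2 * gap_prob, gap_prob, gap_prob))
  base_a <- sample(c("A", "C", "G", "T"), n_cols, replace = TRUE)
  base_b <- ifelse(runif(n_cols) < mismatch_prob,
                   sample(c("A", "C", "G", "T"), n_cols, replace = TRUE),
                   base_a)
  ca <- ifelse(state == "ga", "-", base_a)
  cb <- ifelse(state == "gb", "-", base_b)
  duplicon_alignment(
    chrom_a, start_a, start_a + sum(ca != "-"),
    chrom_b, start_b, start_b + sum(cb != "-"),
    strand_b = if (inverted) "-" else "+",
    seq_a = paste(ca, collapse = ""),
    seq_b = paste(cb, collapse = ""),
    identity = 0.99
  )
}

# independent projection oracle: character scanning over the gapped strings
oracle_project <- function(aln, pos, from = "a") {
  sa <- if (from == "a") aln$chars_a else aln$chars_b
  sb <- if (from == "a") aln$chars_b else aln$chars_a
  if (from == "a") {
    lo_s <- aln$start_a
    minus_src <- FALSE
  } else {
    lo_s <- aln$start_b
    minus_src <- aln$strand_b == "-"
  }
  # column index holding the pos-th non-gap character of the source
  k <- if (minus_src) {
    # source sequence runs along the minus strand: first char is end-1
    (if (from == "b") aln$end_b else aln$end_a) - pos
  } else {
    pos - lo_s + 1L
  }
  cnt <- 0L
  col <- NA_integer_
  for (i in seq_along(sa)) {
    if (sa[i] != "-") {
      cnt <- cnt + 1L
      if (cnt == k) { col <- i; break }
    }
  }
  if (is.na(col) || sb[col] == "-") return(NA_integer_)
  nb <- sum(sb[seq_len(col)] != "-")
  if (from == "a") {
    if (aln$strand_b == "+") aln$start_b + nb - 1L else aln$end_b - nb
  } else {
    aln$start_a + nb - 1L
  }
}

## ---- misc -----------------------------------------------------------------

make_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(unname(seqs))
  names(g) <- names(seqs)
  g
}

# small but complete bundle configuration used across integration tests
small_sim <- function(seed = 1, ...) {
  sim_config(n_chromosomes = 2, chrom_length = 300000, n_duplicons = 10,
             n_planted_discordant = 6, n_planted_insertions = 8,
             n_shared_repeats = 8, n_remodeled = 4, n_background_cpg = 600,
             n_flank_cpg_per_insertion = 15, n_genes = 20,
             n_snp_pairs = 2, n_alt_pairs = 2, n_nocyto_pairs = 2,
             n_planted_windows = 4, seed = seed, ...)
}

write_test_chain <- function(path, header, blocks) {
  writeLines(c(header, blocks, ""), path)
  path
}

# the 20-pair filter fixture: rows 1-6 are the designed survivors
filter_fixture <- function() {
  mk <- function(i, ma, ua, mb, ub, alt_a = FALSE, alt_b = FALSE,
                 cyt_a = TRUE, cyt_b = TRUE) {
    data.frame(pair = as.integer(i), chrom_a = "chr1", pos_a = 1000L * i,
               chrom_b = "chr2", pos_b = 1000L * i,
               meth_a = ma, unmeth_a = ua, meth_b = mb, unmeth_b = ub,
               alt_allele_a = alt_a, alt_allele_b = alt_b,
               cytosine_evidence_a = cyt_a, cytosine_evidence_b = cyt_b)
  }
  pairs <- rbind(
    mk(1, 3, 3, 10, 10),                    # clean
    mk(2, 25, 25, 25, 25),                  # total exactly 100: retained
    mk(3, 6, 0, 0, 6),                      # depth exactly 6: retained
    mk(4, 10, 5, 8, 4),
    mk(5, 0, 10, 10, 0),
    mk(6, 30, 10, 20, 10),
    mk(7, 2, 3, 10, 10),                    # depth 5 at copy a
    mk(8, 10, 10, 3, 2),                    # depth 5 at copy b
    mk(9, 1, 1, 1, 1),                      # both shallow
    mk(10, 30, 30, 25, 26),                 # total 111
    mk(11, 60, 0, 0, 50),                   # total 110
    mk(12, 50, 10, 30, 11),                 # total 101: rejected
    mk(13, 10, 10, 10, 10),                 # SNP on the C of copy a
    mk(14, 10, 10, 10, 10),                 # SNP on the left flank of copy a
    mk(15, 10, 10, 10, 10),                 # SNP on the right flank of copy b
    mk(16, 10, 10, 10, 10, alt_a = TRUE),
    mk(17, 10, 10, 10, 10, alt_b = TRUE),
    mk(18, 10, 10, 10, 10, cyt_a = FALSE),
    mk(19, 10, 10, 10, 10, cyt_b = FALSE),
    mk(20, 10, 10, 10, 10)                  # SNP on the C of copy b
  )
  snps <- data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(13000L, 14000L - 1L, 15000L + 1L, 20000L),
    end = c(13001L, 14000L, 15000L + 2L, 20001L)
  )
  list(pairs = pairs, snps = snps, survivors = 1:6)
}
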