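#!/usr/bin/env Rscript
# Chromatin divergence between duplicon copies: mappability-masked 500-bp
# window read counts with binomial discordance calls per mark, and the
# SP1-like flanking read-depth contrast at discordant CpG pairs.
# Reads results/data and results/discordant_pairs.tsv (from 02); writes
# results/windows_<mark>.tsv.

suppressMessages(library(paradiverge))

aln <- parse_duplication_alignments("results/data/duplicon_alignments.txt")
mapp <- read_bed("results/data/mappability.bed")

for (mark in c("H3K4me3", "DNase")) {
  reads <- read_bed(sprintf("results/data/reads_%s.bed", mark))
  win <- do.call(rbind, lapply(aln, function(a) {
    count_window_reads(make_window_pairs(a, mapp), reads)
  }))
  win <- classify_discordant_windows(test_window_discordance(win))
  message(sprintf("%s: %d/%d testable windows discordant (one-copy loss)",
                  mark, sum(win$discordant), sum(!is.na(win$p_value))))
  write.table(win, sprintf("results/windows_%s.tsv", mark), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

disc <- read.delim("results/discordant_pairs.tsv")
sp1 <- read_bed("results/data/reads_SP1.bed")
fl <- flanking_read_profile(disc, sp1)
message(sprintf("SP1-like reads around hypo vs hyper copies: median %d vs %d, paired p = %.2g",
                median(fl$per_pair$count_hypo), median(fl$per_pair$count_hyper),
                fl$p_value))
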