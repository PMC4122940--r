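#!/usr/bin/env Rscript
# Genomic context of discordant sites: CpG island/shore classes, TSS
# distances, duplicon-junction proximity, per-class repeat proximity, and
# the flank FASTA export for motif discovery.
# Reads results/data, results/pair_table.tsv, results/discordant_pairs.tsv;
# writes results/tss_distances.tsv and results/discordant_flanks_*.fa.

suppressMessages(library(paradiverge))

pairs <- read.delim("results/pair_table.tsv")
disc <- read.delim("results/discordant_pairs.tsv")
islands <- read_bed("results/data/cpg_islands.bed")
genes <- data.table::fread("results/data/genes.tsv", data.table = FALSE)
duplicons <- read_bed("results/data/duplicons.bed")
repeats <- read_bed("results/data/repeats.bed")

sites <- data.frame(chrom = c(disc$chrom_a, disc$chrom_b),
                    pos = c(disc$pos_a, disc$pos_b))
cls <- table(classify_island_shore(sites$chrom, sites$pos, islands))
message("discordant site classes: ",
        paste(names(cls), cls, collapse = ", "))

tss <- tss_distance_table(pairs, genes)
message(sprintf("%.0f%% of discordant pairs have both copies > 1 kb from a TSS",
                100 * tss$fraction_discordant_distal))
write.table(tss$table, "results/tss_distances.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

conc <- pairs[!pairs$discordant, ]
jct <- junction_distance_test(
  sites, data.frame(chrom = c(conc$chrom_a, conc$chrom_b),
                    pos = c(conc$pos_a, conc$pos_b)), duplicons)
message(sprintf("junction distance: discordant median %d, concordant median %d (p = %.2f)",
                jct$median_discordant, jct$median_concordant, jct$p_value))

rpt <- repeat_proximity_test(disc, repeats)
for (i in seq_len(nrow(rpt))) {
  message(sprintf("  %s: hyper median %.0f vs hypo median %.0f (paired p = %.3g)",
                  rpt$class[i], rpt$median_hyper[i], rpt$median_hypo[i],
                  rpt$p_value[i]))
}

genome <- Biostrings::readDNAStringSet("results/data/genome.fa")
names(genome) <- sub("\\s.*", "", names(genome))
hyper_is_a <- disc$hyper_copy == "a"
fa <- export_flank_fasta(
  data.frame(chrom = c(ifelse(hyper_is_a, disc$chrom_a, disc$chrom_b),
                       ifelse(hyper_is_a, disc$chrom_b, disc$chrom_a)),
             pos = c(ifelse(hyper_is_a, disc$pos_a, disc$pos_b),
                     ifelse(hyper_is_a, disc$pos_b, disc$pos_a)),
             group = rep(c("hyper", "hypo"), each = nrow(disc))),
  genome, out_dir = "results", prefix = "discordant_flanks")
message("flank FASTA for motif discovery: ", paste(fa, collapse = ", "))
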