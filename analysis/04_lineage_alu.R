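#!/usr/bin/env Rscript
# Cross-species analyses: ancestral/derived assignment through the outgroup
# chain, lineage-specific Alu insertion detection, flanking methylation
# profiles and the paired flank test, remodelled-site selection and the
# expression linkage.
# Reads results/data and results/pair_table.tsv; writes
# results/flanking_profile.tsv and results/insertions.tsv.

suppressMessages(library(paradiverge))

chain1 <- read_chain("results/data/outgroup1.chain")
chain2 <- read_chain("results/data/outgroup2.chain")
synteny <- data.table::fread("results/data/synteny.tsv", data.table = FALSE)

pairs <- read.delim("results/pair_table.tsv")
inter <- pairs[pairs$chrom_a != pairs$chrom_b, ]
anc <- assign_ancestral_derived(inter, chain1, synteny)
message(sprintf("ancestral/derived determined for %d/%d interchromosomal pairs",
                sum(anc != "undetermined"), nrow(inter)))

repeats <- read_bed("results/data/repeats.bed")
events <- detect_lineage_specific_insertions(repeats, chain1, chain2)
message(sprintf("%d lineage-specific insertions (%s)", nrow(events),
                paste(names(table(events$family)), table(events$family),
                      collapse = ", ")))
write.table(events, "results/insertions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

covh <- combine_strand_counts(read_coverage("results/data/coverage_brain_human.tsv"))
covo <- combine_strand_counts(read_coverage("results/data/coverage_brain_outgroup.tsv"))
ortho <- match_orthologous_cpgs(covh, covo, chain1)
prof <- flanking_methylation_profile(events, ortho)
write.table(prof, "results/flanking_profile.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
pt <- paired_flank_test(events, ortho)
message(sprintf("flanking methylation elevated by %.3f within 1 kb of insertions (paired t p = %.2g, n = %d)",
                pt$mean_diff, pt$p_value, pt$n))

remod <- select_remodeled_sites(ortho, events)
message(sprintf("%d low-outgroup-methylation flank sites; %d remodelled (gain >= 0.6)",
                nrow(remod$background), nrow(remod$foreground)))

genes <- data.table::fread("results/data/genes.tsv", data.table = FALSE)
exprs <- data.table::fread("results/data/expression.tsv", data.table = FALSE)
link <- expression_linkage(genes, remod$foreground, exprs)
message(sprintf("genes with remodelled promoters: %d lower / %d higher in the insertion lineage (sign test p = %.3g)",
                link$n_lower, link$n_higher, link$p_value))
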