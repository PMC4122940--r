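#!/usr/bin/env Rscript
# Generate the synthetic study bundle with planted ground truth.
# Writes results/data/ (genome, alignments, coverage, tracks, chains, truth).

suppressMessages(library(paradiverge))

seed <- 1L
cfg <- sim_config(seed = seed)
bundle <- simulate_dataset(cfg, "results/data")

truth <- bundle$truth
message(sprintf("bundle written to results/data (seed %d):", seed))
message(sprintf("  %d duplicons, %d paralogous CpG pairs", truth$n_duplicons,
                truth$n_pairs))
message(sprintf("  %d planted discordant pairs, %d planted Alu insertions per lineage",
                length(truth$discordant_pair_ids),
                nrow(truth$insertions_human)))
message(sprintf("  %d planted one-copy chromatin losses per mark",
                sum(truth$planted_windows$mark == truth$planted_windows$mark[1])))
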