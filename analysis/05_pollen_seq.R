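#!/usr/bin/env Rscript
# Step 5: classify crossover read pairs from the pooled crossover-molecule
# sequencing library through the exact-match filter cascade, and build the
# normalized, cM-weighted per-base recombination profile.

suppressPackageStartupMessages(library(panxo))

sim <- "results/sim"
pm <- read_key_table("results/panmolecule_key.csv")
gd <- read.delim("results/genetic_distance.tsv")
cm_wt <- gd$cM[gd$genotype == "wt"]

pairs <- read_fastq_pairs(file.path(sim, "crossover_reads_1.fastq"),
                          file.path(sim, "crossover_reads_2.fastq"))
cat(sprintf("classifying %d read pairs...\n", nrow(pairs)))
# the synthetic amplification orientation puts parent A at the lower
# pan coordinate of each crossover molecule
res <- classify_pairs(pairs, pm, lower_parent = "A")
print(res$ledger)

ledger_df <- data.frame(stage = names(res$ledger),
                        read_pairs = unname(unclass(res$ledger)))
write.table(ledger_df, "results/filter_ledger.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(res$pairs, "results/crossover_read_pairs.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

raw <- accumulate_coverage(res$pairs, pm)
prof <- normalize_profile(raw, nrow(res$pairs), cm_wt)
write.table(as.data.frame(prof), "results/coverage_profile.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

fl <- fragment_length_histogram(res$pairs)
cat(sprintf("accepted crossover pairs: %d; fragment span mean %.1f bp (sd %.1f)\n",
            fl$n, fl$mean, fl$sd))
write.table(fl$histogram, "results/fragment_lengths.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("wrote filter ledger, crossover pairs, coverage profile, fragment histogram\n")
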