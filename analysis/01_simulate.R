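#!/usr/bin/env Rscript
# Step 1: generate the synthetic pollen-typing study.
#
# Emulates the measured experiment at one hotspot locus: a ~9.5 kb amplicon
# with ~27 SNPs/kb between the two parents plus indels, a known two-peak
# crossover landscape, 500 Sanger-genotyped single crossover molecules,
# 20,000 sonicated 2x75 bp read pairs from mass-amplified crossover
# molecules, and limiting-dilution titration series for wild type and a
# crossover-reduced mutant. Everything is seeded and the ground truth is
# written alongside the data.

suppressPackageStartupMessages(library(panxo))

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- sim_config(seed = 20180101, length_bp = 9482, snp_rate = 0.0274,
                  n_molecules = 500)

hp <- make_haplotypes(cfg)
pm <- hp$truth$pan
write_haplotype_fasta(list(hp$hap_a, hp$hap_b), file.path(out, "haplotypes.fasta"))
write_key_table(pm, file.path(out, "truth_key.csv"))

# crossover landscape generated by the inverse-divergence model itself:
# local intensity log(a) + b * x^(-c) with x the polymorphism weight in the
# surrounding 500 bp, so sparse regions recombine more
landscape <- list(kind = "inverse_divergence", a = 1, b = 30, c = 1,
                  window_bp = 500)
gaps <- panxo:::marker_gaps(pm)
intensity <- panxo:::gap_intensity(pm, gaps, landscape)

sim <- sample_crossover_molecules(pm, cfg$n_molecules, landscape, seed = 11)
write.csv(sim$genotypes, file.path(out, "molecule_genotypes.csv"),
          row.names = FALSE)
write.csv(sim$molecules[, c("molecule_id", "breakpoint", "left_marker",
                            "right_marker")],
          file.path(out, "truth_breakpoints.csv"), row.names = FALSE)

pairs <- make_read_pairs(sim$molecules, 20000, cfg, seed = 12)
write_fastq_pairs(pairs, file.path(out, "crossover_reads"))

# titrations: wild type and a mutant with ~40% fewer crossover molecules;
# each class is titrated around its own informative dilution range
ti <- function(lambda, dil, class) simulate_titration(
  lambda, dil, cfg$titration$n_reactions * 8, molecule_class = class)
set.seed(13)
dil_xo <- c(256, 512, 1024)
dil_par <- c(262144, 524288, 1048576)
wt <- rbind(
  cbind(class = "crossover", ti(300, dil_xo, "crossover")$levels),
  cbind(class = "parental", ti(400000, dil_par, "parental")$levels))
mut <- rbind(
  cbind(class = "crossover", ti(180, dil_xo, "crossover")$levels),
  cbind(class = "parental", ti(400000, dil_par, "parental")$levels))
names(wt)[2] <- names(mut)[2] <- "dilution_factor"
write.csv(wt, file.path(out, "titration_wt.csv"), row.names = FALSE)
write.csv(mut, file.path(out, "titration_mutant.csv"), row.names = FALSE)

write.csv(cbind(gaps, weight = intensity),
          file.path(out, "truth_landscape.csv"), row.names = FALSE)

cat("Synthetic study written to", out, "\n")
cat(sprintf("  amplicon: %d bp (pan), %d SNPs, %d indel records\n",
            pm$length_bp, sum(pm$positions$snp),
            sum(polymorphism_track(pm)$kind != "snp")))
cat(sprintf("  %d crossover molecules, %d read pairs, 2 titration series\n",
            cfg$n_molecules, 20000L))
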