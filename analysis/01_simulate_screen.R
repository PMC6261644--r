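#!/usr/bin/env Rscript
# Simulate the flank-library screen at the study's design: 1024 variants,
# three hormone (dex) and three vehicle replicates, 5e6 reads per sample,
# NB dispersion 0.05, 15% enhancing (+1 log2) and 10% blunting (-1 log2)
# variants.  Writes the count matrix, sample sheet and ground truth that
# the later stages consume.

library(synstarr)

seed <- 20260922L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

flank <- enumerate_variants(gbs_templates()$cgt)
cfg <- screen_sim_config(flank, n_replicates = 3L, depth = 5e6,
                         alpha = 0.05, f_enh = 0.15, f_blunt = 0.10,
                         beta_enh = 1, beta_blunt = -1, seed = seed)
screen <- simulate_screen(cfg)

write_counts_tsv(screen$counts, file.path(out_dir, "flank_counts.tsv"))
write.table(screen$samples, file.path(out_dir, "flank_samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(screen$truth, file.path(out_dir, "flank_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_run_report(list(stage = "simulate", seed = seed,
                      n_variants = length(flank$keys),
                      depth = cfg$depth, dispersion = cfg$alpha,
                      f_enh = cfg$f_enh, f_blunt = cfg$f_blunt),
                 file.path(out_dir, "01_simulate_report.json"))

cat(sprintf("Simulated %d variants x %d samples (%.1fM total reads).\n",
            nrow(screen$counts), ncol(screen$counts),
            sum(screen$counts) / 1e6))
cat(sprintf("Planted: %d enhancing, %d blunting, %d neutral.\n",
            sum(screen$truth$class == "enhancing"),
            sum(screen$truth$class == "blunting"),
            sum(screen$truth$class == "neutral")))
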