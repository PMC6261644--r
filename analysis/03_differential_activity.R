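#!/usr/bin/env Rscript
# Per-variant activity from the simulated screen: median-of-ratios
# normalisation, moderated NB dispersions, Wald tests, BH adjustment, and
# enhancing / blunting / neutral classification at padj < 0.01.  Compares
# the calls against the simulation truth.

library(synstarr)

out_dir <- "results"
counts <- read_counts_tsv(file.path(out_dir, "flank_counts.tsv"))
samples <- read_sample_sheet(file.path(out_dir, "flank_samples.tsv"))
truth <- read.delim(file.path(out_dir, "flank_truth.tsv"),
                    stringsAsFactors = FALSE)

qc <- replicate_correlations(counts, samples)
res <- differential_activity(counts, samples, alpha = 0.01, mode = "flank")
cc <- attr(res, "class_counts")

write_results_tsv(res, file.path(out_dir, "flank_differential.tsv"))
write.table(qc, file.path(out_dir, "flank_replicate_qc.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tr <- truth[match(res$key, truth$key), ]
confusion <- table(truth = tr$class, called = res$class)
pos <- tr$class != "neutral"
called <- res$class != "neutral"
sens <- sum(called & pos & sign(res$log2FoldChange) == sign(tr$beta)) /
  sum(pos)
fdr <- sum(called & !pos) / max(1, sum(called))
write_run_report(list(stage = "differential", alpha = 0.01,
                      class_counts = as.list(cc),
                      sensitivity = sens, fdr = fdr,
                      replicate_r_min = min(qc$r)),
                 file.path(out_dir, "03_differential_report.json"))

cat(sprintf("Replicate correlations (log10 counts): %.3f-%.3f.\n",
            min(qc$r), max(qc$r)))
cat(sprintf("Classes at padj < 0.01: %s.\n",
            paste(names(cc), cc, sep = " = ", collapse = ", ")))
cat(sprintf("Against truth: sensitivity %.3f, FDR %.3f.\n", sens, fdr))
print(confusion)
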