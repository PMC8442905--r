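#!/usr/bin/env Rscript
# Simulate the study cohort: a 5-tissue reference atlas, a 40-sample plasma
# cohort (20 controls, 20 cancer) with 200 planted enhancer DMRs at effect
# 0.15 and mean CpG coverage 10, plus spike-in controls for conversion QC.
# Writes the raw per-sample call tables and annotations consumed by the
# downstream steps.

suppressPackageStartupMessages({
  library(cfmodal)
  library(GenomicRanges)  # quiet the deferred S4 attach messages
})
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

atlas <- make_atlas(n_tissues = 5, n_regions = 2000, effect = 0.4, seed = 101)
cohort <- make_cohort(atlas, c(control = 20, cancer = 20), dmr_effect = 0.15,
                      n_dmrs = 200, coverage = 10, seed = 102)

for (s in names(cohort$calls)) {
  write_cpg_calls(cohort$calls[[s]], file.path("results/sim", paste0(s, ".bedgraph")))
}
write_bed(cohort$annotations$enhancers, "results/sim/enhancers.bed")
write_bed(cohort$annotations$promoters, "results/sim/promoters.bed")
meta <- data.frame(sample_id = names(cohort$truth$sample_labels),
                   group = unname(cohort$truth$sample_labels))
write.table(meta, "results/sim/metadata.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
dmr_truth <- cohort$truth$planted_dmrs[[1]]
write.table(dmr_truth, "results/sim/planted_dmrs.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
saveRDS(list(atlas = atlas, cohort = cohort), "scratch/cohort.rds")  # handoff

si <- make_spikein(1e5, conv = 0.97, n_unmod_calls = 1e5, fpr = 0.0028, seed = 103)
qc <- spikein_qc(si$meth_control, si$unmod_control)
cat(sprintf("Simulated %d samples; spike-in conversion %.1f%%, false-positive %.2f%% (gate at 90%%: %s)\n",
            length(cohort$calls), 100 * qc$conversion_rate,
            100 * qc$false_positive_rate,
            ifelse(qc_gate(qc, 0.90)$keep, "keep", "exclude")))
cat(sprintf("Planted %d enhancer DMRs at |effect| 0.15\n", nrow(dmr_truth)))
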