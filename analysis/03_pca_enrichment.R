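#!/usr/bin/env Rscript
# Unsupervised structure: PCA of 1-kb window methylation, the windows most
# correlated with the group-separating component, and their overlap
# enrichment in enhancers vs promoters.

suppressPackageStartupMessages({
  library(cfmodal)
  library(GenomicRanges)  # quiet the deferred S4 attach messages
})
sim <- readRDS("scratch/cohort.rds")
wmm <- window_levels(sim$cohort$calls, width = 1000, min_mean_cov = 2)
labels <- sim$cohort$truth$sample_labels[rownames(wmm$levels)]

pca <- methyl_pca(wmm$levels)
sep <- apply(pca$scores[, 1:5], 2, function(s) {
  abs(mean(s[labels == "cancer"]) - mean(s[labels == "control"])) / sd(s)
})
pc <- which.max(sep)
cat(sprintf("PC%d separates the groups best (%.2f SD); explains %.1f%% variance\n",
            pc, max(sep), 100 * pca$explained_variance[pc]))

scores <- data.frame(sample = rownames(pca$scores), group = labels,
                     pca$scores[, 1:5])
write.table(scores, "results/pca_scores.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

top <- pc_correlates(wmm$levels, pca, component = pc, proba = 0.01, top_n = 200)
write.table(top, "results/pc_top_windows.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

enr <- lapply(list(enhancer = sim$cohort$annotations$enhancers,
                   promoter = sim$cohort$annotations$promoters),
              function(f) fisher_overlap(top$window, colnames(wmm$levels), f))
tab <- do.call(rbind, lapply(names(enr), function(n) {
  data.frame(feature = n, odds_ratio = enr[[n]]$odds_ratio,
             p_value = enr[[n]]$p_value,
             overlap = enr[[n]]$contingency[["a"]], query = length(top$window))
}))
write.table(tab, "results/enrichment.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(sprintf("Top-%d PC%d windows: enhancer OR %.1f (p = %.2e); promoter OR %.2f\n",
            nrow(top), pc, tab$odds_ratio[1], tab$p_value[1], tab$odds_ratio[2]))
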