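#!/usr/bin/env Rscript
# Two-class cancer-vs-control prediction: DMR selection (Welch t, p < 0.002,
# |diff| > 0.05, enhancer windows only) nested inside leave-one-out
# cross-validation of an elastic-net logistic model; ROC/AUC; external
# scoring of cirrhosis-like samples; DMR stability under down-sampling.

suppressPackageStartupMessages({
  library(cfmodal)
  library(GenomicRanges)  # quiet the deferred S4 attach messages
})
sim <- readRDS("scratch/cohort.rds")
wmm <- window_levels(sim$cohort$calls, width = 1000, min_mean_cov = 2)
y <- sim$cohort$truth$sample_labels[rownames(wmm$levels)]
enh <- windows_in_features(wmm, sim$cohort$annotations$enhancers)

loo <- loo_predict(wmm$levels, y, positive = "cancer", candidates = enh, seed = 104)
roc <- roc_auc(loo$scores, y, "cancer")
cat(sprintf("LOO AUC %.3f; %d-%d DMRs per fold; %d unique DMRs across folds\n",
            roc$auc, min(loo$fold_n_features), max(loo$fold_n_features),
            length(loo$dmr_union)))
planted <- sim$cohort$truth$planted_dmrs[[1]]$window
cat(sprintf("%.0f%% of selected DMRs are planted windows\n",
            100 * mean(loo$dmr_union %in% planted)))

write.table(data.frame(sample = names(loo$scores), group = y, score = loo$scores),
            "results/loo_scores.tsv", sep = "\t", row.names = FALSE, quote = FALSE)
write.table(data.frame(threshold = roc$thresholds, tpf = roc$tpf, fpf = roc$fpf),
            "results/roc_curve.tsv", sep = "\t", row.names = FALSE, quote = FALSE)

# independent validation set: cirrhosis-like samples without the planted effect
ext <- make_cohort(sim$atlas, c(control = 4, cirrhosis = 4), dmr_effect = 0,
                   n_dmrs = 0, coverage = 10, seed = 105)
wext <- window_levels(ext$calls, 1000, 2)
common <- intersect(colnames(wmm$levels), colnames(wext$levels))
sc <- score_external(loo, wmm$levels[, common], wext$levels[, common])
cat(sprintf("External cirrhosis-like mean score %.2f vs cancer mean %.2f\n",
            mean(sc$scores), mean(sc$refit_scores[y == "cancer"])))

# DMR stability against a half-coverage rerun
half <- make_cohort(sim$atlas, c(control = 20, cancer = 20), dmr_effect = 0.15,
                    n_dmrs = 200, coverage = 5, seed = 102)
whalf <- window_levels(half$calls, 1000, 2)
yh <- half$truth$sample_labels[rownames(whalf$levels)]
dm_half <- find_dmrs(whalf$levels[yh == "cancer", ], whalf$levels[yh == "control", ],
                     candidates = windows_in_features(whalf, half$annotations$enhancers))
cat(sprintf("DMR stability at half coverage: %.0f%% of reference DMRs recovered\n",
            100 * dmr_stability(loo$dmr_union, dm_half$window)))
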