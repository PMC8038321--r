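#!/usr/bin/env Rscript
# Summarize the classifier metrics (mean +/- SD, coefficient of variation),
# run the paired Wilcoxon comparisons across optimization criteria and input
# sets (validation and test kept separate), and plot the averaged ROC of the
# best classifier by validation F1.

suppressPackageStartupMessages(library(ehglabor))

metrics <- read.csv("results/05_metrics.csv")
rep_ <- compare_report(metrics)
write.csv(rep_$summary, "results/06_summary.csv", row.names = FALSE)
write.csv(rep_$comparisons, "results/06_comparisons.csv", row.names = FALSE)

val <- rep_$summary[rep_$summary$subset == "validation", ]
best <- val[which.max(val$f1_mean), ]
cat(sprintf("best by validation F1: %s_%s_set%d: F1 %.1f +/- %.1f%% (CV %.1f%%)\n",
            best$classifier, best$criterion, best$input_set,
            best$f1_mean, best$f1_sd, best$f1_cv))
sig <- rep_$comparisons[rep_$comparisons$p_value < 0.05, ]
cat(sprintf("%d of %d pairwise comparisons significant at p < 0.05 (raw p-values)\n",
            nrow(sig), nrow(rep_$comparisons)))

# averaged ROC for the best configuration, recomputed from its experiment
raw <- read.csv(sprintf("results/03_table_set%d.csv", best$input_set))
fn <- setdiff(names(raw), c("id", "label", "origin"))
attr(raw, "feature_names") <- fn
attr(raw, "input_set") <- best$input_set
class(raw) <- c("ehg_table", "data.frame")
grid <- switch(best$classifier,
               elm = list(n_hidden = c(50, 100, 150), activation = c("sigmoid", "tanh")),
               rf = list(n_trees = c(100, 250), max_depth = c(8, 0), min_node_size = c(1, 5)),
               knn = list(k = c(3, 7, 11), minkowski_p = 2,
                          kernel = c("rectangular", "triangular", "gaussian")))
ex <- run_experiment(raw, kinds = best$classifier, criteria = best$criterion,
                     grids = setNames(list(grid), best$classifier),
                     n_reps = 30, n_seeds = 10, seed = 1L)
sel <- ex$selections[[paste(best$classifier, best$criterion, sep = "_")]]
roc_pts <- list()
for (sub in c("validation", "test")) {
  ev <- evaluate_selected(ex$design, sel, sub)
  av <- average_roc(ev$scores, ev$labels)
  roc_pts[[sub]] <- data.frame(subset = sub, fpr = av$fpr, tpr = av$mean_tpr,
                               mean_auc = av$mean_auc)
  cat(sprintf("%s AUC: %.1f%%\n", sub, 100 * av$mean_auc))
}
roc_df <- do.call(rbind, roc_pts)
write.csv(roc_df, "results/06_roc.csv", row.names = FALSE)

pdf("results/06_roc.pdf", width = 5, height = 5)
plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "False positive rate",
     ylab = "True positive rate", main = "Averaged ROC, best classifier")
abline(0, 1, lty = 3, col = "grey")
cols <- c(validation = "steelblue", test = "firebrick")
for (sub in names(cols))
  lines(roc_df$fpr[roc_df$subset == sub], roc_df$tpr[roc_df$subset == sub],
        col = cols[sub], lwd = 2)
legend("bottomright", legend = sprintf("%s (AUC %.1f%%)", names(cols),
       100 * sapply(names(cols), function(s) roc_df$mean_auc[roc_df$subset == s][1])),
       col = cols, lwd = 2, bty = "n")
dev.off()
cat("wrote results/06_roc.csv and results/06_roc.pdf\n")
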