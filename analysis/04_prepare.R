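#!/usr/bin/env Rscript
# Balance input set 2 with SMOTE (five neighbors, 3:1 target), build the 30
# stratified train/validation/test partitions, and record the per-partition
# PCA dimensionality at 98% retained variance.

suppressPackageStartupMessages(library(ehglabor))

seed <- 1L
raw <- read.csv("results/03_table_set2.csv")
fn <- setdiff(names(raw), c("id", "label", "origin"))
attr(raw, "feature_names") <- fn
attr(raw, "input_set") <- 2L
class(raw) <- c("ehg_table", "data.frame")

bal <- smote(raw, ratio = 3, k = 5, seed = seed)
write.csv(as.data.frame(bal), "results/04_balanced_table.csv", row.names = FALSE)
cat(sprintf("balanced table: %d samples (%d minority / %d majority)\n",
            nrow(bal), sum(bal$label == 1), sum(bal$label == 0)))

parts <- make_partitions(bal, n_reps = 30, seed = seed + 1L)
jsonlite::write_json(
  lapply(parts, function(p) lapply(p, function(ix) bal$id[ix])),
  "results/04_partitions.json")
cat(sprintf("30 partitions: train %d / validation %d / test %d\n",
            length(parts[[1]]$train), length(parts[[1]]$validation),
            length(parts[[1]]$test)))

ncomp <- vapply(parts, function(p)
  fit_pca(bal[p$train, fn])$n_components, integer(1))
write.csv(data.frame(partition = seq_along(parts), pca_components = ncomp),
          "results/04_pca_components.csv", row.names = FALSE)
cat("PCA components at 98% variance (per partition):",
    paste(range(ncomp), collapse = "-"), "\n")
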