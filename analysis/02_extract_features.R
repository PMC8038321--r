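#!/usr/bin/env Rscript
# Read the simulated recordings back through the ingest path (CSV + sidecar),
# condition each to the 0.1-4 Hz bipolar signal at 20 Hz, cut 120 s windows
# with 50% overlap, and compute the 23 EHG parameters per window.
# Output: a long-format window-feature table plus the per-recording metadata
# needed for aggregation.

suppressPackageStartupMessages(library(ehglabor))

raw_dir <- "scratch/cohort"
manifest <- read.csv(file.path(raw_dir, "manifest.csv"))

rows <- list()
meta <- list()
for (i in seq_len(nrow(manifest))) {
  rec <- read_recording(file.path(raw_dir, manifest$file[i]), "csv")
  ws <- cut_windows(condition(rec))
  feat <- extract_features(ws)
  rows[[i]] <- cbind(data.frame(recording_id = rec$id), feat)
  meta[[i]] <- data.frame(recording_id = rec$id, ttd_days = rec$ttd_days,
                          t(rec$obstetric))
  if (i %% 20 == 0) cat("processed", i, "recordings\n")
}
windows <- do.call(rbind, rows)
write.csv(windows, "results/02_window_features.csv", row.names = FALSE)
write.csv(do.call(rbind, meta), "results/02_recording_meta.csv", row.names = FALSE)

cat(sprintf("Extracted %d windows x %d features from %d recordings.\n",
            nrow(windows), length(ehg_feature_names()), nrow(manifest)))
cat("Median windows per recording:",
    median(table(windows$recording_id)), "\n")
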