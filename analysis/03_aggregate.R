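#!/usr/bin/env Rscript
# Collapse window features to one sample per recording by trend-directed
# percentiles (90th for rising features, 10th for falling ones) or the median,
# and assemble the four classifier input tables:
#   set 1: P10-P90 EHG + obstetric   set 2: P50 EHG + obstetric
#   set 3: P10-P90 EHG               set 4: P50 EHG

suppressPackageStartupMessages(library(ehglabor))

windows <- read.csv("results/02_window_features.csv")
meta <- read.csv("results/02_recording_meta.csv")

ob_names <- c("cervical_length_mm", "gestational_age_weeks", "maternal_age_years",
              "gestations", "parity", "abortions")
cf <- lapply(seq_len(nrow(meta)), function(i) {
  id <- meta$recording_id[i]
  list(id = id,
       features = windows[windows$recording_id == id, , drop = FALSE],
       obstetric = unlist(meta[i, ob_names]),
       ttd_days = meta$ttd_days[i])
})

for (set in 1:4) {
  tab <- build_table(cf, set)
  write.csv(as.data.frame(tab), sprintf("results/03_table_set%d.csv", set),
            row.names = FALSE)
  cat(sprintf("input set %d: %d samples x %d features, %d imminent\n",
              set, nrow(tab), length(attr(tab, "feature_names")), sum(tab$label)))
}
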