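#' Collapse per-window features to one value per recording
#'
#' Under `mode = "p50"` every feature is summarized by its median over the
#' analysis windows. Under `mode = "p10_90"` (trend-directed percentiles) the
#' 90th percentile is taken for features that rise in contractile periods as
#' labor approaches (amplitude, DF1, DF2, deciles, H/L ratio, time
#' reversibility) and the 10th percentile for features that fall (SMR, both
#' Lempel-Ziv measures, sample/fuzzy/spectral entropy, SD1, SD2, SD1/SD2), so
#' the aggregate reflects the burst-rich windows rather than baseline.
#' Percentiles use linear interpolation between closest order statistics
#' (quantile type 7). Windows where a feature is undefined are excluded from
#' that feature's percentile only.
#'
#' @param features per-window feature data frame from [extract_features()].
#' @param mode `"p50"` or `"p10_90"`.
#' @return Named numeric vector over [ehg_feature_names()]; a feature missing
#'   in every window aggregates to `NA`.
#' @export
aggregate_recording <- function(features, mode = c("p50", "p10_90")) {
  mode <- match.arg(mode)
  nms <- ehg_feature_names()
  stopifnot(all(nms %in% names(features)))
  up <- ehg_increasing_features()
  vapply(nms, function(nm) {
    v <- features[[nm]]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    prob <- if (mode == "p50") 0.5 else if (nm %in% up) 0.9 else 0.1
    stats::quantile(v, prob, type = 7, names = FALSE)
  }, numeric(1))
}

#' Assemble the classifier input table for one input set
#'
#' Input sets follow the study design: (1) trend-directed 10th-90th
#' percentiles of the EHG parameters plus the six obstetric covariates;
#' (2) 50th percentile plus obstetric covariates; (3) 10th-90th percentiles
#' only; (4) 50th percentile only. The binary label is positive when time to
#' delivery is at most `ttd_threshold` days.
#'
#' Recordings with a fully missing EHG aggregate, or (for sets 1 and 2) a
#' missing obstetric covariate, are excluded; exclusions are reported in the
#' `excluded` attribute with the offending field named.
#'
#' @param cohort_features list with one element per recording, each a list
#'   holding `id`, `features` (per-window data frame), `obstetric` (named
#'    6-vector) and `ttd_days`. [extract_cohort_features()] produces this.
#' @param input_set integer 1-4.
#' @param ttd_threshold days; default 7 (inclusive).
#' @return An `ehg_table`: data frame with `id`, `label` (1 = imminent),
#'   `origin`, then 23 or 29 feature columns. Attributes: `feature_names`,
#'   `input_set`, `excluded`.
#' @export
build_table <- function(cohort_features, input_set, ttd_threshold = 7) {
  stopifnot(input_set %in% 1:4)
  mode <- if (input_set %in% c(1, 3)) "p10_90" else "p50"
  with_obstetric <- input_set %in% c(1, 2)
  excluded <- character(0)
  rows <- list()
  for (rf in cohort_features) {
    agg <- aggregate_recording(rf$features, mode)
    if (anyNA(agg)) {
      excluded <- c(excluded, paste0(rf$id, ": EHG feature ",
                                     paste(names(agg)[is.na(agg)], collapse = ","),
                                     " undefined in all windows"))
      next
    }
    if (with_obstetric && anyNA(rf$obstetric)) {
      excluded <- c(excluded, paste0(rf$id, ": missing obstetric field ",
                                     paste(names(rf$obstetric)[is.na(rf$obstetric)],
                                           collapse = ",")))
      next
    }
    feat <- if (with_obstetric) c(agg, rf$obstetric) else agg
    rows[[length(rows) + 1]] <-
      cbind(data.frame(id = rf$id,
                       label = as.integer(rf$ttd_days <= ttd_threshold),
                       origin = "real", stringsAsFactors = FALSE),
            as.data.frame(as.list(feat)))
  }
  if (length(excluded) > 0)
    message("excluded ", length(excluded), " recording(s): ",
            paste(excluded, collapse = "; "))
  tab <- do.call(rbind, rows)
  attr(tab, "feature_names") <- setdiff(names(tab), c("id", "label", "origin"))
  attr(tab, "input_set") <- input_set
  attr(tab, "excluded") <- excluded
  class(tab) <- c("ehg_table", "data.frame")
  tab
}

#' Run a cohort through conditioning, windowing and feature extraction
#'
#' @param cohort an `ehg_cohort` (or any list of `ehg_recording` objects).
#' @param band,fs_out see [condition()].
#' @param win_s,overlap see [cut_windows()].
#' @param params see [window_features()].
#' @return List of per-recording elements (`id`, `features`, `obstetric`,
#'   `ttd_days`), ready for [build_table()]. Recordings without any valid
#'   window are dropped with a warning.
#' @export
extract_cohort_features <- function(cohort, band = c(0.1, 4), fs_out = 20,
                                    win_s = 120, overlap = 0.5, params = list()) {
  out <- list()
  for (rec in cohort) {
    sig <- condition(rec, band = band, fs_out = fs_out)
    ws <- suppressWarnings(cut_windows(sig, win_s = win_s, overlap = overlap))
    if (length(ws$windows) == 0) {
      warning("recording ", rec$id, " excluded: no valid analysis window")
      next
    }
    out[[length(out) + 1]] <- list(
      id = rec$id,
      features = extract_features(ws, params),
      obstetric = rec$obstetric,
      ttd_days = rec$ttd_days)
  }
  out
}
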