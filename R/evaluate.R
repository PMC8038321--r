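#' Confusion counts of a binary prediction
#'
#' A true positive is an imminent delivery (label 1) correctly predicted.
#'
#' @param pred predicted 0/1 labels.
#' @param truth reference 0/1 labels.
#' @return Named vector `tp, tn, fp, fn`.
#' @export
confusion_counts <- function(pred, truth) {
  c(tp = sum(pred == 1 & truth == 1), tn = sum(pred == 0 & truth == 0),
    fp = sum(pred == 1 & truth == 0), fn = sum(pred == 0 & truth == 1))
}

#' F1-score, sensitivity and specificity (percent)
#'
#' `F1 = 100 * 2 TP / (2 TP + FP + FN)`, `sensitivity = 100 * TP / (TP + FN)`,
#' `specificity = 100 * TN / (TN + FP)`. A zero denominator yields the `NA`
#' sentinel.
#'
#' @param counts named vector from [confusion_counts()].
#' @return Named vector `f1, sensitivity, specificity` in percent.
#' @export
classification_metrics <- function(counts) {
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  div <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(f1 = div(2 * tp, 2 * tp + fp + fn),
    sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp))
}

#' Mean, SD and coefficient of variation of a metric across partitions
#'
#' @param v numeric vector of per-partition metric values (percent).
#' @return Named vector `mean, sd, cv` with `cv = 100 * sd / mean` (percent),
#'   `NA` when the mean is not positive.
#' @export
summarize_metric <- function(v) {
  m <- mean(v, na.rm = TRUE)
  s <- stats::sd(v, na.rm = TRUE)
  c(mean = m, sd = s, cv = if (!is.na(m) && m > 0) 100 * s / m else NA_real_)
}

# Exact distribution of the positive-rank sum W+ for (possibly midrank-tied)
# ranks, by convolution over doubled ranks (integers). Returns P(W+ <= w) and
# P(W+ >= w) at the observed doubled statistic w2.
signed_rank_exact_p <- function(ranks2, w2) {
  maxsum <- sum(ranks2)
  probs <- numeric(maxsum + 1)  # index s+1 = P(sum = s), scaled by 2^n
  probs[1] <- 1
  for (r in ranks2) {
    shifted <- c(rep(0, r), probs[seq_len(maxsum + 1 - r)])
    probs <- probs + shifted
  }
  total <- sum(probs)
  p_le <- sum(probs[seq_len(w2 + 1)]) / total
  p_ge <- sum(probs[(w2 + 1):(maxsum + 1)]) / total
  c(p_le = p_le, p_ge = p_ge)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences. Zero differences are dropped; ties
#' receive midranks. With 25 or fewer nonzero pairs the exact null
#' distribution of the positive-rank sum is computed by convolution (valid
#' under midranks); otherwise the normal approximation with tie correction and
#' continuity correction is used. All differences zero gives `p = 1` (flagged
#' via `degenerate = TRUE`).
#'
#' @param a,b paired metric vectors (same length, paired by partition).
#' @param exact_max largest number of nonzero pairs for the exact branch.
#' @return List with `statistic` (positive-rank sum V), `p_value`, `n_nonzero`,
#'   `method`, `degenerate`.
#' @export
paired_wilcoxon <- function(a, b, exact_max = 25) {
  stopifnot(length(a) == length(b))
  ok <- !(is.na(a) | is.na(b))
  d <- a[ok] - b[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p_value = 1, n_nonzero = 0,
                method = "degenerate", degenerate = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    w2 <- as.integer(round(2 * v))
    p2 <- signed_rank_exact_p(r2, w2)
    p <- min(1, 2 * min(p2))
    return(list(statistic = v, p_value = p, n_nonzero = n, method = "exact",
                degenerate = FALSE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  cc <- sign(v - mu) * 0.5
  z <- (v - mu - cc) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = v, p_value = p, n_nonzero = n, method = "normal",
       degenerate = FALSE)
}

#' ROC curve and AUC from continuous scores
#'
#' Threshold sweep over the unique scores; AUC by the trapezoid rule (equal to
#' the Mann-Whitney U statistic divided by the product of class sizes).
#'
#' @param scores continuous positive-class scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return List with `fpr`, `tpr` (monotone threshold sweep, including the
#'   (0,0) and (1,1) endpoints) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("ROC requires both classes present")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  # collapse tied scores: keep the last index of each tie block
  keep <- c(diff(s) != 0, TRUE)
  tpr <- c(0, tp[keep] / n_pos)
  fpr <- c(0, fp[keep] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Vertically averaged ROC over partitions
#'
#' Per-partition ROC curves are interpolated onto a fixed 101-point FPR grid
#' and averaged pointwise; the mean AUC is the mean of the per-partition AUCs.
#'
#' @param scores,labels lists of per-partition score and label vectors.
#' @return List with `fpr` (grid), `mean_tpr`, `aucs`, `mean_auc`.
#' @export
average_roc <- function(scores, labels) {
  grid <- seq(0, 1, by = 0.01)
  curves <- Map(roc_curve, scores, labels)
  tprs <- vapply(curves, function(cv) {
    stats::approx(cv$fpr, cv$tpr, xout = grid, method = "linear",
                  ties = "ordered", rule = 2)$y
  }, numeric(length(grid)))
  aucs <- vapply(curves, `[[`, numeric(1), "auc")
  list(fpr = grid, mean_tpr = rowMeans(tprs), aucs = aucs, mean_auc = mean(aucs))
}

#' Pairwise statistical comparison report across classifier configurations
#'
#' Takes a long metric table (columns `classifier`, `criterion`, `input_set`,
#' `subset`, `partition`, `f1`, `sensitivity`, `specificity`) and emits
#' (a) the mean +/- SD (CV) summary per configuration and subset, and
#' (b) paired Wilcoxon signed-rank p-values for the two families of
#' comparisons used in the study design: same classifier and input set across
#' the two optimization criteria, and same classifier and criterion across
#' input sets. Validation and test results are never mixed: each comparison is
#' computed within one subset. Raw p-values are reported without multiplicity
#' correction.
#'
#' @param metrics long-format data frame as described above.
#' @return List with `summary` and `comparisons` data frames.
#' @export
compare_report <- function(metrics) {
  need <- c("classifier", "criterion", "input_set", "subset", "partition",
            "f1", "sensitivity", "specificity")
  stopifnot(all(need %in% names(metrics)))
  key_cols <- c("classifier", "criterion", "input_set", "subset")
  metric_names <- c("f1", "sensitivity", "specificity")

  keys <- unique(metrics[key_cols])
  rownames(keys) <- NULL
  summary_rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- merge(metrics, keys[i, , drop = FALSE])
    row <- keys[i, , drop = FALSE]
    for (mn in metric_names) {
      sm <- summarize_metric(sel[[mn]])
      row[[paste0(mn, "_mean")]] <- sm["mean"]
      row[[paste0(mn, "_sd")]] <- sm["sd"]
      row[[paste0(mn, "_cv")]] <- sm["cv"]
    }
    row
  })
  summary_df <- do.call(rbind, summary_rows)

  get_part <- function(classifier, criterion, input_set, subset) {
    sel <- metrics[metrics$classifier == classifier &
                     metrics$criterion == criterion &
                     metrics$input_set == input_set &
                     metrics$subset == subset, ]
    sel[order(sel$partition), ]
  }
  comp_rows <- list()
  add_comp <- function(type, a, b, subset) {
    if (nrow(a) == 0 || nrow(b) == 0) return()
    if (!identical(a$partition, b$partition)) stop("mismatched partition sets")
    for (mn in metric_names) {
      w <- paired_wilcoxon(a[[mn]], b[[mn]])
      comp_rows[[length(comp_rows) + 1]] <<- data.frame(
        type = type, subset = subset, metric = mn,
        classifier_a = a$classifier[1], criterion_a = a$criterion[1],
        input_set_a = a$input_set[1],
        classifier_b = b$classifier[1], criterion_b = b$criterion[1],
        input_set_b = b$input_set[1],
        statistic = w$statistic, p_value = w$p_value,
        stringsAsFactors = FALSE)
    }
  }
  for (sub in unique(metrics$subset)) {
    for (cls in unique(metrics$classifier)) {
      sets <- sort(unique(metrics$input_set[metrics$classifier == cls]))
      crits <- unique(metrics$criterion[metrics$classifier == cls])
      # (a) same classifier & input set, across criteria
      if (length(crits) == 2) {
        for (is_ in sets)
          add_comp("criterion", get_part(cls, crits[1], is_, sub),
                   get_part(cls, crits[2], is_, sub), sub)
      }
      # (b) same classifier & criterion, across input sets
      for (cr in crits) {
        if (length(sets) >= 2) {
          pairs <- utils::combn(sets, 2)
          for (pi in seq_len(ncol(pairs)))
            add_comp("input_set", get_part(cls, cr, pairs[1, pi], sub),
                     get_part(cls, cr, pairs[2, pi], sub), sub)
        }
      }
    }
  }
  list(summary = summary_df,
       comparisons = if (length(comp_rows)) do.call(rbind, comp_rows)
                     else data.frame())
}
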