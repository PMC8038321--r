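# Independent brute-force oracles used to validate the package implementations.
# These are direct transcriptions of the defining formulas, kept free of any
# package internals.

# O(N^2) sample entropy pair counts (templates 1..N-m for lengths m and m+1).
sampen_oracle_counts <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0L
  B <- 0L
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1L
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1L
      }
    }
  }
  list(A = A, B = B)
}

sampen_oracle <- function(x, m = 2, r = 0.15 * sd(x)) {
  cnt <- sampen_oracle_counts(x, m, r)
  if (cnt$A == 0 || cnt$B == 0) return(NA_real_)
  -log(cnt$A / cnt$B)
}

# O(N^2) fuzzy entropy with mean-centered templates and exp(-(d/r)^grad)
# membership.
fuzzyen_oracle <- function(x, m = 2, r = 0.15 * sd(x), grad = 2) {
  n <- length(x)
  nt <- n - m
  sum_m <- 0
  sum_m1 <- 0
  for (i in 1:(nt - 1)) {
    ti_m <- x[i:(i + m - 1)] - mean(x[i:(i + m - 1)])
    ti_m1 <- x[i:(i + m)] - mean(x[i:(i + m)])
    for (j in (i + 1):nt) {
      tj_m <- x[j:(j + m - 1)] - mean(x[j:(j + m - 1)])
      tj_m1 <- x[j:(j + m)] - mean(x[j:(j + m)])
      sum_m <- sum_m + exp(-(max(abs(ti_m - tj_m)) / r)^grad)
      sum_m1 <- sum_m1 + exp(-(max(abs(ti_m1 - tj_m1)) / r)^grad)
    }
  }
  -log(sum_m1 / sum_m)
}

# LZ76 phrase count by the exhaustive-history definition: each phrase is the
# shortest word starting at p that is not a substring of everything before its
# last character (overlap allowed).
lz76_oracle <- function(s) {
  n <- length(s)
  count <- 0L
  p <- 1L
  while (p <= n) {
    k <- 1L
    repeat {
      if (p + k - 1L > n) break
      word <- s[p:(p + k - 1L)]
      if (p + k - 2L < k) { found <- FALSE } else {
        hist <- s[1:(p + k - 2L)]
        nh <- length(hist) - k + 1L
        found <- nh >= 1 && any(vapply(seq_len(nh), function(st)
          all(hist[st:(st + k - 1L)] == word), logical(1)))
      }
      if (!found) break
      k <- k + 1L
    }
    count <- count + 1L
    p <- p + k
  }
  count
}

# Exhaustive two-sided signed-rank p-value by enumerating all sign assignments.
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  p_le <- mean(vs <= v_obs)
  p_ge <- mean(vs >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Mann-Whitney U based AUC (ties get half credit).
auc_rank_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  u <- 0
  for (p in pos) u <- u + sum(p > neg) + 0.5 * sum(p == neg)
  u / (length(pos) * length(neg))
}

# Brute-force count of fully valid windows on a regular start grid.
window_count_oracle <- function(duration_s, win_s, step_s, bad_intervals) {
  starts <- seq(0, duration_s - win_s, by = step_s)
  ok <- vapply(starts, function(s) {
    if (nrow(bad_intervals) == 0) return(TRUE)
    !any(s < bad_intervals[, 2] & (s + win_s) > bad_intervals[, 1])
  }, logical(1))
  sum(ok)
}

# Minimal EDF writer (int16 records) for reader tests.
write_edf_fixture <- function(path, signals, fs, labels,
                              phys_min = -1000, phys_max = 1000) {
  ns <- length(signals)
  record_dur <- 1
  n_samp <- as.integer(fs * record_dur)
  n_records <- length(signals[[1]]) %/% n_samp[1]
  dig_min <- -32768
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- sprintf(paste0("%-", w, "s"), as.character(x))
    writeBin(charToRaw(substr(s, 1, w)), con)
  }
  pad("0", 8); pad("patient", 80); pad("recording", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(256 * (ns + 1), 8); pad("", 44); pad(n_records, 8); pad(record_dur, 8)
  pad(ns, 4)
  for (l in labels) pad(l, 16)
  for (i in seq_len(ns)) pad("transducer", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (i in seq_len(ns)) pad(phys_min, 8)
  for (i in seq_len(ns)) pad(phys_max, 8)
  for (i in seq_len(ns)) pad(dig_min, 8)
  for (i in seq_len(ns)) pad(dig_max, 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(rep(n_samp, ns)[i], 8)
  for (i in seq_len(ns)) pad("", 32)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      seg <- signals[[i]][((r - 1) * n_samp + 1):(r * n_samp)]
      dig <- as.integer(round((seg - phys_min) / gain + dig_min))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

# Small conditioned-signal constructor for windowing tests.
fake_conditioned <- function(samples, fs = 20, valid_mask = NULL, id = "fake") {
  structure(list(id = id, fs = fs, samples = samples,
                 valid_mask = if (is.null(valid_mask)) rep(TRUE, length(samples)) else valid_mask),
            class = "ehg_conditioned")
}

# Fabricated per-recording feature sets for aggregation/table tests.
fake_cohort_features <- function(n_pos, n_neg, n_windows = 5, seed = 1) {
  set.seed(seed)
  nms <- ehg_feature_names()
  mk <- function(i, positive) {
    feats <- as.data.frame(matrix(runif(n_windows * 23), n_windows, 23,
                                  dimnames = list(NULL, nms)))
    list(id = sprintf("r%03d", i),
         features = cbind(data.frame(window_index = 1:n_windows,
                                     start_s = 60 * (0:(n_windows - 1))), feats),
         obstetric = c(cervical_length_mm = runif(1, 10, 35),
                       gestational_age_weeks = runif(1, 28, 34),
                       maternal_age_years = runif(1, 20, 42),
                       gestations = 1, parity = 0, abortions = 0),
         ttd_days = if (positive) runif(1, 0.5, 7) else runif(1, 8, 60))
  }
  c(lapply(seq_len(n_pos), mk, positive = TRUE),
    lapply(n_pos + seq_len(n_neg), mk, positive = FALSE))
}
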