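#' Configuration for the synthetic EHG cohort generator
#'
#' Builds the parameter set for [generate_cohort()]. The defaults emulate a
#' cohort of 140 thirty-minute recordings (30 from women who delivered within
#' 7 days, 110 who delivered later) sampled at 20 Hz, in which intermittent
#' EHG bursts (uterine contractions) ride on a colored-noise baseline. The
#' imminent-delivery class has, on average, larger burst amplitude, burst
#' spectral content shifted above 0.34 Hz, and more regular (less complex)
#' burst carriers, reproducing the electrophysiological trends the downstream
#' features are designed to pick up.
#'
#' Per-class parameters are length-2 numeric vectors named
#' `c(imminent = , control = )`.
#'
#' @param n_imminent,n_control class sizes (recordings).
#' @param duration_s recording duration in seconds.
#' @param fs_out output sampling rate in Hz.
#' @param burst_rate_per_10min per-class mean number of bursts per 10 minutes.
#' @param burst_amp_uV per-class mean burst peak amplitude (microvolt-scale
#'   arbitrary units); per-recording values vary around these means with SD
#'   `burst_amp_sd`.
#' @param burst_amp_sd between-recording SD of burst amplitude (same units).
#' @param burst_center_hz per-class mean center frequency of burst content (Hz).
#' @param baseline_amp RMS amplitude of the 1/f baseline noise.
#' @param regularity_ar per-class pole radius of the AR(2) resonator that
#'   generates burst carriers; closer to 1 means a narrower band and a more
#'   predictable, less complex burst. Must lie in [0, 1).
#' @param obstetric_means,obstetric_sds per-class parameters of the six
#'   obstetric covariates; lists with elements `imminent` and `control`, each a
#'   named vector over `cervical_length_mm`, `gestational_age_weeks`,
#'   `maternal_age_years`, `gestations`, `parity`, `abortions` (the count
#'   covariates are Poisson means; their "sds" entries are truncation maxima).
#' @param seed integer seed; the full cohort is a deterministic function of the
#'   configuration.
#' @return An object of class `ehg_synth_config`.
#' @export
synth_config <- function(n_imminent = 30L,
                         n_control = 110L,
                         duration_s = 1800,
                         fs_out = 20,
                         burst_rate_per_10min = c(imminent = 2.5, control = 1.5),
                         burst_amp_uV = c(imminent = 55, control = 40),
                         burst_amp_sd = 15,
                         burst_center_hz = c(imminent = 0.45, control = 0.35),
                         baseline_amp = 8,
                         regularity_ar = c(imminent = 0.985, control = 0.955),
                         obstetric_means = list(
                           imminent = c(cervical_length_mm = 15, gestational_age_weeks = 31,
                                        maternal_age_years = 33, gestations = 0.8,
                                        parity = 0.6, abortions = 0.3),
                           control = c(cervical_length_mm = 27, gestational_age_weeks = 31,
                                       maternal_age_years = 33, gestations = 0.8,
                                       parity = 0.6, abortions = 0.3)),
                         obstetric_sds = list(
                           imminent = c(cervical_length_mm = 5, gestational_age_weeks = 2.5,
                                        maternal_age_years = 5, gestations = 6,
                                        parity = 4, abortions = 3),
                           control = c(cervical_length_mm = 6, gestational_age_weeks = 2.5,
                                       maternal_age_years = 5, gestations = 6,
                                       parity = 4, abortions = 3)),
                         seed = 1L) {
  if (n_imminent <= 0 || n_control <= 0)
    stop("class sizes `n_imminent` and `n_control` must be positive")
  if (duration_s <= 0) stop("`duration_s` must be positive")
  if (fs_out <= 0) stop("`fs_out` must be positive")
  if (any(burst_rate_per_10min <= 0)) stop("burst rates must be positive")
  if (any(burst_amp_uV < 0)) stop("burst amplitudes must be nonnegative")
  if (any(regularity_ar < 0) || any(regularity_ar >= 1))
    stop("`regularity_ar` must lie in [0, 1)")
  cfg <- list(
    n_imminent = as.integer(n_imminent), n_control = as.integer(n_control),
    duration_s = duration_s, fs_out = fs_out,
    burst_rate_per_10min = burst_rate_per_10min,
    burst_amp_uV = burst_amp_uV, burst_amp_sd = burst_amp_sd,
    burst_center_hz = burst_center_hz, baseline_amp = baseline_amp,
    regularity_ar = regularity_ar,
    obstetric_means = obstetric_means, obstetric_sds = obstetric_sds,
    seed = as.integer(seed))
  class(cfg) <- "ehg_synth_config"
  cfg
}

# 1/f-shaped noise band-limited to [f_lo, f_hi], scaled to unit SD.
pink_bandlimited <- function(n, fs, f_lo = 0.1, f_hi = 4) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  af <- abs(f)
  gain <- ifelse(af >= f_lo & af <= f_hi, 1 / sqrt(pmax(af, f_lo)), 0)
  x <- Re(stats::fft(W * gain, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(x)
  x / s
}

# Narrowband burst carrier: AR(2) resonator at f0 with pole radius rho,
# driven by white noise, scaled to unit peak envelope (max |x| = 1).
ar2_carrier <- function(n, fs, f0, rho) {
  a1 <- 2 * rho * cos(2 * pi * f0 / fs)
  a2 <- -rho^2
  e <- stats::rnorm(n + 200)
  x <- stats::filter(e, c(a1, a2), method = "recursive")
  x <- as.numeric(x)[-seq_len(200)]
  mx <- max(abs(x))
  if (mx == 0) return(x)
  x / mx
}

# Tukey (tapered cosine) window, taper fraction alpha.
tukey_window <- function(n, alpha = 0.5) {
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

rpois_trunc <- function(n, lambda, max) pmin(stats::rpois(n, lambda), max)

generate_recording <- function(cfg, class, id) {
  fs <- cfg$fs_out
  n <- round(cfg$duration_s * fs)
  cls <- class  # "imminent" or "control"

  baseline1 <- cfg$baseline_amp * pink_bandlimited(n, fs)
  baseline2 <- cfg$baseline_amp * pink_bandlimited(n, fs)

  # uterine activity (common to both electrodes, opposite sign about midline)
  sig <- numeric(n)
  n_burst <- stats::rpois(1, cfg$burst_rate_per_10min[[cls]] * cfg$duration_s / 600)
  amp_rec <- max(0, stats::rnorm(1, cfg$burst_amp_uV[[cls]], cfg$burst_amp_sd))
  f0_rec <- max(0.2, stats::rnorm(1, cfg$burst_center_hz[[cls]], 0.03))
  if (n_burst > 0 && amp_rec > 0) {
    for (b in seq_len(n_burst)) {
      dur <- stats::runif(1, 30, 90)
      start <- stats::runif(1, 0, max(cfg$duration_s - dur, 0))
      i0 <- floor(start * fs) + 1
      len <- min(round(dur * fs), n - i0 + 1)
      if (len < 2) next
      env <- tukey_window(len, alpha = 0.5)
      carrier <- ar2_carrier(len, fs, f0_rec, cfg$regularity_ar[[cls]])
      amp_b <- amp_rec * stats::runif(1, 0.8, 1.2)
      idx <- i0:(i0 + len - 1)
      sig[idx] <- sig[idx] + amp_b * env * carrier
    }
  }

  ttd <- if (cls == "imminent") stats::runif(1, 0.5, 7) else stats::runif(1, 8, 60)
  mu <- cfg$obstetric_means[[cls]]
  sdv <- cfg$obstetric_sds[[cls]]
  obstetric <- c(
    cervical_length_mm = max(0, stats::rnorm(1, mu[["cervical_length_mm"]], sdv[["cervical_length_mm"]])),
    gestational_age_weeks = stats::rnorm(1, mu[["gestational_age_weeks"]], sdv[["gestational_age_weeks"]]),
    maternal_age_years = stats::rnorm(1, mu[["maternal_age_years"]], sdv[["maternal_age_years"]]),
    gestations = 1 + rpois_trunc(1, mu[["gestations"]], sdv[["gestations"]]),
    parity = rpois_trunc(1, mu[["parity"]], sdv[["parity"]]),
    abortions = rpois_trunc(1, mu[["abortions"]], sdv[["abortions"]]))

  rec <- list(
    id = id,
    fs = fs,
    m1 = baseline1 + 0.5 * sig,
    m2 = baseline2 - 0.5 * sig,
    valid_intervals = matrix(c(0, cfg$duration_s), nrow = 1,
                             dimnames = list(NULL, c("start_s", "end_s"))),
    obstetric = obstetric,
    ttd_days = ttd,
    class = cls)
  class(rec) <- "ehg_recording"
  rec
}

#' Generate a synthetic EHG cohort
#'
#' Simulates `n_imminent + n_control` two-channel monopolar recordings. Each
#' channel is 1/f baseline noise band-limited to 0.1-4 Hz plus (with opposite
#' polarity on the two electrodes, so the bipolar difference recovers it) a
#' train of Poisson-arriving EHG bursts: Tukey-windowed envelopes of duration
#' U(30, 90) s modulating a narrowband AR(2) carrier at the class's center
#' frequency. Imminent-class recordings draw larger burst amplitudes, higher
#' center frequencies and more regular carriers. Time to delivery is sampled
#' U(0.5, 7) days for the imminent class and U(8, 60) for controls.
#'
#' The result is deterministic for a fixed configuration (including its seed).
#'
#' @param config an [synth_config()] object.
#' @return A list of `ehg_recording` objects (class `ehg_cohort`), imminent
#'   recordings first.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ehg_synth_config"))
  withr_seed <- config$seed
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(withr_seed)
  classes <- c(rep("imminent", config$n_imminent), rep("control", config$n_control))
  cohort <- lapply(seq_along(classes), function(i) {
    generate_recording(config, classes[i], sprintf("rec%03d", i))
  })
  class(cohort) <- c("ehg_cohort", "list")
  attr(cohort, "config") <- config
  cohort
}

#' Inject motion-artifact segments into a recording
#'
#' Marks a set of non-overlapping intervals totaling approximately `fraction`
#' of the recording duration as unusable (removed from `valid_intervals`) and
#' superimposes large-amplitude transients there, emulating the movement
#' artifacts that are excluded from analysis by annotation.
#'
#' @param rec an `ehg_recording`.
#' @param fraction proportion of the duration to corrupt, in [0, 1).
#' @param seed integer seed for artifact placement.
#' @return The modified recording.
#' @export
inject_artifacts <- function(rec, fraction, seed = 1L) {
  stopifnot(inherits(rec, "ehg_recording"))
  if (fraction < 0 || fraction >= 1) stop("`fraction` must lie in [0, 1)")
  if (fraction == 0) return(rec)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  dur <- length(rec$m1) / rec$fs
  target <- fraction * dur
  # draw artifact intervals until the target corrupted time is reached
  bad <- matrix(numeric(0), ncol = 2)
  total <- 0
  guard <- 0
  while (total < target && guard < 1000) {
    guard <- guard + 1
    len <- min(stats::runif(1, 5, 40), target - total + 5)
    start <- stats::runif(1, 0, dur - len)
    cand <- c(start, start + len)
    # reject overlaps with existing artifact intervals
    if (nrow(bad) > 0 && any(cand[1] < bad[, 2] & cand[2] > bad[, 1])) next
    bad <- rbind(bad, cand)
    total <- total + len
  }
  bad <- bad[order(bad[, 1]), , drop = FALSE]
  # superimpose transients
  amp <- 10 * max(stats::sd(rec$m1), stats::sd(rec$m2), 1)
  for (i in seq_len(nrow(bad))) {
    idx <- (floor(bad[i, 1] * rec$fs) + 1):min(ceiling(bad[i, 2] * rec$fs), length(rec$m1))
    spike <- amp * stats::rnorm(length(idx))
    rec$m1[idx] <- rec$m1[idx] + spike
    rec$m2[idx] <- rec$m2[idx] - spike
  }
  rec$valid_intervals <- subtract_intervals(rec$valid_intervals, bad)
  rec
}

# Set difference of half-open interval lists: valid minus bad, both matrices
# with columns start/end. Returns a sorted non-overlapping matrix.
subtract_intervals <- function(valid, bad) {
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(valid))) {
    segs <- matrix(valid[i, ], ncol = 2)
    for (j in seq_len(nrow(bad))) {
      nxt <- matrix(numeric(0), ncol = 2)
      for (s in seq_len(nrow(segs))) {
        a <- segs[s, 1]; b <- segs[s, 2]
        lo <- bad[j, 1]; hi <- bad[j, 2]
        if (hi <= a || lo >= b) {
          nxt <- rbind(nxt, c(a, b))
        } else {
          if (lo > a) nxt <- rbind(nxt, c(a, lo))
          if (hi < b) nxt <- rbind(nxt, c(hi, b))
        }
      }
      segs <- nxt
      if (nrow(segs) == 0) break
    }
    out <- rbind(out, segs)
  }
  out <- out[order(out[, 1]), , drop = FALSE]
  colnames(out) <- c("start_s", "end_s")
  out
}

#' Write a cohort to disk as CSV recordings with JSON sidecars
#'
#' Writes, per recording, `<id>.csv` (columns `time_s,m1,m2`) and `<id>.json`
#' (valid intervals, obstetric covariates, time to delivery), plus a cohort
#' `manifest.csv` listing recording files and labels.
#'
#' @param cohort an `ehg_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(rec) {
    n <- length(rec$m1)
    df <- data.frame(time_s = (seq_len(n) - 1) / rec$fs, m1 = rec$m1, m2 = rec$m2)
    csv <- file.path(dir, paste0(rec$id, ".csv"))
    utils::write.csv(df, csv, row.names = FALSE)
    side <- list(
      valid_intervals = unname(apply(rec$valid_intervals, 1, function(r) c(r[1], r[2]), simplify = FALSE)),
      obstetric = as.list(rec$obstetric),
      ttd_days = rec$ttd_days)
    jsonlite::write_json(side, file.path(dir, paste0(rec$id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    data.frame(id = rec$id, file = basename(csv), ttd_days = rec$ttd_days,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
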