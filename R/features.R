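#' @useDynLib ehglabor, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Names of the 23 per-window EHG parameters
#'
#' Order: peak-to-peak amplitude; dominant frequencies DF1 (0.2-1 Hz) and DF2
#' (0.34-1 Hz); high-to-low band energy ratio; power-spectrum deciles D1-D9;
#' spectral moment ratio; binary and 6-state Lempel-Ziv complexity; sample,
#' fuzzy and spectral entropy; time reversibility; Poincare SD1, SD2 and their
#' ratio.
#' @export
ehg_feature_names <- function() {
  c("app", "df1", "df2", "hl_ratio", paste0("d", 1:9), "smr",
    "lz_bin", "lz_multi6", "sampen", "fuzzyen", "specen",
    "timerev", "sd1", "sd2", "sd1_sd2")
}

# Features that rise during contractile periods as labor approaches get the
# 90th percentile under trend-directed aggregation; the rest get the 10th.
ehg_increasing_features <- function() {
  c("app", "df1", "df2", "hl_ratio", paste0("d", 1:9), "timerev")
}

#' Estimate the power spectral density of one analysis window
#'
#' Mean-removed, Hamming-tapered one-sided periodogram over the full window,
#' giving a frequency resolution of `fs / length(window)` (1/120 Hz at the
#' default 120 s, 20 Hz windows) -- fine enough to resolve the narrow
#' 0.2-0.34 Hz low band. The density is scaled so that its integral equals the
#' taper-normalized time-domain power (Parseval).
#'
#' @param window numeric sample vector.
#' @param fs sampling rate in Hz.
#' @return List of class `ehg_psd` with `freqs` (Hz) and `power` (density).
#' @export
estimate_psd <- function(window, fs) {
  n <- length(window)
  x <- window - mean(window)
  if (all(x == 0)) {
    k <- 0:(n %/% 2)
    out <- list(freqs = k * fs / n, power = rep(0, length(k)), constant = TRUE)
    class(out) <- "ehg_psd"
    return(out)
  }
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  y <- x * w
  Y <- stats::fft(y)
  k <- 0:(n %/% 2)
  p <- (Mod(Y[k + 1])^2) / (fs * sum(w^2))
  # one-sided: double all bins except DC (and Nyquist when n is even)
  dbl <- rep(2, length(k))
  dbl[1] <- 1
  if (n %% 2 == 0) dbl[length(k)] <- 1
  out <- list(freqs = k * fs / n, power = dbl * p, constant = FALSE)
  class(out) <- "ehg_psd"
  out
}

#' Spectral EHG parameters from a window PSD
#'
#' Computes the dominant frequency in 0.2-1 Hz (DF1) and 0.34-1 Hz (DF2); the
#' high-to-low energy ratio (energy in 0.34-1 Hz over energy in 0.2-0.34 Hz);
#' the deciles D1-D9 of cumulative spectral power over the 0.2-1 Hz band (the
#' smallest grid frequency at which cumulative power reaches k/10 of the band
#' total); and the spectral moment ratio SMR = M(-1)/M(5) with
#' M(n) = sum power(f) * f^n over the same band.
#'
#' @param psd an `ehg_psd`.
#' @param band_df band for DF1, deciles and SMR (default `c(0.2, 1)` Hz).
#' @param fwl,fwh fast-wave low and high bands for the H/L ratio.
#' @param smr_orders the two moment orders of the SMR (default `c(-1, 5)`).
#' @return Named numeric vector `df1, df2, hl_ratio, d1..d9, smr`; undefined
#'   values (zero band power) are `NA`.
#' @export
spectral_features <- function(psd, band_df = c(0.2, 1), fwl = c(0.2, 0.34),
                              fwh = c(0.34, 1), smr_orders = c(-1, 5)) {
  f <- psd$freqs
  p <- psd$power
  out <- stats::setNames(rep(NA_real_, 13),
                         c("df1", "df2", "hl_ratio", paste0("d", 1:9), "smr"))
  if (isTRUE(psd$constant) || sum(p) == 0) return(out)

  in_df <- f >= band_df[1] & f <= band_df[2]
  in_df2 <- f >= fwh[1] & f <= fwh[2]
  if (any(in_df) && sum(p[in_df]) > 0)
    out["df1"] <- f[in_df][which.max(p[in_df])]
  if (any(in_df2) && sum(p[in_df2]) > 0)
    out["df2"] <- f[in_df2][which.max(p[in_df2])]

  e_low <- sum(p[f >= fwl[1] & f < fwl[2]])
  e_high <- sum(p[f >= fwh[1] & f <= fwh[2]])
  if (e_low > 0) out["hl_ratio"] <- e_high / e_low

  pb <- p[in_df]
  fb <- f[in_df]
  tot <- sum(pb)
  if (tot > 0) {
    cum <- cumsum(pb) / tot
    for (k in 1:9) out[paste0("d", k)] <- fb[which(cum >= k / 10)[1]]
    m_lo <- sum(pb * fb^smr_orders[1])
    m_hi <- sum(pb * fb^smr_orders[2])
    if (m_hi > 0) out["smr"] <- m_lo / m_hi
  }
  out
}

#' Peak-to-peak amplitude of a window
#' @param window numeric vector.
#' @return `max(window) - min(window)`.
#' @export
peak_to_peak <- function(window) max(window) - min(window)

#' Normalized Lempel-Ziv (LZ76) complexity
#'
#' Symbolizes the window (binary: above/below the median; multistate: `n_states`
#' equal-probability quantile bins), counts exhaustive-history phrases with the
#' LZ76 parsing rule, and normalizes: `c(n) * log(n, base = n_states) / n`.
#' Lower values indicate more regular signals.
#'
#' @param window numeric vector (length >= 2).
#' @param n_states number of symbols, 2 (binary) or 6 (multistate) in the
#'   standard EHG parameter set.
#' @return Normalized complexity (a constant window gives the minimal value,
#'   `2 * log(n, n_states) / n`).
#' @export
lempel_ziv <- function(window, n_states = 2) {
  n <- length(window)
  if (n < 2) stop("window too short for Lempel-Ziv complexity")
  if (n_states == 2) {
    s <- as.integer(window > stats::median(window))
  } else {
    qs <- stats::quantile(window, probs = seq(0, 1, length.out = n_states + 1),
                          type = 7, names = FALSE)
    qs <- qs[-c(1, length(qs))]
    s <- findInterval(window, unique(qs))
  }
  c_n <- lz76_count_cpp(s)
  c_n * (log(n) / log(n_states)) / n
}

#' Sample entropy of a window
#'
#' `-ln(A/B)` where `B` counts template pairs of length `m` within Chebyshev
#' distance `r` (self-matches excluded; templates start at 1..N-m for both
#' lengths) and `A` the same for length `m + 1`.
#'
#' @param window numeric vector.
#' @param m embedding dimension (default 2).
#' @param r tolerance; default `0.15 * sd(window)`.
#' @return Sample entropy in nats; `NA` if the window is constant or no
#'   matches exist (`A = 0` or `B = 0`).
#' @export
sample_entropy <- function(window, m = 2, r = 0.15 * stats::sd(window)) {
  if (is.na(r) || r <= 0) return(NA_real_)
  cnt <- sampen_counts_cpp(as.numeric(window), as.integer(m), r)
  if (cnt$B == 0 || cnt$A == 0) return(NA_real_)
  -log(cnt$A / cnt$B)
}

#' Fuzzy entropy of a window
#'
#' Like sample entropy, but templates are mean-centered and the hard match
#' indicator is replaced by the soft membership `exp(-(d/r)^grad)`, so the
#' estimate stays finite where sample entropy is undefined.
#'
#' @inheritParams sample_entropy
#' @param grad membership gradient exponent (default 2).
#' @return `-ln(phi_{m+1} / phi_m)` in nats; `NA` for constant windows.
#' @export
fuzzy_entropy <- function(window, m = 2, r = 0.15 * stats::sd(window), grad = 2) {
  if (is.na(r) || r <= 0) return(NA_real_)
  s <- fuzzyen_sums_cpp(as.numeric(window), as.integer(m), r, grad)
  if (is.na(s$phi_m) || s$phi_m == 0 || s$phi_m1 == 0) return(NA_real_)
  -log(s$phi_m1 / s$phi_m)
}

#' Normalized spectral entropy
#'
#' Shannon entropy of the PSD normalized to a probability mass over the bins
#' inside `band`, divided by the log of the number of bins; 0 for a single
#' spectral line, 1 for an exactly flat in-band spectrum.
#'
#' @param psd an `ehg_psd`.
#' @param band analysis band in Hz (default the full 0.1-4 Hz EHG bandwidth).
#' @return Value in [0, 1], or `NA` when the in-band power is zero.
#' @export
spectral_entropy <- function(psd, band = c(0.1, 4)) {
  sel <- psd$freqs >= band[1] & psd$freqs <= band[2]
  p <- psd$power[sel]
  tot <- sum(p)
  if (length(p) < 2 || tot == 0 || is.na(tot)) return(NA_real_)
  q <- p / tot
  q <- q[q > 0]
  -sum(q * log(q)) / log(sum(sel))
}

#' Time reversibility
#'
#' Third moment of lagged differences, `mean((x_t - x_{t-lag})^3)`; zero for
#' time-symmetric signals (such as any linear Gaussian process), negated
#' exactly under time reversal.
#'
#' @param window numeric vector.
#' @param lag lag in samples (default 1).
#' @return Time reversibility in (signal units)^3.
#' @export
time_reversibility <- function(window, lag = 1) {
  n <- length(window)
  if (n <= lag) stop("window not longer than the lag")
  d <- window[(lag + 1):n] - window[1:(n - lag)]
  sum(d^3) / (n - lag)
}

#' Poincare plot descriptors
#'
#' SD1 and SD2 are the dispersions of the lag-`lag` Poincare cloud
#' perpendicular and parallel to the identity line:
#' `sd1 = sd((x_{i+lag} - x_i)/sqrt(2))`, `sd2 = sd((x_{i+lag} + x_i)/sqrt(2))`.
#' Their ratio indexes signal randomness (near 1 for white noise, small for
#' strongly low-pass signals).
#'
#' @param window numeric vector.
#' @param lag lag in samples (default 1).
#' @return Named vector `sd1, sd2, sd1_sd2` (`sd1_sd2` is `NA` when `sd2 = 0`).
#' @export
poincare <- function(window, lag = 1) {
  n <- length(window)
  if (n <= lag + 1) stop("window too short for Poincare descriptors")
  a <- window[1:(n - lag)]
  b <- window[(lag + 1):n]
  sd1 <- stats::sd((b - a) / sqrt(2))
  sd2 <- stats::sd((b + a) / sqrt(2))
  c(sd1 = sd1, sd2 = sd2, sd1_sd2 = if (sd2 == 0) NA_real_ else sd1 / sd2)
}

#' Compute the 23 EHG parameters for one window
#'
#' @param window numeric sample vector.
#' @param fs sampling rate in Hz.
#' @param params optional list overriding feature defaults (`m`, `r_factor`,
#'   `grad`, `band_df`, `fwl`, `fwh`, `smr_orders`, `specen_band`, `lag`).
#' @return Named numeric vector over [ehg_feature_names()]; undefined features
#'   are `NA` (sentinel), never imputed.
#' @export
window_features <- function(window, fs, params = list()) {
  p <- utils::modifyList(list(
    m = 2, r_factor = 0.15, grad = 2,
    band_df = c(0.2, 1), fwl = c(0.2, 0.34), fwh = c(0.34, 1),
    smr_orders = c(-1, 5), specen_band = c(0.1, 4), lag = 1), params)
  out <- stats::setNames(rep(NA_real_, 23), ehg_feature_names())
  out["app"] <- peak_to_peak(window)
  psd <- estimate_psd(window, fs)
  out[c("df1", "df2", "hl_ratio", paste0("d", 1:9), "smr")] <-
    spectral_features(psd, p$band_df, p$fwl, p$fwh, p$smr_orders)
  sdw <- stats::sd(window)
  out["lz_bin"] <- lempel_ziv(window, 2)
  out["lz_multi6"] <- lempel_ziv(window, 6)
  if (!is.na(sdw) && sdw > 0) {
    out["sampen"] <- sample_entropy(window, p$m, p$r_factor * sdw)
    out["fuzzyen"] <- fuzzy_entropy(window, p$m, p$r_factor * sdw, p$grad)
  }
  out["specen"] <- spectral_entropy(psd, p$specen_band)
  out["timerev"] <- time_reversibility(window, p$lag)
  out[c("sd1", "sd2", "sd1_sd2")] <- poincare(window, p$lag)
  out
}

#' Extract the per-window feature table of a recording
#'
#' @param windows an `ehg_windows` object from [cut_windows()].
#' @param params see [window_features()].
#' @return Data frame with `window_index`, `start_s` and the 23 feature
#'   columns, one row per window in time order.
#' @export
extract_features <- function(windows, params = list()) {
  stopifnot(inherits(windows, "ehg_windows"))
  rows <- lapply(seq_along(windows$windows), function(i) {
    window_features(windows$windows[[i]], windows$fs, params)
  })
  feat <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(window_index = seq_along(windows$windows),
                   start_s = windows$start_times), feat)
}
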