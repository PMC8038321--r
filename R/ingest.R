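#' Read a raw EHG recording with its annotation sidecar
#'
#' Reads a two-channel monopolar recording from CSV (columns
#' `time_s`, `m1`, `m2`) or EDF (channels `M1`, `M2`) together with a JSON
#' sidecar carrying the usable-signal intervals, obstetric covariates and time
#' to delivery. Missing obstetric fields are kept as `NA` and flagged via the
#' `missing_obstetric` element, never silently imputed.
#'
#' @param path path to the recording file.
#' @param format `"csv"` or `"edf"`.
#' @param sidecar path to the JSON sidecar; defaults to the recording path with
#'   a `.json` extension.
#' @param min_fs minimum acceptable input sampling rate (Hz). Real recordings
#'   must be sampled fast enough to represent the 0.1-4 Hz analysis band.
#' @return An `ehg_recording` with fields `id`, `fs`, `m1`, `m2`,
#'   `valid_intervals`, `obstetric`, `ttd_days`.
#' @export
read_recording <- function(path, format = c("csv", "edf"), sidecar = NULL,
                           min_fs = 20) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("recording file not found: ", path)
  if (is.null(sidecar)) sidecar <- sub("\\.[^.]+$", ".json", path)
  if (!file.exists(sidecar)) stop("sidecar file not found: ", sidecar)

  if (format == "csv") {
    df <- utils::read.csv(path)
    for (col in c("time_s", "m1", "m2"))
      if (!col %in% names(df)) stop("recording CSV is missing column \"", col, "\"")
    dt <- stats::median(diff(df$time_s))
    fs <- round(1 / dt, 6)  # undo accumulated floating error in the time column
    m1 <- df$m1
    m2 <- df$m2
  } else {
    edf <- read_edf(path)
    i1 <- match("M1", edf$labels)
    i2 <- match("M2", edf$labels)
    if (is.na(i1)) stop("EDF file is missing channel \"M1\"")
    if (is.na(i2)) stop("EDF file is missing channel \"M2\"")
    if (abs(edf$fs[i1] - edf$fs[i2]) > 1e-9)
      stop("channels M1 and M2 have different sampling rates")
    fs <- edf$fs[i1]
    m1 <- edf$signals[[i1]]
    m2 <- edf$signals[[i2]]
  }
  if (fs < min_fs)
    stop("sampling rate ", fs, " Hz is below the minimum of ", min_fs, " Hz")
  if (length(m1) != length(m2)) stop("channels m1 and m2 differ in length")

  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(side$ttd_days)) stop("sidecar is missing field \"ttd_days\"")
  vi <- side$valid_intervals
  if (is.null(vi)) vi <- matrix(c(0, length(m1) / fs), nrow = 1)
  vi <- matrix(as.numeric(unlist(vi)), ncol = 2, byrow = !is.matrix(vi))
  if (is.matrix(side$valid_intervals)) vi <- side$valid_intervals
  colnames(vi) <- c("start_s", "end_s")

  ob_names <- c("cervical_length_mm", "gestational_age_weeks", "maternal_age_years",
                "gestations", "parity", "abortions")
  obstetric <- stats::setNames(rep(NA_real_, 6), ob_names)
  for (nm in ob_names)
    if (!is.null(side$obstetric[[nm]])) obstetric[nm] <- as.numeric(side$obstetric[[nm]])

  rec <- list(
    id = sub("\\.[^.]+$", "", basename(path)),
    fs = fs, m1 = m1, m2 = m2,
    valid_intervals = vi,
    obstetric = obstetric,
    missing_obstetric = ob_names[is.na(obstetric)],
    ttd_days = as.numeric(side$ttd_days))
  class(rec) <- "ehg_recording"
  rec
}

# Chain of decimation stages with factors <= 10 (single large-factor IIR
# decimation is numerically fragile).
decimation_factors <- function(q) {
  out <- integer(0)
  while (q > 10) {
    f <- max(Filter(function(d) q %% d == 0, 2:10))
    if (length(f) == 0 || f == -Inf) stop("cannot factor decimation ratio ", q,
                                          " into stages of 10 or less")
    out <- c(out, f)
    q <- q / f
  }
  c(out, q)
}

#' Condition a recording to the analysis band and rate
#'
#' Forms the bipolar signal `m1 - m2`, decimates it to `fs_out` with
#' anti-alias filtering (chained stages of factor at most 10), removes the
#' mean, and applies a zero-phase (forward-backward) 5th-order Butterworth
#' band-pass over `band`. The usable-signal intervals are resampled into a
#' per-sample boolean mask.
#'
#' @param rec an `ehg_recording`.
#' @param band band-pass edges in Hz; default `c(0.1, 4)`, the EHG bandwidth.
#' @param fs_out output sampling rate in Hz; `rec$fs` must be an integer
#'   multiple of it.
#' @param order Butterworth order (applied twice via `filtfilt`).
#' @return A list of class `ehg_conditioned` with `id`, `fs`, `samples`,
#'   `valid_mask`.
#' @export
condition <- function(rec, band = c(0.1, 4), fs_out = 20, order = 5) {
  stopifnot(inherits(rec, "ehg_recording"))
  if (band[1] >= band[2]) stop("band edges must be increasing")
  if (band[2] >= fs_out / 2) stop("upper band edge must be below the output Nyquist rate")
  if (rec$fs < 2 * band[2]) stop("input sampling rate too low for the requested band")
  x <- rec$m1 - rec$m2
  fs <- rec$fs
  if (abs(fs - fs_out) > 1e-9) {
    q_total <- fs / fs_out
    if (abs(q_total - round(q_total)) > 1e-6)
      stop("input rate ", fs, " Hz is not an integer multiple of ", fs_out, " Hz")
    for (q in decimation_factors(round(q_total))) {
      if (q > 1) x <- signal::decimate(x, q, ftype = "iir")
    }
    fs <- fs_out
  }
  x <- x - mean(x)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, x)
  x <- x - mean(x)  # filter edge transients leave a residual offset

  n <- length(x)
  mask <- rep(FALSE, n)
  t0 <- (seq_len(n) - 1) / fs
  for (i in seq_len(nrow(rec$valid_intervals))) {
    mask <- mask | (t0 >= rec$valid_intervals[i, 1] & t0 < rec$valid_intervals[i, 2])
  }
  out <- list(id = rec$id, fs = fs, samples = x, valid_mask = mask)
  class(out) <- "ehg_conditioned"
  out
}

#' Cut a conditioned signal into overlapping artifact-free analysis windows
#'
#' Windows advance on a regular grid of `win_s * (1 - overlap)` seconds from
#' the start of the recording; a window is kept only if every sample in it is
#' valid (fully inside the annotated usable intervals).
#'
#' @param sig an `ehg_conditioned` signal.
#' @param win_s window length in seconds (default 120).
#' @param overlap fractional overlap between consecutive windows (default 0.5).
#' @return A list of class `ehg_windows` with `id`, `fs`, `windows` (list of
#'   numeric vectors) and `start_times` (seconds).
#' @export
cut_windows <- function(sig, win_s = 120, overlap = 0.5) {
  stopifnot(inherits(sig, "ehg_conditioned"))
  if (overlap < 0 || overlap >= 1) stop("`overlap` must lie in [0, 1)")
  L <- round(win_s * sig$fs)
  n <- length(sig$samples)
  if (L > n) stop("window longer than the signal")
  step <- round(L * (1 - overlap))
  starts <- seq(1, n - L + 1, by = step)
  keep <- vapply(starts, function(s) all(sig$valid_mask[s:(s + L - 1)]), logical(1))
  starts <- starts[keep]
  if (length(starts) == 0)
    warning("recording ", sig$id, " has no fully valid analysis window")
  out <- list(
    id = sig$id, fs = sig$fs,
    windows = lapply(starts, function(s) sig$samples[s:(s + L - 1)]),
    start_times = (starts - 1) / sig$fs)
  class(out) <- "ehg_windows"
  out
}
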