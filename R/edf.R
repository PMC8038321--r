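#' Read a two-channel EDF file
#'
#' Minimal reader for European Data Format files: parses the ASCII header and
#' the 16-bit little-endian sample records, applies the per-channel physical
#' calibration, and returns the signals with their sampling rates. Sufficient
#' for monopolar abdominal EHG files with channels labelled `M1` and `M2`;
#' annotations and discontinuous files are not supported.
#'
#' @param path path to an EDF file.
#' @return A list with `labels`, `fs` (Hz per channel), and `signals` (list of
#'   numeric vectors in physical units).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_txt <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  version <- hdr_txt(8)
  hdr_txt(80)  # patient id
  hdr_txt(80)  # recording id
  hdr_txt(8); hdr_txt(8)  # start date, time
  header_bytes <- as.integer(hdr_txt(8))
  hdr_txt(44)  # reserved
  n_records <- as.integer(hdr_txt(8))
  record_dur <- as.numeric(hdr_txt(8))
  ns <- as.integer(hdr_txt(4))
  if (is.na(ns) || ns < 1) stop("EDF header: invalid signal count")
  field <- function(w) vapply(seq_len(ns), function(i) hdr_txt(w), character(1))
  labels <- field(16)
  field(80)  # transducer
  field(8)   # physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)  # prefiltering
  n_samp <- as.integer(field(8))
  field(32)  # reserved
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  signals <- vector("list", ns)
  for (i in seq_len(ns)) signals[[i]] <- numeric(n_records * n_samp[i])
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = n_samp[i], size = 2, endian = "little")
      signals[[i]][((r - 1) * n_samp[i] + 1):(r * n_samp[i])] <- gain[i] * raw + offset[i]
    }
  }
  list(labels = labels, fs = n_samp / record_dur, signals = signals,
       n_records = n_records, record_dur = record_dur, header_bytes = header_bytes,
       version = version)
}
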