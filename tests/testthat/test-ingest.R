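test_that("synthetic CSV recordings round-trip through the reader", {
  cfg <- synth_config(n_imminent = 1, n_control = 1, duration_s = 300, seed = 17)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  rec <- read_recording(file.path(dir, "rec001.csv"), "csv")
  orig <- coh[[1]]
  expect_equal(rec$fs, 20)
  expect_equal(rec$m1, orig$m1, tolerance = 1e-12)
  expect_equal(rec$m2, orig$m2, tolerance = 1e-12)
  expect_equal(rec$ttd_days, orig$ttd_days)
  expect_equal(rec$obstetric, orig$obstetric)
  expect_equal(unname(rec$valid_intervals), unname(orig$valid_intervals))
  expect_length(rec$missing_obstetric, 0)

  manifest <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(manifest), 2)
})

test_that("reader validation names the offending field", {
  dir <- withr::local_tempdir()
  df <- data.frame(time_s = (0:99) / 20, m1 = rnorm(100))
  write.csv(df, file.path(dir, "bad.csv"), row.names = FALSE)
  jsonlite::write_json(list(ttd_days = 10), file.path(dir, "bad.json"),
                       auto_unbox = TRUE)
  expect_error(read_recording(file.path(dir, "bad.csv"), "csv"), "\"m2\"")
  expect_error(read_recording(file.path(dir, "nothere.csv"), "csv"), "not found")

  df2 <- data.frame(time_s = (0:99) / 10, m1 = rnorm(100), m2 = rnorm(100))
  write.csv(df2, file.path(dir, "slow.csv"), row.names = FALSE)
  jsonlite::write_json(list(ttd_days = 10), file.path(dir, "slow.json"),
                       auto_unbox = TRUE)
  expect_error(read_recording(file.path(dir, "slow.csv"), "csv", min_fs = 40),
               "sampling rate")
})

test_that("EDF files read back consistently with an independent header parse", {
  dir <- withr::local_tempdir()
  fs_in <- 500
  n_sec <- 4
  tt <- seq(0, n_sec - 1 / fs_in, by = 1 / fs_in)
  m1 <- 50 * sin(2 * pi * 0.5 * tt)
  m2 <- 20 * cos(2 * pi * 0.3 * tt)
  path <- file.path(dir, "rec.edf")
  write_edf_fixture(path, list(m1, m2), fs_in, c("M1", "M2"))
  jsonlite::write_json(list(ttd_days = 12,
                            valid_intervals = list(c(0, n_sec))),
                       file.path(dir, "rec.json"), auto_unbox = TRUE)
  rec <- read_recording(path, "edf", min_fs = 40)
  expect_equal(rec$fs, 500)
  expect_length(rec$m1, n_sec * fs_in)
  # quantization error bounded by the digital resolution
  expect_lt(max(abs(rec$m1 - m1)), 2000 / 65535 + 1e-9)
  expect_lt(max(abs(rec$m2 - m2)), 2000 / 65535 + 1e-9)

  # independent parse of the fixed-layout ASCII header
  con <- file(path, "rb")
  hdr <- rawToChar(readBin(con, "raw", 256))
  close(con)
  expect_equal(as.integer(substr(hdr, 237, 244)), n_sec)   # record count
  expect_equal(as.integer(substr(hdr, 253, 256)), 2L)      # signal count

  bad <- file.path(dir, "bad.edf")
  write_edf_fixture(bad, list(m1, m2), fs_in, c("M1", "OTHER"))
  file.copy(file.path(dir, "rec.json"), file.path(dir, "bad.json"))
  expect_error(read_recording(bad, "edf"), "\"M2\"")
})

test_that("conditioning cancels common mode and respects the band", {
  n <- 300 * 20
  base <- rnorm(n)
  rec <- structure(list(id = "x", fs = 20, m1 = base, m2 = base,
                        valid_intervals = matrix(c(0, 300), 1),
                        obstetric = NULL, ttd_days = 10),
                   class = "ehg_recording")
  out <- condition(rec)
  expect_true(all(abs(out$samples) < 1e-9))

  tt <- seq(0, 300 - 0.05, by = 0.05)
  mk_rec <- function(sig) structure(
    list(id = "x", fs = 20, m1 = sig, m2 = rep(0, length(sig)),
         valid_intervals = matrix(c(0, 300), 1), obstetric = NULL, ttd_days = 10),
    class = "ehg_recording")
  inband <- sin(2 * pi * 0.5 * tt)
  out1 <- condition(mk_rec(inband))
  rms <- function(x) sqrt(mean(x^2))
  core <- 400:5600  # ignore filter edge transients
  expect_lt(abs(rms(out1$samples[core]) - rms(inband[core])) / rms(inband[core]), 0.05)
  expect_lt(abs(mean(out1$samples)), 1e-6 * sd(out1$samples))

  outband <- sin(2 * pi * 6 * tt)
  rec6 <- structure(list(id = "x", fs = 40, m1 = sin(2 * pi * 6 * seq(0, 300 - 1/40, by = 1/40)),
                         m2 = rep(0, 12000), valid_intervals = matrix(c(0, 300), 1),
                         obstetric = NULL, ttd_days = 10), class = "ehg_recording")
  out2 <- condition(rec6)
  expect_lt(rms(out2$samples[core]), 0.05 * rms(outband))
})

test_that("a 500 Hz half-hour recording decimates to 36000 samples", {
  fs_in <- 500
  tt <- seq(0, 1800 - 1 / fs_in, by = 1 / fs_in)
  rec <- structure(list(id = "x", fs = fs_in, m1 = sin(2 * pi * 0.5 * tt),
                        m2 = rep(0, length(tt)),
                        valid_intervals = matrix(c(0, 1800), 1),
                        obstetric = NULL, ttd_days = 10),
                   class = "ehg_recording")
  out <- condition(rec)
  expect_length(out$samples, 36000)
  expect_equal(out$fs, 20)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(abs(rms(out$samples[2000:34000]) - 1 / sqrt(2)) / (1 / sqrt(2)), 0.05)
})

test_that("conditioning an already conditioned signal is nearly idempotent", {
  cfg <- synth_config(n_imminent = 1, n_control = 1, duration_s = 600, seed = 19)
  rec <- generate_cohort(cfg)[[1]]
  once <- condition(rec)
  rec2 <- structure(list(id = "x", fs = 20, m1 = once$samples,
                         m2 = rep(0, length(once$samples)),
                         valid_intervals = matrix(c(0, 600), 1),
                         obstetric = NULL, ttd_days = 10),
                    class = "ehg_recording")
  twice <- condition(rec2)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(abs(rms(twice$samples) - rms(once$samples)) / rms(once$samples), 0.02)
})

test_that("window cutting follows the overlap grid and validity rule", {
  sig <- fake_conditioned(rnorm(36000))
  ws <- cut_windows(sig)
  expect_length(ws$windows, 29)
  expect_true(all(vapply(ws$windows, length, integer(1)) == 2400))
  expect_equal(diff(ws$start_times), rep(60, 28))
  expect_length(cut_windows(sig, overlap = 0)$windows, 15)

  # invalid block [500, 600) removes exactly the windows that touch it
  mask <- rep(TRUE, 36000)
  mask[(500 * 20 + 1):(600 * 20)] <- FALSE
  ws2 <- cut_windows(fake_conditioned(rnorm(36000), valid_mask = mask))
  bad <- matrix(c(500, 600), 1)
  expect_length(ws2$windows, window_count_oracle(1800, 120, 60, bad))
  expect_false(any(ws2$start_times > 380 & ws2$start_times < 600))

  # window count never increases as invalid time grows
  counts <- vapply(c(0, 100, 300, 700), function(bad_len) {
    m <- rep(TRUE, 36000)
    if (bad_len > 0) m[(500 * 20 + 1):((500 + bad_len) * 20)] <- FALSE
    length(cut_windows(fake_conditioned(rnorm(36000), valid_mask = m))$windows)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))

  expect_warning(
    cut_windows(fake_conditioned(rnorm(3000), valid_mask = rep(FALSE, 3000))),
    "no fully valid")
})
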