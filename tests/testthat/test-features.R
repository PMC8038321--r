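fs <- 20
t120 <- seq(0, 120 - 1 / fs, by = 1 / fs)

test_that("periodogram locates pure tones and satisfies Parseval", {
  x <- sin(2 * pi * 0.5 * t120)
  psd <- estimate_psd(x, fs)
  expect_equal(psd$freqs[which.max(psd$power)], 0.5)
  expect_equal(diff(psd$freqs)[1], 1 / 120)

  set.seed(42)
  w <- rnorm(2400)
  psd <- estimate_psd(w, fs)
  ham <- 0.54 - 0.46 * cos(2 * pi * seq(0, 2399) / 2399)
  tapered_power <- sum(((w - mean(w)) * ham)^2) / sum(ham^2)
  integrated <- sum(psd$power) * fs / 2400
  expect_lt(abs(integrated - tapered_power) / tapered_power, 0.01)

  x2 <- sin(2 * pi * 0.25 * t120) + sin(2 * pi * 0.6 * t120)
  psd2 <- estimate_psd(x2, fs)
  p1 <- psd2$power[which.min(abs(psd2$freqs - 0.25))]
  p2 <- psd2$power[which.min(abs(psd2$freqs - 0.6))]
  expect_lt(abs(p1 - p2) / max(p1, p2), 0.05)
})

test_that("spectral features behave on degenerate and constructed spectra", {
  tone <- sin(2 * pi * 0.5 * t120)
  sf <- spectral_features(estimate_psd(tone, fs))
  expect_equal(unname(sf["df1"]), 0.5)
  expect_equal(unname(sf["df2"]), 0.5)
  for (k in 1:9) expect_lt(abs(sf[[paste0("d", k)]] - 0.5), 1 / 120 + 1e-12)

  two <- sin(2 * pi * 0.25 * t120) + sin(2 * pi * 0.6 * t120)
  sf2 <- spectral_features(estimate_psd(two, fs))
  expect_lt(abs(sf2[["hl_ratio"]] - 1), 0.1)

  # exactly flat constructed PSD on a fine grid covering 0.2-1 Hz
  freqs <- seq(0.1, 4, by = 1 / 1200)
  flat <- structure(list(freqs = freqs, power = as.numeric(freqs >= 0.2 & freqs <= 1),
                         constant = FALSE), class = "ehg_psd")
  sff <- spectral_features(flat)
  expect_lt(abs(sff[["d5"]] - 0.6), 2 / 1200)
  expect_lt(max(abs(diff(sapply(1:9, function(k) sff[[paste0("d", k)]])) - 0.08)),
            2 / 1200)

  expect_true(all(is.na(spectral_features(estimate_psd(rep(3, 2400), fs)))))
})

test_that("peak-to-peak amplitude equals the scan oracle", {
  expect_equal(peak_to_peak(rep(5, 100)), 0)
  expect_equal(peak_to_peak(sin(2 * pi * 0.5 * t120)), 2, tolerance = 1e-3)
  set.seed(3)
  x <- cumsum(rnorm(500))
  expect_identical(peak_to_peak(x), max(x) - min(x))
})

test_that("LZ76 phrase counts match definition-based parses", {
  # constant sequence: exhaustive history has exactly 2 phrases
  n <- 2400
  expect_equal(lempel_ziv(rep(1, n), 2), 2 * log2(n) / n)

  # alternating and short random sequences against the exhaustive-history oracle
  lz_count <- function(x, states) {
    lempel_ziv(x, states) * length(x) / (log(length(x)) / log(states))
  }
  alt <- rep(c(0, 1), 16)
  expect_equal(lz_count(alt + runif(32, 0, 0.1), 2),
               lz76_oracle(as.integer(alt)))
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(20:40, 1))
    s_bin <- as.integer(x > median(x))
    expect_equal(lz_count(x, 2), lz76_oracle(s_bin))
  }
})

test_that("Lempel-Ziv complexity orders noise above a slow sine", {
  set.seed(5)
  tsin <- sin(2 * pi * 0.3 * t120)
  for (i in 1:20) {
    noise <- runif(2400)
    expect_gt(lempel_ziv(noise, 2), 0.9)
    expect_gt(lempel_ziv(noise, 2), lempel_ziv(tsin + rnorm(2400, 0, 1e-6), 2))
  }
})

test_that("sample entropy matches the quadratic oracle and known limits", {
  # pure ramp: every template pair at constant difference, A/B = 1
  expect_equal(sample_entropy(seq(0, 1, length.out = 300), r = 0.1), 0)
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(300)
    expect_equal(sample_entropy(x), sampen_oracle(x), tolerance = 1e-12)
  }
  # iid noise is less regular than a slow sine at matched SD
  t300 <- seq(0, 15 - 0.05, by = 0.05)
  for (i in 1:20) {
    noise <- rnorm(300)
    sine <- sin(2 * pi * 0.3 * t300) * sd(noise) / sd(sin(2 * pi * 0.3 * t300))
    expect_gt(sample_entropy(noise), sample_entropy(sine))
  }
})

test_that("fuzzy entropy matches the quadratic oracle and stays finite", {
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(300)
    expect_equal(fuzzy_entropy(x), fuzzyen_oracle(x), tolerance = 1e-10)
  }
  expect_true(is.na(fuzzy_entropy(rep(2, 300))))
  # a window engineered so no m+1 template pair matches (sampen undefined)
  # but soft membership keeps fuzzy entropy finite
  base <- c(0, 0.001, 50, 0, 0.001, -50)
  x <- c(base, seq(100, 700, length.out = 294))
  r <- 0.01
  expect_true(is.na(sample_entropy(x, r = r)))
  expect_true(is.finite(fuzzy_entropy(x, r = r)))
})

test_that("spectral entropy hits its delta and uniform limits", {
  freqs <- seq(0.1, 4, by = 1 / 120)
  delta <- structure(list(freqs = freqs,
                          power = as.numeric(seq_along(freqs) == 50),
                          constant = FALSE), class = "ehg_psd")
  expect_equal(spectral_entropy(delta), 0)
  unif <- structure(list(freqs = freqs, power = rep(2, length(freqs)),
                         constant = FALSE), class = "ehg_psd")
  expect_equal(spectral_entropy(unif), 1)
  set.seed(2)
  noise <- rnorm(2400)
  tone <- sin(2 * pi * 0.5 * t120)
  expect_gt(spectral_entropy(estimate_psd(noise, fs)),
            spectral_entropy(estimate_psd(tone, fs)))
})

test_that("time reversibility is zero for sines, antisymmetric, negative for sawtooth", {
  tone <- sin(2 * pi * 0.5 * t120)  # integer number of cycles in the window
  # the N-1 lagged differences miss one sample of the last cycle, leaving a
  # residue of order (2*sin(pi*f/fs))^3 / N ~ 1e-6; zero only in the limit
  expect_lt(abs(time_reversibility(tone)), 1e-4)
  set.seed(4)
  x <- cumsum(rnorm(400))
  expect_equal(time_reversibility(rev(x)), -time_reversibility(x))
  # slow rise, fast fall
  saw <- rep(c(seq(0, 1, length.out = 19), 0), 20)
  d <- diff(saw)
  expect_equal(time_reversibility(saw), sum(d^3) / length(d))
  expect_lt(time_reversibility(saw), 0)
})

test_that("Poincare descriptors follow the lag-covariance identities", {
  expect_true(is.na(poincare(rep(1, 100))["sd1_sd2"]))
  expect_equal(unname(poincare(rep(1, 100))[c("sd1", "sd2")]), c(0, 0))
  set.seed(6)
  x <- rnorm(5000)
  pc <- poincare(x)
  expect_equal(unname(pc["sd1_sd2"]), 1, tolerance = 0.05)
  # identity: sd1^2 ~ var - lag1cov, sd2^2 ~ var + lag1cov
  v <- var(x)
  cv <- cov(x[-length(x)], x[-1])
  expect_equal(unname(pc["sd1"])^2, v - cv, tolerance = 0.01)
  expect_equal(unname(pc["sd2"])^2, v + cv, tolerance = 0.01)
  # strongly low-pass signal: points hug the identity line
  lp <- as.numeric(stats::filter(rnorm(5000), rep(1, 20), sides = 1))[-(1:20)]
  expect_lt(unname(poincare(lp)["sd1_sd2"]), 0.5)
})

test_that("feature vector has 23 fields and survives degenerate windows", {
  set.seed(8)
  f <- window_features(rnorm(2400), fs)
  expect_length(f, 23)
  expect_identical(names(f), ehg_feature_names())

  fz <- window_features(rep(0, 2400), fs)
  expect_equal(unname(fz["app"]), 0)
  expect_true(is.na(fz["sampen"]))
  expect_length(fz, 23)
})

test_that("features partition into amplitude-equivariant and invariant sets", {
  set.seed(10)
  x <- as.numeric(stats::filter(rnorm(2600), rep(1, 4), sides = 1))[-(1:4)] +
    0.3 * sin(2 * pi * 0.4 * seq(0, 129.75, by = 0.05))[1:2596]
  x <- x[1:2400]
  c_scale <- 3.7
  f1 <- window_features(x, fs)
  f2 <- window_features(c_scale * x, fs)
  lin <- c("app", "sd1", "sd2")
  cub <- "timerev"
  inv <- setdiff(ehg_feature_names(), c(lin, cub))
  for (nm in lin) expect_equal(f2[[nm]], c_scale * f1[[nm]], tolerance = 1e-6)
  expect_equal(f2[[cub]], c_scale^3 * f1[[cub]], tolerance = 1e-6)
  for (nm in inv) expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-6)
})

test_that("power-spectrum deciles are monotone on random windows", {
  set.seed(12)
  for (i in 1:25) {
    x <- as.numeric(stats::filter(rnorm(2410), runif(3), sides = 1))[-(1:10)]
    f <- window_features(x, fs)
    dec <- as.numeric(f[paste0("d", 1:9)])
    expect_true(all(diff(dec) >= 0))
  }
})
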