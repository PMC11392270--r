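test_that("band table matches the canonical ten-band configuration", {
  b <- ehg_bands()
  expect_equal(nrow(b), 10L)
  expect_true(all(b$f_lo < b$f_hi))
  expect_equal(b$f_lo[b$band == "B0Lp"], 0.125)
  expect_equal(b$f_hi[b$band == "B0Lp"], 0.575)
  expect_equal(unname(unlist(b[b$band == "B3", c("f_lo", "f_hi")])),
               c(3.5, 5.0))
  expect_error(ehg_band("B0H"), "unknown band")
})

test_that("feature sets have the study sizes and exclusions", {
  expect_equal(nrow(ehg_feature_set("set1")), 76L)
  expect_equal(nrow(ehg_feature_set("set2")), 60L)
  expect_equal(nrow(ehg_feature_set("set3")), 30L)
  expect_equal(nrow(ehg_feature_set("set4")), 24L)
  s1 <- ehg_feature_set("set1")
  expect_false(any(s1$feature == "PA" & s1$band %in% c("B0", "B0b")))
  expect_false(any(ehg_feature_set("set2")$band %in% c("B0Hp", "Bb")))
  expect_true("PA_S3_B0Lp" %in% s1$name)
})

test_that("bandpass filter preserves in-band tones and rejects out-of-band", {
  fs <- 20
  t <- seq_len(6000) / fs
  inband <- bandpass_filter(sin(2 * pi * 0.3 * t), "B0Lp", fs)
  mid <- 1000:5000
  expect_gt(max(abs(inband[mid])), 0.95)
  out <- bandpass_filter(sin(2 * pi * 3 * t), "B0Lp", fs)
  atten_db <- 20 * log10(max(abs(out[mid])))
  expect_lt(atten_db, -40)
  expect_equal(bandpass_filter(rep(0, 6000), "B1", fs), rep(0, 6000))
  expect_error(bandpass_filter(rnorm(6000), "B3", fs = 8), "Nyquist")
})

test_that("power spectrum: tone localization and Parseval consistency", {
  fs <- 20
  n <- 2000
  x <- sin(2 * pi * 0.5 * seq_len(n) / fs)
  sp <- power_spectrum(x, fs)
  expect_true(all(sp$power >= 0))
  expect_equal(sp$freq[which.max(sp$power)], 0.5, tolerance = 1 / 100)
  w <- withr::with_seed(3, rnorm(n))
  spw <- power_spectrum(w, fs)
  # one-sided sum: double the interior bins
  tot <- (2 * sum(spw$power) - spw$power[1] -
            ifelse(n %% 2 == 0, spw$power[nrow(spw)], 0)) / n
  expect_equal(tot, mean(w^2), tolerance = 0.05)
  spc <- power_spectrum(rep(2, 100), fs)
  expect_gt(spc$power[1], 0)
  expect_equal(max(spc$power[-1]), 0, tolerance = 1e-20)
})

test_that("PF and MF match independent direct-DFT oracles to 1e-9", {
  fs <- 20
  x <- fixture_signal(n = 1200, fs = fs)
  sp <- power_spectrum(x, fs)
  for (band in c("B0", "B0Lp", "B1", "B0b")) {
    bd <- ehg_band(band)
    expect_equal(peak_frequency(sp, band),
                 oracle_pf(x, fs, bd$f_lo, bd$f_hi), tolerance = 1e-9,
                 info = band)
    expect_equal(median_frequency(sp, band),
                 oracle_mf(x, fs, bd$f_lo, bd$f_hi), tolerance = 1e-9,
                 info = band)
  }
})

test_that("PF picks the larger of two in-band peaks", {
  fs <- 20
  t <- seq_len(3000) / fs
  x <- sin(2 * pi * 0.2 * t) + 2 * sin(2 * pi * 0.4 * t)
  expect_equal(peak_frequency(power_spectrum(x, fs), "B0Lp"), 0.4,
               tolerance = 0.01)
})

test_that("MF of a flat in-band spectrum sits near the band midpoint", {
  fs <- 20
  n <- 4000
  sp <- tibble::tibble(freq = (0:(n / 2)) * fs / n,
                       power = rep(1, n / 2 + 1))
  attr(sp, "fs") <- fs
  attr(sp, "M") <- n
  mf <- median_frequency(sp, "B1")   # 1.0 - 2.2 Hz
  expect_equal(mf, 1.6, tolerance = 2 * fs / n + 1e-9)
  sp0 <- sp
  sp0$power <- rep(0, nrow(sp0))
  expect_error(median_frequency(sp0, "B1"), "zero in-band power")
})

test_that("normalized peak amplitude is a spectral ratio with PA(B0) = 1", {
  fs <- 20
  withr::with_seed(11, {
    for (i in 1:10) {
      x <- rnorm(1500) + sin(2 * pi * runif(1, 0.1, 0.9) *
                               seq_len(1500) / fs)
      expect_equal(peak_amplitude_normalized(x, "B0", fs, trim_s = 5), 1.0,
                   tolerance = 1e-12)
    }
  })
  # tone at 0.3 Hz (amp 1) and 1.5 Hz (amp 1/2): power ratio 1/4
  t <- seq_len(18000) / fs
  x <- sin(2 * pi * 0.3 * t) + 0.5 * sin(2 * pi * 1.5 * t)
  pa <- peak_amplitude_normalized(x, "B1", fs)
  expect_equal(pa, 0.25, tolerance = 0.02)
  expect_gte(pa, 0)
})

test_that("sample entropy equals the O(N^2) brute-force oracle exactly", {
  x <- withr::with_seed(7, rnorm(2000))
  expect_equal(sample_entropy(x), oracle_se(x), tolerance = 1e-12)
  x2 <- withr::with_seed(8, arima.sim(list(ar = 0.9), 800))
  expect_equal(sample_entropy(as.numeric(x2), m = 2L, r_frac = 0.2),
               oracle_se(as.numeric(x2), m = 2L, r_frac = 0.2),
               tolerance = 1e-12)
})

test_that("sample entropy orders periodic below shuffled", {
  saw <- rep(seq(-1, 1, length.out = 20), 50)
  shuf <- withr::with_seed(5, sample(saw))
  expect_lt(sample_entropy(saw), sample_entropy(shuf))
})

test_that("sample entropy degenerate branch matches the printed fallback", {
  # alternating series with growing swings: no extended template matches
  x <- c(0, 10, -10, 20, -20, 30, -30, 40, -40, 50)
  n <- length(x)
  m <- 3L
  expect_equal(sample_entropy(x, m = m), -log((n - m) / (n - m - 1)))
  expect_lt(sample_entropy(x, m = m), 0)  # negative as printed
  expect_equal(sample_entropy(x, m = m, fallback_sign_corrected = TRUE),
               log((n - m) / (n - m - 1)))
  expect_error(sample_entropy(c(1, 2, 3)), "too short")
})

test_that("sample entropy is non-increasing in the tolerance r", {
  x <- withr::with_seed(9, rnorm(600))
  ses <- vapply(c(0.1, 0.15, 0.25, 0.5), function(r) {
    sample_entropy(x, r_frac = r)
  }, 1.0)
  expect_true(all(diff(ses) <= 1e-12))
})

test_that("features are invariant to positive rescaling of the signal", {
  fs <- 20
  x <- fixture_signal(n = 1600, fs = fs)
  sp1 <- power_spectrum(x, fs)
  sp2 <- power_spectrum(7.3 * x, fs)
  expect_equal(peak_frequency(sp1, "B0Lp"), peak_frequency(sp2, "B0Lp"))
  expect_equal(median_frequency(sp1, "B1"), median_frequency(sp2, "B1"))
  expect_equal(peak_amplitude_normalized(x, "B0Lp", fs, trim_s = 5),
               peak_amplitude_normalized(7.3 * x, "B0Lp", fs, trim_s = 5),
               tolerance = 1e-7)
  expect_equal(sample_entropy(x), sample_entropy(7.3 * x),
               tolerance = 1e-9)
})

test_that("extract_features returns one value per spec, deterministically", {
  rec <- generate_record("premature", fs = 20, duration_s = 120, seed = 21)
  specs <- ehg_feature_set("set4")
  fv1 <- extract_features(rec, specs, trim_s = 5)
  fv2 <- extract_features(rec, specs, trim_s = 5)
  expect_identical(fv1, fv2)
  expect_equal(ncol(fv1), 2L + nrow(specs))
  expect_false(anyNA(fv1))
  expect_equal(fv1$label, "premature")
  # PF/MF stay inside their band (within one bin)
  parsed <- parse <- ehg_feature_set("set4")
  for (i in seq_len(nrow(parsed))) {
    if (parsed$feature[i] %in% c("PF", "MF")) {
      bd <- ehg_band(parsed$band[i])
      v <- fv1[[parsed$name[i]]]
      expect_gte(v, bd$f_lo - 0.01)
      expect_lte(v, bd$f_hi + 0.01)
    }
  }
})
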