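# Independent brute-force oracles, deliberately written against the
# definitions rather than the package implementation.

# direct O(N^2) DFT power spectrum: P(k) = |sum x_n e^{-2pi i k n / N}|^2 / N
oracle_spectrum <- function(x) {
  n <- length(x)
  ks <- 0:floor(n / 2)
  vapply(ks, function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n))
    (re^2 + im^2) / n
  }, 1.0)
}

# half-open band bins [ceil(f_lo M / fs), ceil(f_hi M / fs)), 0-based k
oracle_band_k <- function(n, fs, f_lo, f_hi) {
  k <- ceiling(f_lo * n / fs):(ceiling(f_hi * n / fs) - 1L)
  k[k <= floor(n / 2)]
}

oracle_pf <- function(x, fs, f_lo, f_hi) {
  p <- oracle_spectrum(x)
  k <- oracle_band_k(length(x), fs, f_lo, f_hi)
  k[which.max(p[k + 1L])] * fs / length(x)
}

oracle_mf <- function(x, fs, f_lo, f_hi) {
  p <- oracle_spectrum(x)
  k <- oracle_band_k(length(x), fs, f_lo, f_hi)
  pk <- p[k + 1L]
  j <- which(cumsum(pk) >= sum(pk) / 2)[1L]
  k[j] * fs / length(x)
}

# O(N^2) sample entropy with the package's documented counting convention
oracle_se <- function(x, m = 3L, r_frac = 0.15,
                      fallback_sign_corrected = FALSE) {
  n <- length(x)
  r <- r_frac * sd(x)
  n_m <- n - m + 1L        # number of length-m templates
  cm <- 0
  cm1 <- 0
  for (i in 1:(n_m - 1L)) {
    js <- (i + 1L):n_m
    d <- rep(0, length(js))
    for (k in 0:(m - 1L)) {
      d <- pmax(d, abs(x[i + k] - x[js + k]))
    }
    match_m <- d <= r
    cm <- cm + sum(match_m)
    ext <- js <= n - m & i <= n - m   # both extendable to length m+1
    if (i <= n - m) {
      d1 <- abs(x[i + m] - x[js + m])
      cm1 <- cm1 + sum(match_m & ext & d1 <= r)
    }
  }
  if (cm1 != 0 && cm != 0) {
    -log(cm1 / cm)
  } else {
    v <- -log((n - m) / (n - m - 1))
    if (fallback_sign_corrected) abs(v) else v
  }
}

# Mann-Whitney pair-counting AUC, ties counted one half
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == "premature"]
  neg <- scores[labels == "term"]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# small deterministic multi-tone signal used in several spectral tests
fixture_signal <- function(n = 1200, fs = 20, seed = 42) {
  withr::with_seed(seed, {
    t <- seq_len(n) / fs
    sin(2 * pi * 0.3 * t) + 0.5 * sin(2 * pi * 1.5 * t) +
      0.2 * rnorm(n)
  })
}

# tiny feature table with a planted separable feature, for selection tests
toy_feature_table <- function(n_min = 12, n_maj = 30, n_noise = 3,
                              seed = 99, gap = 3) {
  withr::with_seed(seed, {
    n <- n_min + n_maj
    lab <- c(rep("premature", n_min), rep("term", n_maj))
    tab <- tibble::tibble(
      record_id = sprintf("r%03d", seq_len(n)),
      label = lab,
      signal = c(rnorm(n_min, gap), rnorm(n_maj, 0))
    )
    for (j in seq_len(n_noise)) {
      tab[[paste0("noise", j)]] <- rnorm(n)
    }
    tab
  })
}
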