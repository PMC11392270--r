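#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase) via
#' [signal::filtfilt()]. The filter transient at both ends is handled
#' downstream by [trim_transient()].
#'
#' @param x Numeric signal.
#' @param band One-row band tibble (see [ehg_band()]) or band name.
#' @param fs Sampling rate in Hz.
#' @param order Butterworth order (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, band, fs, order = 4L) {
  band <- as_band(band)
  if (band$f_hi > fs / 2) {
    stop("band upper edge ", band$f_hi, " Hz exceeds Nyquist (fs/2 = ",
         fs / 2, " Hz)", call. = FALSE)
  }
  if (band$f_lo <= 0 || band$f_lo >= band$f_hi) {
    stop("invalid band edges", call. = FALSE)
  }
  bf <- signal::butter(order, c(band$f_lo, band$f_hi) / (fs / 2),
                       type = "pass")
  if (length(x) <= 3L * filter_transient_len(bf)) {
    stop("signal too short for the filter transient", call. = FALSE)
  }
  as.numeric(signal::filtfilt(bf, x))
}

as_band <- function(band) {
  if (is.character(band)) return(ehg_band(band))
  stopifnot(is.data.frame(band), nrow(band) == 1L,
            all(c("f_lo", "f_hi") %in% names(band)))
  band
}

filter_transient_len <- function(bf) {
  3L * (max(length(bf$b), length(bf$a)) - 1L)
}

#' Trim filter transients from both signal ends
#'
#' @param x Filtered signal.
#' @param fs Sampling rate in Hz.
#' @param trim_s Seconds to drop from each end (default 15).
#' @return Shortened signal.
#' @export
trim_transient <- function(x, fs, trim_s = 15) {
  k <- round(trim_s * fs)
  if (2L * k >= length(x)) stop("trim longer than signal", call. = FALSE)
  if (k <= 0L) return(x)
  x[(k + 1L):(length(x) - k)]
}

#' Periodogram power spectrum
#'
#' Magnitude-squared DFT of the full signal, scaled by 1/M where M is the
#' signal length, reported over the non-negative frequencies. Bin k sits at
#' frequency k * fs / M, so the resolution is fs / M.
#'
#' @param x Numeric signal (length >= 2).
#' @param fs Sampling rate in Hz.
#' @return Tibble with columns `freq` (Hz) and `power`, with attributes
#'   `fs` and `M` (DFT length).
#' @export
power_spectrum <- function(x, fs) {
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  m <- length(x)
  xf <- fft(x)
  half <- floor(m / 2)
  p <- (Mod(xf[1:(half + 1L)])^2) / m
  sp <- tibble::tibble(freq = (0:half) * fs / m, power = p)
  attr(sp, "fs") <- fs
  attr(sp, "M") <- m
  sp
}

# indices of spectrum rows inside the half-open band [f_lo, f_hi)
band_bins <- function(sp, band) {
  band <- as_band(band)
  fs <- attr(sp, "fs")
  m <- attr(sp, "M")
  k_lo <- ceiling(band$f_lo * m / fs)
  k_hi <- ceiling(band$f_hi * m / fs)  # exclusive
  if (k_hi <= k_lo) stop("band contains no spectrum bins", call. = FALSE)
  k <- k_lo:(k_hi - 1L)
  k <- k[k <= floor(m / 2)]
  if (length(k) == 0L) stop("band contains no spectrum bins", call. = FALSE)
  k + 1L  # rows: row 1 is k = 0
}

#' Peak frequency of the in-band power spectrum
#'
#' Frequency of the largest in-band spectral component (first bin on ties).
#'
#' @param sp Spectrum from [power_spectrum()].
#' @param band Band tibble or name.
#' @return Frequency in Hz.
#' @export
peak_frequency <- function(sp, band) {
  rows <- band_bins(sp, band)
  sp$freq[rows[which.max(sp$power[rows])]]
}

#' Median frequency of the in-band power spectrum
#'
#' The frequency of the smallest in-band bin at which the cumulative in-band
#' power first reaches half of the total in-band power.
#'
#' @inheritParams peak_frequency
#' @return Frequency in Hz.
#' @export
median_frequency <- function(sp, band) {
  rows <- band_bins(sp, band)
  p <- sp$power[rows]
  tot <- sum(p)
  if (tot <= 0) stop("zero in-band power: median frequency undefined",
                     call. = FALSE)
  j <- which(cumsum(p) >= tot / 2)[1L]
  sp$freq[rows[j]]
}

#' Normalized peak amplitude
#'
#' Largest in-band component of the band-filtered signal's power spectrum,
#' divided by the largest component, within the reference band B0
#' (0.08--1.0 Hz), of the B0-filtered signal's power spectrum. Dimensionless;
#' identically 1.0 when `band` is the reference band itself.
#'
#' @param x Raw (unfiltered) signal.
#' @param band Band tibble or name.
#' @param fs Sampling rate in Hz.
#' @param trim_s Transient trim in seconds applied after filtering.
#' @return Dimensionless ratio >= 0.
#' @export
peak_amplitude_normalized <- function(x, band, fs, trim_s = 15) {
  band <- as_band(band)
  ref <- pa_reference_band()
  xb <- trim_transient(bandpass_filter(x, band, fs), fs, trim_s)
  xr <- trim_transient(bandpass_filter(x, ref, fs), fs, trim_s)
  spb <- power_spectrum(xb, fs)
  pk <- max(spb$power[band_bins(spb, band)])
  spr <- power_spectrum(xr, fs)
  pk_ref <- max(spr$power[band_bins(spr, ref)])
  if (pk_ref <= 0) stop("zero reference peak: PA undefined", call. = FALSE)
  pk / pk_ref
}

#' Sample entropy
#'
#' Negative log of the conditional probability that template vectors
#' matching for `m` points (Chebyshev distance <= r) also match for `m + 1`
#' points. Matches are counted over unordered pairs i != j. The tolerance is
#' `r_frac` times the standard deviation of `x`. When either match count is
#' zero the conventional fallback value `-ln((N - m) / (N - m - 1))` is
#' returned; note this is negative as written, and
#' `fallback_sign_corrected = TRUE` returns its absolute value instead.
#'
#' @param x Numeric series (the band-filtered analysis series).
#' @param m Embedding dimension (default 3).
#' @param r_frac Tolerance as a fraction of `sd(x)` (default 0.15).
#' @param fallback_sign_corrected Return `+ln((N-m)/(N-m-1))` in the
#'   degenerate branch (default `FALSE`, i.e. the branch value as
#'   conventionally printed).
#' @return Sample entropy in nats.
#' @export
sample_entropy <- function(x, m = 3L, r_frac = 0.15,
                           fallback_sign_corrected = FALSE) {
  n <- length(x)
  if (n <= m + 1L) stop("series too short for embedding dimension m",
                        call. = FALSE)
  s <- sd(x)
  r <- if (s > 0) r_frac * s else 0
  cnt <- se_match_counts(as.numeric(x), as.integer(m), r)
  if (cnt$c_m1 != 0 && cnt$c_m != 0) {
    -log(cnt$c_m1 / cnt$c_m)
  } else {
    v <- -log((n - m) / (n - m - 1))
    if (fallback_sign_corrected) abs(v) else v
  }
}

#' Extract features from one EHG record
#'
#' Band-filters the requested signal for each spec, trims the filter
#' transient, and computes the spectral features (PF, MF, PA from the
#' periodogram) and sample entropy of the band-limited series. Deterministic
#' given the record and settings.
#'
#' @param rec An `ehg_record` (see [read_ehg_record()], [generate_record()]).
#' @param specs Feature-spec tibble from [ehg_feature_specs()] /
#'   [ehg_feature_set()].
#' @param trim_s Transient trim in seconds (default 15).
#' @param se_params List with `m` and `r_frac` for sample entropy.
#' @return One-row tibble: `record_id`, `label`, then one column per spec
#'   (canonical names).
#' @export
extract_features <- function(rec, specs, trim_s = 15,
                             se_params = list(m = 3L, r_frac = 0.15)) {
  stopifnot(inherits(rec, "ehg_record"))
  fs <- rec$fs
  # one filtered series per (signal, band) pair, shared across features
  combos <- dplyr::distinct(specs, .data$signal, .data$band)
  filtered <- purrr::pmap(combos, function(signal, band) {
    trim_transient(bandpass_filter(rec$signals[, signal], band, fs), fs,
                   trim_s)
  })
  names(filtered) <- paste(combos$signal, combos$band, sep = ".")
  spectra <- purrr::map(filtered, power_spectrum, fs = fs)
  # PA needs the reference-band peak per signal
  pa_sigs <- unique(specs$signal[specs$feature == "PA"])
  ref <- pa_reference_band()
  pa_ref <- purrr::map_dbl(setNames(pa_sigs, pa_sigs), function(sg) {
    xr <- trim_transient(bandpass_filter(rec$signals[, sg], ref, fs), fs,
                         trim_s)
    spr <- power_spectrum(xr, fs)
    max(spr$power[band_bins(spr, ref)])
  })
  vals <- purrr::pmap_dbl(specs[c("feature", "signal", "band")],
    function(feature, signal, band) {
      key <- paste(signal, band, sep = ".")
      switch(feature,
        PF = peak_frequency(spectra[[key]], band),
        MF = median_frequency(spectra[[key]], band),
        PA = {
          sp <- spectra[[key]]
          max(sp$power[band_bins(sp, band)]) / pa_ref[[signal]]
        },
        SE = sample_entropy(filtered[[key]], m = se_params$m,
                            r_frac = se_params$r_frac)
      )
    })
  out <- tibble::tibble(record_id = rec$record_id,
                        label = record_label(rec))
  out[specs$name] <- as.list(vals)
  out
}

record_label <- function(rec) {
  if (is.null(rec$meta$gestation_at_delivery)) return(NA_character_)
  if (rec$meta$gestation_at_delivery < 37) "premature" else "term"
}

#' Extract a feature table from a record collection
#'
#' @param collection An `ehg_collection` (see [load_dataset()],
#'   [generate_dataset()]).
#' @param specs Feature-spec tibble.
#' @param ... Passed to [extract_features()].
#' @return Feature table: tibble with `record_id`, `group`, `label` and one
#'   column per feature spec.
#' @export
extract_feature_table <- function(collection, specs, ...) {
  stopifnot(inherits(collection, "ehg_collection"))
  rows <- purrr::map(collection$records, extract_features, specs = specs,
                     ...)
  tab <- dplyr::bind_rows(rows)
  groups <- tibble::tibble(record_id = names(collection$groups),
                           group = unname(collection$groups))
  dplyr::relocate(dplyr::left_join(tab, groups, by = "record_id"),
                  "record_id", "group", "label")
}
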