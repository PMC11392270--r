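#' Class-effect parameters for the synthetic EHG generator
#'
#' The generator plants the two class effects the downstream analysis is
#' built to detect: (i) a narrowband low-frequency (FWL-like) component
#' inside 0.125--0.575 Hz whose spectral peak is elevated by
#' `fwl_peak_gain` (power ratio) in the premature class, and (ii) maternal
#' heart-rate harmonics whose fundamental is lowered by `mhr_shift` Hz in
#' the premature class, lowering the band-B3 median frequency. A fixed
#' higher-frequency component near 0.7 Hz anchors the reference peak of
#' band B0 so the normalized peak amplitude in B0Lp responds to the planted
#' gain. The third harmonic must stay inside B3 (3.5--5.0 Hz) for both
#' classes.
#'
#' @param fwl_peak_gain Multiplicative elevation (>= 1) of the FWL spectral
#'   peak power in the premature class. 1 = null effect.
#' @param mhr_base Maternal-heart fundamental in Hz (term class).
#' @param mhr_shift Hz subtracted from `mhr_base` in the premature class
#'   (>= 0). 0 = null effect.
#' @param harmonic_amps Amplitudes of harmonics 1--3 of the maternal heart
#'   rate, relative to the FWH anchor amplitude.
#' @param noise_exponent Spectral slope of the 1/f^a background.
#' @param snr Total tone-to-noise power ratio.
#' @param noise_jitter_sd SD of the per-record log-normal jitter on the
#'   noise level (recording-quality variation, independent of class).
#' @param fwl_amp,fwh_amp Base amplitudes of the FWL component (term class)
#'   and of the 0.7 Hz anchor component.
#' @param b3_interference_amp Amplitude of a class-independent narrowband
#'   interference component (band-limited noise, 4.09--4.19 Hz) sitting
#'   between the two classes' third-harmonic ranges. Its concentrated
#'   spectral ridge frequently owns the in-band peak, so the class effect
#'   expresses itself through the median frequency rather than the peak
#'   location.
#' @param amp_jitter_sd SD of the per-record log-normal amplitude jitter on
#'   the FWL component (controls within-class feature spread).
#' @return List of class `ehg_effects`.
#' @export
ehg_effects <- function(fwl_peak_gain = 3, mhr_base = 1.45,
                        mhr_shift = 0.14,
                        harmonic_amps = c(0.25, 0.18, 0.35),
                        b3_interference_amp = 0,
                        noise_exponent = 0.5, snr = 6,
                        noise_jitter_sd = 0.4,
                        fwl_amp = 0.7, fwh_amp = 1.6,
                        amp_jitter_sd = 0.25) {
  stopifnot(fwl_peak_gain >= 1, mhr_shift >= 0,
            length(harmonic_amps) == 3L)
  if (3 * (mhr_base - mhr_shift) < 3.5 || 3 * mhr_base > 5.0) {
    stop("third maternal-heart harmonic must stay inside B3 (3.5-5.0 Hz) ",
         "for both classes", call. = FALSE)
  }
  structure(list(fwl_peak_gain = fwl_peak_gain, mhr_base = mhr_base,
                 mhr_shift = mhr_shift, harmonic_amps = harmonic_amps,
                 noise_exponent = noise_exponent, snr = snr,
                 noise_jitter_sd = noise_jitter_sd,
                 fwl_amp = fwl_amp, fwh_amp = fwh_amp,
                 b3_interference_amp = b3_interference_amp,
                 amp_jitter_sd = amp_jitter_sd),
            class = "ehg_effects")
}

#' Synthetic dataset configuration
#'
#' Defaults mirror the study's later-record group structure: 32 premature
#' (PL) versus 132 + 43 + 8 + 13 = 196 term records (TL/IL/CL/ICL),
#' 30-minute 3-channel records at 20 Hz. Delivery-mode groups differ only
#' in their metadata label: all term groups share the term effect
#' parameters, mirroring the finding that term delivery modes behave alike.
#'
#' @param group_sizes Named counts for PL, TL, IL, CL, ICL.
#' @param duration_s Record duration in seconds (default 1800).
#' @param fs Sampling rate in Hz (default 20).
#' @param effects An [ehg_effects()] object.
#' @param seed Master seed; every record's randomness derives from it.
#' @return List of class `ehg_synth_config`.
#' @export
ehg_synth_config <- function(group_sizes = c(PL = 32, TL = 132, IL = 43,
                                             CL = 8, ICL = 13),
                             duration_s = 1800, fs = 20,
                             effects = ehg_effects(), seed = 1L) {
  stopifnot(all(c("PL", "TL", "IL", "CL", "ICL") %in% names(group_sizes)),
            group_sizes[["PL"]] >= 2, sum(group_sizes) >= 4,
            duration_s * fs >= 1200)
  structure(list(group_sizes = group_sizes, duration_s = duration_s,
                 fs = fs, effects = effects, seed = as.integer(seed)),
            class = "ehg_synth_config")
}

# 1/f^a background noise with unit variance, via spectral shaping
colored_noise <- function(n, exponent) {
  w <- rnorm(n)
  wf <- fft(w)
  f <- c(1, seq_len(n - 1))        # avoid dividing the DC bin by zero
  f <- pmin(f, n - f + 1)          # symmetric shaping
  shaped <- wf * f^(-exponent / 2)
  x <- Re(fft(shaped, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# band-limited white noise with RMS matched to a tone of amplitude `amp`
narrowband_noise <- function(n, fs, f_lo, f_hi, amp) {
  bf <- signal::butter(2, c(f_lo, f_hi) / (fs / 2), type = "pass")
  x <- as.numeric(signal::filtfilt(bf, rnorm(n)))
  amp * x / stats::sd(x) / sqrt(2)
}

# sinusoid with bounded random-walk frequency jitter and slow amplitude
# modulation (depth drawn per record; physiological tones wax and wane,
# which perturbs waveform regularity far more than spectral peak ratios)
jittered_tone <- function(n, fs, f0, walk_sd, f_min, f_max, amp,
                          am_depth = runif(1, 0.3, 0.9)) {
  steps <- rnorm(n, sd = walk_sd / sqrt(fs))
  f_inst <- f0 + cumsum(steps)
  f_inst <- pmin(pmax(f_inst, f_min), f_max)
  phase <- 2 * pi * cumsum(f_inst) / fs + runif(1, 0, 2 * pi)
  am <- 1 + am_depth * sin(2 * pi * runif(1, 0.005, 0.02) *
                             seq_len(n) / fs + runif(1, 0, 2 * pi))
  amp * am * sin(phase)
}

#' Generate one synthetic EHG record
#'
#' Three channels share the class-dependent components and carry
#' independent 1/f-like background noise. The components are mixed with
#' channel-specific gains reflecting electrode orientation: the FWL
#' (uterine) component projects most strongly onto the horizontal channel
#' S3, and the maternal-heart harmonics onto the vertical channel S2 — so
#' the normalized peak amplitude in B0Lp is most discriminative on S3 and
#' the band-B3 median frequency on S2, matching where the class effects
#' are planted.
#'
#' @param class `"premature"` or `"term"`.
#' @param effects An [ehg_effects()] object.
#' @param fs Sampling rate in Hz.
#' @param duration_s Duration in seconds.
#' @param meta Optional [ehg_metadata()]; a class-consistent one is drawn
#'   when omitted.
#' @param record_id Record identifier.
#' @param seed Optional seed for reproducibility.
#' @return An `ehg_record`.
#' @export
generate_record <- function(class = c("term", "premature"),
                            effects = ehg_effects(), fs = 20,
                            duration_s = 1800, meta = NULL,
                            record_id = "synthetic", seed = NULL) {
  class <- match.arg(class)
  gen <- function() {
    n <- round(fs * duration_s)
    premature <- class == "premature"
    # FWL component: elevated spectral peak in the premature class
    amp_jit <- exp(rnorm(1, sd = effects$amp_jitter_sd))
    gain <- if (premature) sqrt(effects$fwl_peak_gain) else 1
    fwl <- jittered_tone(n, fs, f0 = runif(1, 0.31, 0.45), walk_sd = 0.002,
                         f_min = 0.30, f_max = 0.46,
                         amp = effects$fwl_amp * amp_jit * gain)
    # FWH anchor: dominant B0 peak outside the FWL band
    fwh <- jittered_tone(n, fs, f0 = runif(1, 0.62, 0.9), walk_sd = 0.002,
                         f_min = 0.6, f_max = 0.95,
                         amp = effects$fwh_amp * exp(rnorm(1, sd = 0.05)),
                         am_depth = runif(1, 0, 0.2))
    # maternal-heart harmonics; the premature maternal resting heart rate
    # is lowered by mhr_shift
    hr <- effects$mhr_base - if (premature) effects$mhr_shift else 0
    hr <- hr + runif(1, -0.01, 0.01)
    # heart-rate variability: the wandering fundamental spreads each
    # harmonic's spectral energy over many bins, so band peaks stay
    # anchored elsewhere while the band median tracks the harmonic mass
    steps <- rnorm(n, sd = 0.03 / sqrt(fs))
    hr_inst <- pmin(pmax(hr + cumsum(steps), hr - 0.07), hr + 0.07)
    phase0 <- runif(3, 0, 2 * pi)
    ham <- 1 + runif(1, 0, 0.5) *
      sin(2 * pi * runif(1, 0.005, 0.02) * seq_len(n) / fs +
            runif(1, 0, 2 * pi))
    heart <- rowSums(vapply(1:3, function(h) {
      effects$harmonic_amps[h] * exp(rnorm(1, sd = 0.15)) *
        sin(2 * pi * h * cumsum(hr_inst) / fs + phase0[h])
    }, numeric(n))) * ham
    # class-independent narrowband interference inside B3, between the
    # two classes' third-harmonic ranges
    b3a <- narrowband_noise(n, fs, 4.09, 4.19,
                            effects$b3_interference_amp *
                              exp(rnorm(1, sd = 0.15)))
    # electrode-orientation mixing: rows = components, cols = channels
    mix <- rbind(fwl_c = c(S1 = 0.8, S2 = 0.08, S3 = 1.0),
                 fwh_c = c(0.9, 1.0, 1.0),
                 heart_c = c(0.5, 1.0, 0.03),
                 b3a_c = c(0.5, 1.0, 0.1))
    comps <- cbind(fwl, fwh, heart, b3a)
    # class-independent noise level: analytic power of the nominal (term)
    # component amplitudes, so the planted gain changes only the FWL peak,
    # never the background
    ref_power <- (effects$fwl_amp^2 + effects$fwh_amp^2 +
                    sum(effects$harmonic_amps^2) +
                    effects$b3_interference_amp^2) / 2
    # per-record recording-quality variation, independent of class
    noise_sd <- sqrt(ref_power / effects$snr) *
      exp(rnorm(1, sd = effects$noise_jitter_sd))
    # per-record background spectral slope (inter-subject variability)
    noise_exp <- effects$noise_exponent + runif(1, -0.3, 0.3)
    sig <- vapply(1:3, function(ch) {
      as.numeric(comps %*% mix[, ch]) +
        noise_sd * colored_noise(n, noise_exp)
    }, numeric(n))
    colnames(sig) <- c("S1", "S2", "S3")
    if (is.null(meta)) {
      rec_wk <- runif(1, 29, 32)
      meta <- if (premature) {
        ehg_metadata(rec_wk, min(rec_wk + runif(1, 1, 5), 36.5),
                     "spontaneous", "SYNTHETIC", epoch = "later")
      } else {
        ehg_metadata(rec_wk, runif(1, 37.5, 41.5), "spontaneous",
                     "SYNTHETIC", epoch = "later")
      }
    }
    new_ehg_record(record_id, sig, fs, meta)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

group_delivery_mode <- function(group) {
  switch(group, PL = "spontaneous", TL = "spontaneous", IL = "induced",
         CL = "cesarean", ICL = "induced_cesarean")
}

# draw class-consistent metadata for one record of a group
draw_group_metadata <- function(group) {
  rec_wk <- runif(1, 29, 32)
  if (group == "PL") {
    ehg_metadata(rec_wk, min(rec_wk + runif(1, 1, 5), 36.5),
                 "spontaneous", "SYNTHETIC", epoch = "later")
  } else {
    ehg_metadata(rec_wk, runif(1, 37.5, 41.5), group_delivery_mode(group),
                 "SYNTHETIC", epoch = "later")
  }
}

#' Generate a labeled synthetic record collection
#'
#' PL records use the premature effect parameters; all term groups (TL, IL,
#' CL, ICL) use the term parameters and differ only in metadata.
#' Deterministic per config seed: each record's randomness derives from the
#' master seed and the record index.
#'
#' @param config An [ehg_synth_config()].
#' @return An `ehg_collection`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "ehg_synth_config"))
  sizes <- config$group_sizes[c("PL", "TL", "IL", "CL", "ICL")]
  plan <- tibble::tibble(
    group = rep(names(sizes), times = sizes),
    idx_in_group = unlist(lapply(sizes, seq_len), use.names = FALSE)
  )
  plan$record_id <- sprintf("syn_%s_%03d", tolower(plan$group),
                            plan$idx_in_group)
  plan$seed <- (config$seed + 7919L * seq_len(nrow(plan))) %% 2147483629L
  records <- purrr::pmap(plan, function(group, idx_in_group, record_id,
                                        seed) {
    cls <- if (group == "PL") "premature" else "term"
    meta <- withr::with_seed(seed, draw_group_metadata(group))
    generate_record(cls, effects = config$effects, fs = config$fs,
                    duration_s = config$duration_s, meta = meta,
                    record_id = record_id, seed = seed + 1L)
  })
  names(records) <- plan$record_id
  new_ehg_collection(records, setNames(plan$group, plan$record_id))
}

#' Write a collection as WFDB-compatible fixtures
#'
#' @param collection An `ehg_collection`.
#' @param dir Output directory.
#' @param gain ADC gain passed to [write_ehg_record()].
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(collection, dir, gain = 1000) {
  stopifnot(inherits(collection, "ehg_collection"))
  if (length(collection$records) == 0L) {
    warning("empty collection: nothing written")
    return(invisible(dir))
  }
  for (rec in collection$records) write_ehg_record(rec, dir, gain = gain)
  invisible(dir)
}
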