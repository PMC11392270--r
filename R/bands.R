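#' Canonical EHG frequency bands
#'
#' Returns the ten frequency bands used for EHG feature extraction. The four
#' non-overlapping bands B0--B3 separate the uterine activity band
#' (B0, 0.08--1.0 Hz) from the bands reflecting the maternal heart rate and
#' its second and third harmonics (B1--B3). Bb and B0b are broad bands; B0L,
#' B0Lp (0.125--0.575 Hz, closely matching the Fast Wave Low band) and B0Lpp
#' target sub-bands of the low-frequency uterine activity, and B0Hp covers
#' the Fast Wave High range up to 1.0 Hz. Band names use `p` as an ASCII
#' substitute for the prime mark (B0Lp = "B0L'").
#'
#' @return A tibble with columns `band`, `f_lo`, `f_hi` (Hz).
#' @examples
#' ehg_bands()
#' @export
ehg_bands <- function() {
  tibble::tribble(
    ~band,    ~f_lo, ~f_hi,
    "B0",     0.08,  1.0,
    "B1",     1.0,   2.2,
    "B2",     2.2,   3.5,
    "B3",     3.5,   5.0,
    "Bb",     0.3,   4.0,
    "B0b",    0.08,  4.0,
    "B0L",    0.08,  0.3,
    "B0Lp",   0.125, 0.575,
    "B0Lpp",  0.225, 0.475,
    "B0Hp",   0.575, 1.0
  )
}

#' Look up one band by name
#'
#' @param band Band name as in [ehg_bands()], e.g. `"B0Lp"`.
#' @return One-row tibble with `band`, `f_lo`, `f_hi`.
#' @export
ehg_band <- function(band) {
  tab <- ehg_bands()
  hit <- tab[tab$band == band, ]
  if (nrow(hit) != 1L) {
    stop("unknown band: ", band, call. = FALSE)
  }
  hit
}

# reference band for the normalized peak amplitude
pa_reference_band <- function() ehg_band("B0")

#' Build a feature-specification table
#'
#' A feature specification is one (feature, signal, band) triple; its
#' canonical name is `<feature>_<signal>_<band>`, e.g. `PA_S3_B0Lp`.
#' `PA` is disallowed in bands `B0` and `B0b` because the normalized peak
#' amplitude is identically 1.0 there (the reference band contains the band).
#'
#' @param features Character vector among `"PF"`, `"MF"`, `"PA"`, `"SE"`.
#' @param signals Character vector among `"S2"`, `"S3"`.
#' @param bands Character vector of band names from [ehg_bands()].
#' @param drop_degenerate_pa Drop `PA` specs in bands `B0`/`B0b`
#'   (default `TRUE`).
#' @return Tibble with columns `name`, `feature`, `signal`, `band`.
#' @examples
#' ehg_feature_specs(bands = c("B0L", "B0Lp", "B3"))
#' @export
ehg_feature_specs <- function(features = c("PF", "MF", "PA", "SE"),
                              signals = c("S2", "S3"),
                              bands = ehg_bands()$band,
                              drop_degenerate_pa = TRUE) {
  stopifnot(all(features %in% c("PF", "MF", "PA", "SE")),
            all(signals %in% c("S1", "S2", "S3")),
            all(bands %in% ehg_bands()$band))
  specs <- tidyr::expand_grid(feature = features, signal = signals,
                              band = bands)
  if (drop_degenerate_pa) {
    specs <- dplyr::filter(specs,
                           !(.data$feature == "PA" &
                               .data$band %in% c("B0", "B0b")))
  }
  dplyr::mutate(specs,
                name = paste(.data$feature, .data$signal, .data$band,
                             sep = "_"),
                .before = 1L)
}

#' The four study feature sets
#'
#' * set1: all four features for S2/S3 over all 10 bands, minus the
#'   degenerate PA specs (76 features).
#' * set2: set1 without the least promising bands B0Hp and Bb (60).
#' * set3: bands B0L, B0Lp, B3 and B0b only, minus PA in B0b (30).
#' * set4: set3 without B0b (24).
#'
#' @param set One of `"set1"`, `"set2"`, `"set3"`, `"set4"`.
#' @return Feature-spec tibble as from [ehg_feature_specs()].
#' @examples
#' nrow(ehg_feature_set("set1"))  # 76
#' @export
ehg_feature_set <- function(set = c("set1", "set2", "set3", "set4")) {
  set <- match.arg(set)
  bands <- switch(set,
    set1 = ehg_bands()$band,
    set2 = setdiff(ehg_bands()$band, c("B0Hp", "Bb")),
    set3 = c("B0L", "B0Lp", "B3", "B0b"),
    set4 = c("B0L", "B0Lp", "B3")
  )
  ehg_feature_specs(bands = bands)
}

# parse canonical names back into a spec tibble
parse_feature_names <- function(names) {
  parts <- strsplit(names, "_", fixed = TRUE)
  ok <- vapply(parts, length, 1L) == 3L
  if (!all(ok)) {
    stop("not canonical feature names: ",
         paste(names[!ok], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    name = names,
    feature = vapply(parts, `[[`, "", 1L),
    signal = vapply(parts, `[[`, "", 2L),
    band = vapply(parts, `[[`, "", 3L)
  )
}
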