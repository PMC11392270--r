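#' Record metadata
#'
#' Per-record clinical metadata: gestational ages (weeks) at recording and
#' at delivery, the delivery mode, and the dataset of origin. A record is
#' premature iff delivery occurred before 37 completed weeks.
#'
#' @param gestation_at_recording,gestation_at_delivery Weeks.
#' @param delivery_mode One of `"spontaneous"`, `"induced"`, `"cesarean"`,
#'   `"induced_cesarean"`.
#' @param dataset One of `"TPEHG_DB"`, `"TPEHGT_DS"`, `"ICEHG_DS"`,
#'   `"SYNTHETIC"`.
#' @param epoch Optional dataset-provided recording-epoch label
#'   (`"early"`/`"later"`); used by [load_dataset()] when present.
#' @return A list of class `ehg_metadata`.
#' @export
ehg_metadata <- function(gestation_at_recording, gestation_at_delivery,
                         delivery_mode = c("spontaneous", "induced",
                                           "cesarean", "induced_cesarean"),
                         dataset = c("SYNTHETIC", "TPEHG_DB", "TPEHGT_DS",
                                     "ICEHG_DS"),
                         epoch = NULL) {
  delivery_mode <- match.arg(delivery_mode)
  dataset <- match.arg(dataset)
  stopifnot(is.numeric(gestation_at_recording),
            is.numeric(gestation_at_delivery))
  if (gestation_at_delivery < gestation_at_recording) {
    stop("gestation at delivery precedes gestation at recording",
         call. = FALSE)
  }
  structure(list(gestation_at_recording = gestation_at_recording,
                 gestation_at_delivery = gestation_at_delivery,
                 delivery_mode = delivery_mode,
                 dataset = dataset,
                 epoch = epoch),
            class = "ehg_metadata")
}

new_ehg_record <- function(record_id, signals, fs, meta) {
  stopifnot(is.matrix(signals), ncol(signals) == 3L,
            identical(colnames(signals), c("S1", "S2", "S3")),
            fs > 0)
  structure(list(record_id = record_id, signals = signals, fs = fs,
                 n_samples = nrow(signals), meta = meta),
            class = "ehg_record")
}

#' @export
print.ehg_record <- function(x, ...) {
  cat(sprintf("<ehg_record %s: 3 x %d samples @ %g Hz, %s, delivery %g wk>\n",
              x$record_id, x$n_samples, x$fs, x$meta$delivery_mode,
              x$meta$gestation_at_delivery))
  invisible(x)
}

new_ehg_collection <- function(records, groups) {
  stopifnot(length(records) == length(groups),
            identical(names(records), names(groups)))
  structure(list(records = records, groups = groups),
            class = "ehg_collection")
}

#' @export
print.ehg_collection <- function(x, ...) {
  cat("<ehg_collection:", length(x$records), "records>\n")
  print(table(x$groups))
  invisible(x)
}

#' Group counts of a record collection
#'
#' @param collection An `ehg_collection`.
#' @return Tibble with `group` and `n`, over PL/TL/IL/CL/ICL.
#' @export
group_counts <- function(collection) {
  stopifnot(inherits(collection, "ehg_collection"))
  lv <- c("PL", "TL", "IL", "CL", "ICL")
  cnt <- table(factor(collection$groups, levels = lv))
  tibble::tibble(group = lv, n = as.integer(cnt))
}

#' Assign a record to its study group
#'
#' Premature records (delivery before 37 weeks) map to PL regardless of
#' delivery mode; term records map by delivery mode: spontaneous to TL,
#' induced to IL, cesarean to CL, induced-cesarean to ICL.
#'
#' @param meta An [ehg_metadata()] object.
#' @return One of `"PL"`, `"TL"`, `"IL"`, `"CL"`, `"ICL"`.
#' @examples
#' assign_group(ehg_metadata(30, 35))            # "PL"
#' assign_group(ehg_metadata(30, 39, "induced")) # "IL"
#' @export
assign_group <- function(meta) {
  stopifnot(inherits(meta, "ehg_metadata"))
  if (meta$gestation_at_delivery < 37) return("PL")
  switch(meta$delivery_mode,
         spontaneous = "TL",
         induced = "IL",
         cesarean = "CL",
         induced_cesarean = "ICL",
         stop("unknown delivery mode: ", meta$delivery_mode, call. = FALSE))
}

# ---- WFDB-style record files -------------------------------------------

#' Write an EHG record as a WFDB-compatible header/signal pair
#'
#' Writes `<record_id>.hea` (text header; metadata in `#` comment lines)
#' and `<record_id>.dat` (format 16: interleaved little-endian 16-bit
#' integers). Samples are quantized by the declared gain (ADC units per
#' physical unit), so the round-trip error is at most half an LSB.
#'
#' @param rec An `ehg_record`.
#' @param dir Output directory.
#' @param gain ADC units per signal unit (default 1000).
#' @return The header path, invisibly.
#' @export
write_ehg_record <- function(rec, dir, gain = 1000) {
  stopifnot(inherits(rec, "ehg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  adc <- round(rec$signals * gain)
  if (any(abs(adc) > 32767)) {
    stop("signal amplitude exceeds 16-bit range at this gain", call. = FALSE)
  }
  hea <- file.path(dir, paste0(rec$record_id, ".hea"))
  dat <- paste0(rec$record_id, ".dat")
  lines <- c(
    sprintf("%s 3 %g %d", rec$record_id, rec$fs, rec$n_samples),
    sprintf("%s 16 %g 16 0 %d 0 0 %s", dat, gain, adc[1, ],
            colnames(rec$signals)),
    sprintf("# gestation_at_recording %g", rec$meta$gestation_at_recording),
    sprintf("# gestation_at_delivery %g", rec$meta$gestation_at_delivery),
    sprintf("# delivery_mode %s", rec$meta$delivery_mode),
    sprintf("# dataset %s", rec$meta$dataset)
  )
  if (!is.null(rec$meta$epoch)) {
    lines <- c(lines, sprintf("# epoch %s", rec$meta$epoch))
  }
  writeLines(lines, hea)
  con <- file(file.path(dir, dat), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
  invisible(hea)
}

#' Read a WFDB-style EHG record
#'
#' Parses the text header and the format-16 signal file and maps the first
#' three declared channels to S1/S2/S3 (the datasets' electrode arithmetic:
#' S1 = E2-E1, S2 = E2-E3, S3 = E4-E3). Metadata is read from `#` comment
#' lines when present.
#'
#' @param path Path to the `.hea` header (or the record name without
#'   extension).
#' @return An `ehg_record`.
#' @export
read_ehg_record <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("header not found: ", hea, call. = FALSE)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  sig_lines <- grep("^\\s*#", lines, invert = TRUE, value = TRUE)
  if (length(sig_lines) < 2L) stop("corrupt header: ", hea, call. = FALSE)
  top <- strsplit(trimws(sig_lines[1L]), "\\s+")[[1L]]
  if (length(top) < 4L) stop("corrupt header line: ", sig_lines[1L],
                             call. = FALSE)
  record_id <- top[1L]
  nsig <- as.integer(top[2L])
  fs <- as.numeric(top[3L])
  nsamp <- as.integer(top[4L])
  if (is.na(nsig) || is.na(fs) || is.na(nsamp) || fs <= 0) {
    stop("corrupt header: ", hea, call. = FALSE)
  }
  if (nsig < 3L) {
    stop("unsupported record (fewer than 3 channels): ", record_id,
         call. = FALSE)
  }
  spec1 <- strsplit(trimws(sig_lines[2L]), "\\s+")[[1L]]
  dat_file <- spec1[1L]
  fmt <- spec1[2L]
  if (fmt != "16") stop("unsupported signal format: ", fmt, call. = FALSE)
  gains <- vapply(sig_lines[-1L], function(l) {
    toks <- strsplit(trimws(l), "\\s+")[[1L]]
    g <- suppressWarnings(as.numeric(sub("[(/].*$", "", toks[3L])))
    if (is.na(g) || g == 0) 200 else g  # WFDB default gain
  }, 1.0, USE.NAMES = FALSE)
  dat_path <- file.path(dirname(hea), dat_file)
  if (!file.exists(dat_path)) stop("signal file not found: ", dat_path,
                                   call. = FALSE)
  raw <- readBin(dat_path, "integer", n = nsig * nsamp + nsig, size = 2L,
                 endian = "little")
  if (length(raw) < nsig * nsamp) {
    stop("truncated signal file: ", dat_path, call. = FALSE)
  }
  adc <- matrix(raw[seq_len(nsig * nsamp)], ncol = nsig, byrow = TRUE)
  sig <- sweep(adc[, 1:3, drop = FALSE], 2L, gains[1:3], "/")
  colnames(sig) <- c("S1", "S2", "S3")
  meta <- parse_meta_comments(meta_lines)
  new_ehg_record(record_id, sig, fs, meta)
}

parse_meta_comments <- function(meta_lines) {
  kv <- list()
  for (l in meta_lines) {
    toks <- strsplit(trimws(sub("^\\s*#\\s*", "", l)), "\\s+")[[1L]]
    if (length(toks) >= 2L) kv[[toks[1L]]] <- paste(toks[-1L], collapse = " ")
  }
  ehg_metadata(
    gestation_at_recording = as.numeric(kv$gestation_at_recording %||% NA),
    gestation_at_delivery = as.numeric(kv$gestation_at_delivery %||% NA),
    delivery_mode = kv$delivery_mode %||% "spontaneous",
    dataset = kv$dataset %||% "SYNTHETIC",
    epoch = kv$epoch
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a directory tree of EHG records
#'
#' Reads every `.hea`/`.dat` pair under `paths`, keeps only "later" records
#' (the dataset's own epoch label when present, otherwise a configurable
#' gestational-age-at-recording threshold), and assigns each retained record
#' its study group.
#'
#' @param paths Directories (searched recursively) or individual `.hea`
#'   paths.
#' @param min_weeks Fallback recording-age threshold in weeks when no epoch
#'   label is present (default 26; "later" records are collected around the
#'   31st gestational week).
#' @return An `ehg_collection`.
#' @export
load_dataset <- function(paths, min_weeks = 26) {
  heas <- unlist(lapply(paths, function(p) {
    if (dir.exists(p)) {
      list.files(p, pattern = "\\.hea$", recursive = TRUE,
                 full.names = TRUE)
    } else p
  }))
  records <- lapply(sort(heas), read_ehg_record)
  keep <- vapply(records, function(r) {
    if (!is.null(r$meta$epoch)) {
      identical(r$meta$epoch, "later")
    } else {
      isTRUE(r$meta$gestation_at_recording >= min_weeks)
    }
  }, TRUE)
  records <- records[keep]
  if (length(records) == 0L) {
    warning("no records passed the recording-epoch filter")
  }
  ids <- vapply(records, `[[`, "", "record_id")
  if (anyDuplicated(ids)) {
    stop("duplicate record ids in dataset", call. = FALSE)
  }
  names(records) <- ids
  groups <- vapply(records, function(r) assign_group(r$meta), "")
  new_ehg_collection(records, groups)
}

# ---- feature table persistence -----------------------------------------

#' Write / read a feature table
#'
#' Feature tables are persisted as CSV with full floating precision; the
#' header names each feature spec canonically (e.g. `PA_S3_B0Lp`). Writing
#' rejects duplicate record ids and missing feature values.
#'
#' @param table Feature table tibble (`record_id`, `group`, `label`,
#'   feature columns).
#' @param path CSV path.
#' @return `read_feature_table()` returns the tibble; `write_feature_table()`
#'   returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table), nrow(table) > 0L,
            "record_id" %in% names(table))
  if (anyDuplicated(table$record_id)) {
    stop("duplicate record ids in feature table", call. = FALSE)
  }
  feat <- feature_columns(table)
  if (anyNA(table[feat])) {
    stop("missing feature values in feature table", call. = FALSE)
  }
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

feature_columns <- function(table) {
  setdiff(names(table), c("record_id", "group", "label"))
}
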