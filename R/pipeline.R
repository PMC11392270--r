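#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: where the records come
#' from (a directory tree of WFDB-style files or a synthetic-data config),
#' which feature sets and classifiers participate, the number of
#' repetitions, and the seed. The config is serialized as a JSON manifest
#' next to every output, and a run is bit-reproducible from its manifest.
#'
#' @param input A directory path (or paths) of records, or an
#'   [ehg_synth_config()].
#' @param feature_sets Character vector of feature-set names.
#' @param classifiers Character vector from [ehg_classifiers()].
#' @param n_reps SFS/evaluation repetitions.
#' @param seed Base seed.
#' @param out_dir Output directory.
#' @param trim_s,k,k_neighbors Stage parameters, see the stage functions.
#' @return List of class `ehg_run_config`.
#' @export
ehg_run_config <- function(input, feature_sets = c("set1", "set2", "set3",
                                                   "set4"),
                           classifiers = ehg_classifiers(), n_reps = 200L,
                           seed = 1L, out_dir = tempfile("ehg_run_"),
                           trim_s = 15, k = 5L, k_neighbors = 5L) {
  structure(list(input = input, feature_sets = feature_sets,
                 classifiers = classifiers, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), out_dir = out_dir,
                 trim_s = trim_s, k = as.integer(k),
                 k_neighbors = as.integer(k_neighbors)),
            class = "ehg_run_config")
}

config_manifest <- function(config, stage) {
  m <- config[setdiff(names(config), "input")]
  m$stage <- stage
  m$input <- if (inherits(config$input, "ehg_synth_config")) {
    list(kind = "synthetic",
         group_sizes = as.list(config$input$group_sizes),
         duration_s = config$input$duration_s, fs = config$input$fs,
         seed = config$input$seed,
         effects = unclass(config$input$effects))
  } else {
    list(kind = "files", paths = config$input)
  }
  m
}

write_manifest <- function(config, stage) {
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  jsonlite::write_json(config_manifest(config, stage),
                       file.path(config$out_dir,
                                 paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
}

load_config_input <- function(config) {
  if (inherits(config$input, "ehg_synth_config")) {
    generate_dataset(config$input)
  } else {
    load_dataset(config$input)
  }
}

#' Run the extraction stage
#'
#' Loads (or generates) the record collection, extracts the union of the
#' configured feature sets, and writes the feature table plus a manifest
#' to the output directory.
#'
#' @param config An [ehg_run_config()].
#' @return The feature table, invisibly; written to
#'   `<out_dir>/features.csv`.
#' @export
run_extract <- function(config) {
  collection <- load_config_input(config)
  specs <- dplyr::distinct(dplyr::bind_rows(
    lapply(config$feature_sets, ehg_feature_set)))
  table <- extract_feature_table(collection, specs, trim_s = config$trim_s)
  write_manifest(config, "extract")
  write_feature_table(table, file.path(config$out_dir, "features.csv"))
  invisible(table)
}

#' Run the selection stage
#'
#' Performs stabilized SFS for every (classifier, feature set) pair and
#' tallies first/second places. Partitions are persisted for reuse by
#' [run_evaluate()].
#'
#' @param config An [ehg_run_config()].
#' @param table Feature table; read from the extract stage's output when
#'   omitted.
#' @return List: `selections` (named list of `ehg_selection`), `tally`
#'   (`ehg_tally`). Histogram and tally JSON written to the output
#'   directory.
#' @export
run_select <- function(config, table = NULL) {
  if (is.null(table)) {
    path <- file.path(config$out_dir, "features.csv")
    if (!file.exists(path)) {
      stop("no feature table: run run_extract() first (missing ", path,
           ")", call. = FALSE)
    }
    table <- read_feature_table(path)
  }
  combos <- tidyr::expand_grid(classifier = config$classifiers,
                               feature_set = config$feature_sets)
  selections <- purrr::pmap(combos, function(classifier, feature_set) {
    stabilized_selection(
      table, classifier,
      features = intersect(ehg_feature_set(feature_set)$name,
                           names(table)),
      n_reps = config$n_reps, base_seed = config$seed, k = config$k,
      k_neighbors = config$k_neighbors)
  })
  names(selections) <- paste(combos$classifier, combos$feature_set,
                             sep = ".")
  tally <- tally_top2(selections)
  write_manifest(config, "select")
  jsonlite::write_json(
    list(histograms = lapply(selections, function(s) s$histogram),
         tally = tidy(tally),
         leak_audit = lapply(selections, function(s) s$leak_audit)),
    file.path(config$out_dir, "selection.json"), digits = NA)
  list(selections = selections, tally = tally)
}

#' Run the evaluation stage
#'
#' Evaluates each configured classifier on the given biomarker feature(s),
#' reusing the persisted partitions from a selection result when provided
#' (the study discipline), or fresh seeded holdouts otherwise. Emits the
#' performance summary, averaged ROC, boundary artifacts and the leak
#' audit.
#'
#' @param config An [ehg_run_config()].
#' @param table Feature table.
#' @param features One or two feature names (e.g. the tally's A and B).
#' @param plans Optional list of `ehg_partition`s to reuse.
#' @return List: `evaluations` (per classifier), `summary` tibble,
#'   `avg_roc` per classifier, `boundary` (1-D threshold for a single
#'   feature, 2-D isoline for a pair), `leak_audit`.
#' @export
run_evaluate <- function(config, table, features, plans = NULL) {
  stopifnot(length(features) %in% 1:2,
            all(features %in% names(table)))
  if (is.null(plans)) {
    plans <- lapply(seq_len(config$n_reps), function(i) {
      stratified_holdout(table, seed = config$seed + i)
    })
  }
  evals <- lapply(setNames(config$classifiers, config$classifiers),
                  function(kind) {
    repeated_evaluation(table, features, kind, plans,
                        k_neighbors = config$k_neighbors)
  })
  summary <- dplyr::bind_rows(lapply(evals, tidy))
  avg_roc <- lapply(evals, function(e) average_roc(e$roc_curves))
  all_models <- unlist(lapply(evals, `[[`, "models"), recursive = FALSE)
  boundary <- if (length(features) == 1L) {
    rng <- range(table[[features]])
    pad <- 0.1 * diff(rng)
    suppressWarnings(
      average_threshold_1d(all_models, c(rng[1] - pad, rng[2] + pad)))
  } else {
    rngx <- range(table[[features[1]]])
    rngy <- range(table[[features[2]]])
    padx <- 0.1 * diff(rngx)
    pady <- 0.1 * diff(rngy)
    average_boundary_2d(all_models,
                        xlim = c(rngx[1] - padx, rngx[2] + padx),
                        ylim = c(rngy[1] - pady, rngy[2] + pady),
                        n = 100L)
  }
  audit <- dplyr::summarise(
    dplyr::bind_rows(lapply(evals, `[[`, "leak_audit")),
    n_synthetic = sum(.data$n_synthetic),
    n_violations = sum(.data$n_violations))
  write_manifest(config, "evaluate")
  readr::write_csv(summary,
                   file.path(config$out_dir, "evaluation_summary.csv"))
  jsonlite::write_json(
    list(leak_audit = audit,
         avg_roc = lapply(avg_roc, `[[`, "points")),
    file.path(config$out_dir, "evaluation.json"), digits = NA)
  list(evaluations = evals, summary = summary, avg_roc = avg_roc,
       boundary = boundary, leak_audit = audit)
}
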