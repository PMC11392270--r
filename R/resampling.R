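#' Stratified train/test holdout
#'
#' Splits a feature table into training and test record-id sets, preserving
#' the class proportions to rounding. Rows are canonically ordered by
#' `record_id` before the seeded draw, so the plan depends only on
#' (seed, record ids), not on row order.
#'
#' @param table Feature table with `record_id` and `label` columns.
#' @param train_frac Training fraction (default 0.8).
#' @param seed RNG seed.
#' @return List of class `ehg_partition`: `train_ids`, `test_ids`, `seed`.
#' @export
stratified_holdout <- function(table, train_frac = 0.8, seed = 1L) {
  check_two_classes(table)
  ids <- split(sort(table$record_id),
               table$label[order(table$record_id)])
  if (any(lengths(ids) < 2L)) {
    stop("each class needs at least 2 records to stratify", call. = FALSE)
  }
  test_ids <- withr::with_seed(seed, {
    unlist(lapply(ids, function(v) {
      n_test <- round((1 - train_frac) * length(v))
      if (n_test < 1L || n_test >= length(v)) {
        stop("train_frac leaves an empty train or test class",
             call. = FALSE)
      }
      sample(v, n_test)
    }), use.names = FALSE)
  })
  structure(list(train_ids = sort(setdiff(table$record_id, test_ids)),
                 test_ids = sort(test_ids), seed = as.integer(seed)),
            class = "ehg_partition")
}

check_two_classes <- function(table) {
  stopifnot(is.data.frame(table), "label" %in% names(table))
  if (length(unique(table$label)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
}

#' Stratified k-fold assignment
#'
#' @param table Feature table (training partition).
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @return Named integer vector: fold index per record id. Per class, fold
#'   sizes differ by at most one.
#' @export
stratified_kfold <- function(table, k = 5L, seed = 1L) {
  check_two_classes(table)
  ids <- split(sort(table$record_id),
               table$label[order(table$record_id)])
  if (any(lengths(ids) < k)) {
    stop("a class has fewer records than folds", call. = FALSE)
  }
  withr::with_seed(seed, {
    folds <- lapply(ids, function(v) {
      setNames(rep_len(seq_len(k), length(v)), sample(v))
    })
    out <- unlist(unname(folds))
    out[order(names(out))]
  })
}

#' SMOTE minority over-sampling
#'
#' Balances the two classes by synthesizing minority-class rows as convex
#' combinations of a minority row and one of its `k_neighbors` nearest
#' minority neighbors (Euclidean distance in feature space). Original rows
#' are preserved unchanged; synthetic rows get fresh record ids and carry
#' their parentage in the `"smote_provenance"` attribute
#' (`record_id`, `parent_a`, `parent_b`, `lambda`), which the leak audit
#' consumes. Call this only on rows of a single training partition.
#'
#' @param table Feature table (training rows only).
#' @param k_neighbors Number of nearest minority neighbors (default 5;
#'   capped at minority size - 1).
#' @param seed RNG seed.
#' @return Balanced feature table with provenance attribute.
#' @export
smote_oversample <- function(table, k_neighbors = 5L, seed = 1L) {
  check_two_classes(table)
  table <- dplyr::arrange(table, .data$record_id)
  counts <- table(table$label)
  if (min(counts) == max(counts)) {
    attr(table, "smote_provenance") <-
      tibble::tibble(record_id = character(), parent_a = character(),
                     parent_b = character(), lambda = numeric())
    return(table)
  }
  minority <- names(counts)[which.min(counts)]
  n_syn <- max(counts) - min(counts)
  min_rows <- table[table$label == minority, , drop = FALSE]
  if (nrow(min_rows) < 2L) {
    stop("minority class of 1: cannot synthesize", call. = FALSE)
  }
  feat <- feature_columns(table)
  X <- as.matrix(min_rows[feat])
  d <- as.matrix(stats::dist(X))
  diag(d) <- Inf
  k_eff <- min(k_neighbors, nrow(X) - 1L)
  nn <- t(apply(d, 1L, function(row) order(row)[seq_len(k_eff)]))
  syn <- withr::with_seed(seed, {
    base_idx <- rep_len(seq_len(nrow(X)), n_syn)
    nb_pick <- sample.int(k_eff, n_syn, replace = TRUE)
    lam <- runif(n_syn)
    list(base = base_idx,
         nb = nn[cbind(base_idx, nb_pick)],
         lambda = lam)
  })
  vals <- X[syn$base, , drop = FALSE] +
    syn$lambda * (X[syn$nb, , drop = FALSE] - X[syn$base, , drop = FALSE])
  syn_rows <- tibble::as_tibble(as.data.frame(vals))
  names(syn_rows) <- feat
  syn_rows <- dplyr::mutate(
    syn_rows,
    record_id = sprintf("smote_%04d", seq_len(n_syn)),
    label = minority, .before = 1L)
  if ("group" %in% names(table)) {
    syn_rows <- dplyr::mutate(syn_rows, group = NA_character_,
                              .after = "record_id")
  }
  out <- dplyr::bind_rows(table, syn_rows[names(table)])
  attr(out, "smote_provenance") <- tibble::tibble(
    record_id = syn_rows$record_id,
    parent_a = min_rows$record_id[syn$base],
    parent_b = min_rows$record_id[syn$nb],
    lambda = syn$lambda)
  out
}

#' Audit SMOTE provenance for leakage
#'
#' Checks that no synthetic sample has a parent outside the allowed
#' (training-side) id set — the Partition-Synthesis requirement that
#' over-sampling happens strictly after partitioning.
#'
#' @param provenance Provenance tibble(s) as attached by
#'   [smote_oversample()], or a list of them.
#' @param allowed_ids Character vector of permissible parent ids, or a list
#'   parallel to `provenance`.
#' @return Tibble: `n_synthetic`, `n_violations`.
#' @export
audit_leakage <- function(provenance, allowed_ids) {
  if (is.data.frame(provenance)) {
    provenance <- list(provenance)
    allowed_ids <- list(allowed_ids)
  }
  n_syn <- 0L
  n_bad <- 0L
  for (i in seq_along(provenance)) {
    pv <- provenance[[i]]
    ok <- pv$parent_a %in% allowed_ids[[i]] &
      pv$parent_b %in% allowed_ids[[i]]
    n_syn <- n_syn + nrow(pv)
    n_bad <- n_bad + sum(!ok)
  }
  tibble::tibble(n_synthetic = n_syn, n_violations = n_bad)
}
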