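#' Order features by p-value
#'
#' Features enter the sequential search in ascending p-value order (the
#' order also breaks ties throughout the selection). By default two-sided
#' Wilcoxon rank-sum p-values comparing premature vs term are computed from
#' `table`; an externally supplied named p-value map takes precedence.
#'
#' @param table Feature table.
#' @param features Feature column names to order (default: all).
#' @param pvalues Optional named numeric map feature -> p-value.
#' @return Character vector of features, ascending p, ties broken by
#'   canonical name.
#' @export
sort_by_pvalue <- function(table, features = feature_columns(table),
                           pvalues = NULL) {
  if (is.null(pvalues)) {
    pvalues <- rank_sum_pvalues(table, features)
  }
  missing <- setdiff(features, names(pvalues))
  if (length(missing) > 0L) {
    warning("no p-value for ", length(missing),
            " feature(s); falling back to canonical order")
    return(sort(features))
  }
  p <- pvalues[features]
  features[order(p, features)]
}

#' Rank-sum separation p-values per feature
#'
#' @param table Feature table with a `label` column.
#' @param features Feature column names.
#' @return Named numeric vector of two-sided Wilcoxon rank-sum p-values.
#' @export
rank_sum_pvalues <- function(table, features = feature_columns(table)) {
  check_two_classes(table)
  prem <- table$label == "premature"
  vapply(setNames(features, features), function(f) {
    suppressWarnings(
      wilcox.test(table[[f]][prem], table[[f]][!prem], exact = FALSE)$p.value)
  }, 1.0)
}

# Build the SMOTE-balanced cross-validation folds once per repetition.
# Balancing happens per fold, strictly after the fold split, in the full
# candidate-feature space; every candidate subset then reuses these folds
# (column subsets), so the whole greedy search shares one set of SMOTE
# draws per fold.
build_cv_folds <- function(train_table, features, k = 5L, seed = 1L,
                           k_neighbors = 5L) {
  fold_of <- stratified_kfold(train_table, k = k, seed = seed)
  train_table <- dplyr::arrange(train_table, .data$record_id)
  folds <- lapply(seq_len(k), function(f) {
    val_ids <- names(fold_of)[fold_of == f]
    tr <- train_table[!train_table$record_id %in% val_ids,
                      c("record_id", "label", features)]
    va <- train_table[train_table$record_id %in% val_ids, , drop = FALSE]
    bal <- smote_oversample(tr, k_neighbors = k_neighbors,
                            seed = seed + 1000L * f)
    list(
      train_X = as.matrix(bal[features]),
      train_y = as.integer(as_label_factor(bal$label)) - 1L,
      val_X = as.matrix(va[features]),
      val_y = as.integer(as_label_factor(va$label)) - 1L,
      val_labels = va$label,
      bal_labels = bal$label,
      provenance = attr(bal, "smote_provenance"),
      allowed_ids = tr$record_id
    )
  })
  list(folds = folds, features = features, fold_of = fold_of)
}

# average CV misclassification error of a feature subset on prepared folds
cv_mce_folds <- function(cv, features, kind) {
  cols <- match(features, cv$features)
  stopifnot(!anyNA(cols))
  if (kind %in% c("lda", "qda")) {
    return(cv_mce_gauss_cpp(
      lapply(cv$folds, `[[`, "train_X"),
      lapply(cv$folds, `[[`, "train_y"),
      lapply(cv$folds, `[[`, "val_X"),
      lapply(cv$folds, `[[`, "val_y"),
      cols - 1L, kind == "qda"))
  }
  errs <- 0L
  total <- 0L
  for (f in cv$folds) {
    tr <- tibble::as_tibble(as.data.frame(f$train_X[, cols, drop = FALSE]))
    names(tr) <- features
    tr$label <- f$bal_labels
    va <- tibble::as_tibble(as.data.frame(f$val_X[, cols, drop = FALSE]))
    names(va) <- features
    model <- train_classifier(tr, features, kind)
    pred <- predict(model, va)$.pred
    errs <- errs + sum(pred != f$val_labels)
    total <- total + length(f$val_labels)
  }
  errs / total
}

#' Cross-validated misclassification error of a feature subset
#'
#' For each fold the remaining folds are SMOTE-balanced, a classifier is
#' trained on the given subset, and the untouched fold is predicted; the
#' MCE is total misclassified over total validated.
#'
#' @param train_table Feature table (one training partition).
#' @param features Feature subset to evaluate.
#' @param kind Classifier kind, see [ehg_classifiers()].
#' @param k Folds (default 5).
#' @param seed RNG seed (fold split and SMOTE draws).
#' @param k_neighbors SMOTE neighbors.
#' @return MCE as a proportion in \[0, 1\].
#' @export
cv_mce <- function(train_table, features, kind, k = 5L, seed = 1L,
                   k_neighbors = 5L) {
  cv <- build_cv_folds(train_table, features, k = k, seed = seed,
                       k_neighbors = k_neighbors)
  cv_mce_folds(cv, features, kind)
}

#' One sequential-forward-selection run
#'
#' Greedily adds, at each step, the feature whose addition minimizes the
#' cross-validated MCE (ties broken by the input p-value order), until all
#' features are ranked. `k_min` is the (first) minimum of the MCE curve.
#'
#' @param train_table Training-partition feature table.
#' @param features Candidate features in ascending p-value order.
#' @param kind Classifier kind.
#' @param k,seed,k_neighbors As in [cv_mce()].
#' @return List: `selected` (all features in selection order), `mce_curve`
#'   (same length), `k_min`.
#' @export
sfs_run <- function(train_table, features, kind, k = 5L, seed = 1L,
                    k_neighbors = 5L) {
  cv <- build_cv_folds(train_table, features, k = k, seed = seed,
                       k_neighbors = k_neighbors)
  selected <- character(0)
  mce_curve <- numeric(length(features))
  remaining <- features
  for (step in seq_along(features)) {
    scores <- vapply(remaining, function(f) {
      cv_mce_folds(cv, c(selected, f), kind)
    }, 1.0)
    best <- which.min(scores)   # first minimum = lowest p-value on ties
    mce_curve[step] <- scores[best]
    selected <- c(selected, remaining[best])
    remaining <- remaining[-best]
  }
  list(selected = selected, mce_curve = mce_curve,
       k_min = which.min(mce_curve),
       provenance = lapply(cv$folds, `[[`, "provenance"),
       allowed_ids = lapply(cv$folds, `[[`, "allowed_ids"))
}

#' Stabilized sequential forward selection
#'
#' Runs the SFS `n_reps` times, each on a fresh stratified 80/20 holdout of
#' the data, and aggregates the occurrence counts of the `k_min`-prefix of
#' every run into a frequency histogram. The number of features in the
#' final subset is the (first) minimum of the MCE curve averaged over runs,
#' and the final subset collects that many highest histogram peaks. The
#' per-repetition partitions are kept so the later performance evaluation
#' reuses exactly the same train/test splits.
#'
#' @param table Full feature table.
#' @param kind Classifier kind.
#' @param features Candidate feature names (default: all feature columns).
#' @param n_reps Number of SFS repetitions (study value 200).
#' @param base_seed Base seed; repetition i uses `base_seed + i`.
#' @param train_frac Holdout training fraction.
#' @param k,k_neighbors As in [cv_mce()].
#' @param pvalues Optional external p-value map for the initial sort.
#' @return An `ehg_selection`: histogram tibble, average MCE curve,
#'   `m_final`, `final_subset`, per-run results, partitions, leak audit.
#' @export
stabilized_selection <- function(table, kind,
                                 features = feature_columns(table),
                                 n_reps = 200L, base_seed = 1L,
                                 train_frac = 0.8, k = 5L,
                                 k_neighbors = 5L, pvalues = NULL) {
  check_two_classes(table)
  sorted <- sort_by_pvalue(table, features, pvalues)
  K <- length(sorted)
  H <- setNames(integer(K), sorted)
  M <- numeric(K)
  per_run <- vector("list", n_reps)
  plans <- vector("list", n_reps)
  audits <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    seed_i <- base_seed + i
    plan <- stratified_holdout(table, train_frac = train_frac,
                               seed = seed_i)
    train <- table[table$record_id %in% plan$train_ids, , drop = FALSE]
    run <- sfs_run(train, sorted, kind, k = k, seed = seed_i,
                   k_neighbors = k_neighbors)
    sel <- run$selected[seq_len(run$k_min)]
    H[sel] <- H[sel] + 1L
    M <- M + run$mce_curve
    per_run[[i]] <- tibble::tibble(rep = i, k_min = run$k_min,
                                   selected = list(sel),
                                   mce_curve = list(run$mce_curve))
    plans[[i]] <- plan
    audits[[i]] <- audit_leakage(run$provenance, run$allowed_ids)
  }
  avg_mce <- M / n_reps
  m_final <- which.min(avg_mce)
  hist_tab <- tibble::tibble(feature = sorted, p_rank = seq_len(K),
                             count = unname(H))
  hist_tab <- dplyr::arrange(hist_tab, dplyr::desc(.data$count),
                             .data$p_rank)
  audit <- dplyr::summarise(dplyr::bind_rows(audits),
                            n_synthetic = sum(.data$n_synthetic),
                            n_violations = sum(.data$n_violations))
  structure(list(
    histogram = hist_tab,
    avg_mce = avg_mce,
    m_final = m_final,
    final_subset = hist_tab$feature[seq_len(m_final)],
    per_run = dplyr::bind_rows(per_run),
    plans = plans,
    kind = kind,
    n_reps = n_reps,
    leak_audit = audit
  ), class = "ehg_selection")
}

#' @export
print.ehg_selection <- function(x, ...) {
  cat(sprintf("<ehg_selection: %s, %d reps, m_final = %d>\n", x$kind,
              x$n_reps, x$m_final))
  cat("final subset:", paste(x$final_subset, collapse = ", "), "\n")
  invisible(x)
}

#' Tally first/second-place features across selection runs
#'
#' For each selection result the features with the highest and
#' second-highest occurrence counts take first and second place (ties by
#' p-value order, which the histogram already encodes). Feature A is the
#' overall most frequent first-place feature; feature B the most frequent
#' second-place feature.
#'
#' @param results List of `ehg_selection` objects (the study uses
#'   5 classifiers x 4 feature sets = 20).
#' @return An `ehg_tally`: `first_place`/`second_place` count tibbles and
#'   `feature_a`, `feature_b`.
#' @export
tally_top2 <- function(results) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "ehg_selection")))
  firsts <- vapply(results, function(r) r$histogram$feature[1L], "")
  seconds <- vapply(results, function(r) r$histogram$feature[2L], "")
  count_tab <- function(v) {
    tab <- sort(table(v), decreasing = TRUE)
    tibble::tibble(feature = names(tab), n = as.integer(tab))
  }
  fp <- count_tab(firsts)
  sp <- count_tab(seconds)
  feature_a <- fp$feature[1L]
  # the two most promising features are distinct: B is the most frequent
  # second-place feature other than A
  sp_b <- sp[sp$feature != feature_a, ]
  feature_b <- if (nrow(sp_b) > 0L) sp_b$feature[1L] else NA_character_
  structure(list(first_place = fp, second_place = sp,
                 feature_a = feature_a, feature_b = feature_b,
                 n_runs = length(results)),
            class = "ehg_tally")
}

#' @export
print.ehg_tally <- function(x, ...) {
  cat(sprintf("<ehg_tally over %d runs: A = %s (%d), B = %s (%d)>\n",
              x$n_runs, x$feature_a, x$first_place$n[1L], x$feature_b,
              x$second_place$n[1L]))
  invisible(x)
}
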