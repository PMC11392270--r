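#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stabilized-selection result
#'
#' @param x An `ehg_selection`.
#' @param ... Unused.
#' @return The occurrence histogram as a tibble (`feature`, `p_rank`,
#'   `count`), ordered by count.
#' @method tidy ehg_selection
#' @export
tidy.ehg_selection <- function(x, ...) x$histogram

#' @rdname tidy.ehg_selection
#' @return `glance()`: one row with `classifier`, `n_reps`, `m_final`,
#'   `min_avg_mce`, leak-audit counts.
#' @method glance ehg_selection
#' @export
glance.ehg_selection <- function(x, ...) {
  tibble::tibble(classifier = x$kind, n_reps = x$n_reps,
                 m_final = x$m_final, min_avg_mce = min(x$avg_mce),
                 n_synthetic = x$leak_audit$n_synthetic,
                 n_violations = x$leak_audit$n_violations)
}

#' Tidy a repeated-evaluation result
#'
#' @param x An `ehg_evaluation`.
#' @param ... Unused.
#' @return `tidy()`: the per-split metric summary (mean, sd per Se, Sp,
#'   PPV, NPV, CA, AUC), mirroring the study's performance tables.
#' @method tidy ehg_evaluation
#' @export
tidy.ehg_evaluation <- function(x, ...) {
  dplyr::mutate(x$summary, classifier = x$kind,
                features = paste(x$features, collapse = "+"),
                .before = 1L)
}

#' @rdname tidy.ehg_evaluation
#' @return `glance()`: one row with test-set CA and AUC (mean and sd) and
#'   the train-test generalization gaps.
#' @method glance ehg_evaluation
#' @export
glance.ehg_evaluation <- function(x, ...) {
  g <- function(split, metric, col) {
    x$summary[[col]][x$summary$split == split & x$summary$metric == metric]
  }
  tibble::tibble(
    classifier = x$kind,
    features = paste(x$features, collapse = "+"),
    n_reps = length(x$roc_curves),
    ca_test = g("test", "CA", "mean"), ca_sd = g("test", "CA", "sd"),
    auc_test = g("test", "AUC", "mean"), auc_sd = g("test", "AUC", "sd"),
    ca_gap = g("train", "CA", "mean") - g("test", "CA", "mean"),
    auc_gap = g("train", "AUC", "mean") - g("test", "AUC", "mean"),
    n_violations = x$leak_audit$n_violations
  )
}

#' Tidy a top-two tally
#'
#' @param x An `ehg_tally`.
#' @param ... Unused.
#' @return Long tibble with `place` (`"first"`/`"second"`), `feature`, `n`.
#' @method tidy ehg_tally
#' @export
tidy.ehg_tally <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$first_place, place = "first", .before = 1L),
    dplyr::mutate(x$second_place, place = "second", .before = 1L))
}
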