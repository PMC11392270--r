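#' Confusion-count classification metrics
#'
#' Premature is the positive class: TP are correctly predicted premature
#' records, TN correctly predicted term records. Sensitivity, specificity,
#' predictive values and accuracy follow directly from the counts;
#' undefined ratios (zero denominator) are returned as `NaN` with a
#' warning.
#'
#' @param labels True labels (`"premature"`/`"term"`).
#' @param predictions Predicted labels.
#' @return One-row tibble: `TP`, `FN`, `TN`, `FP`, `Se`, `Sp`, `PPV`,
#'   `NPV`, `CA`.
#' @export
confusion_metrics <- function(labels, predictions) {
  if (length(labels) == 0L) stop("empty input", call. = FALSE)
  stopifnot(length(labels) == length(predictions))
  tp <- sum(labels == "premature" & predictions == "premature")
  fn <- sum(labels == "premature" & predictions == "term")
  tn <- sum(labels == "term" & predictions == "term")
  fp <- sum(labels == "term" & predictions == "premature")
  ratio <- function(num, den, what) {
    if (den == 0L) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  tibble::tibble(
    TP = tp, FN = fn, TN = tn, FP = fp,
    Se = ratio(tp, tp + fn, "Se"),
    Sp = ratio(tn, tn + fp, "Sp"),
    PPV = ratio(tp, tp + fp, "PPV"),
    NPV = ratio(tn, tn + fn, "NPV"),
    CA = (tp + tn) / (tp + fn + tn + fp)
  )
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique score values (ties
#' grouped) and integrates sensitivity over the false positive rate by the
#' trapezoidal rule, which equals the Mann-Whitney pair-counting statistic
#' with ties counted one half.
#'
#' @param labels True labels (`"premature"`/`"term"`), both present.
#' @param scores Continuous premature-likeness scores (larger = more
#'   premature-like).
#' @return An `ehg_roc`: list with `points` (tibble `fpr`, `tpr`, from
#'   (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  pos <- labels == "premature"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes needed for a ROC curve", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  grp_end <- c(which(diff(s) != 0), length(s))   # last index of each tie set
  tpr <- c(0, cumsum(p)[grp_end] / n1, 1)
  fpr <- c(0, cumsum(!p)[grp_end] / n0, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(points = tibble::tibble(fpr = fpr, tpr = tpr), auc = auc),
            class = "ehg_roc")
}

#' @export
print.ehg_roc <- function(x, ...) {
  cat(sprintf("<ehg_roc: AUC = %.4f, %d points>\n", x$auc,
              nrow(x$points)))
  invisible(x)
}

#' Repeated holdout evaluation under Partition-Synthesis
#'
#' For each persisted partition: the training rows are SMOTE-balanced
#' (never the test rows), the classifier is trained on the given features,
#' and metrics are computed on the untouched test set and, for the
#' generalization check, on the training set. Means and (n-1) standard
#' deviations are aggregated over repetitions; repetitions where a metric
#' is undefined are excluded from that metric's aggregate.
#'
#' @param table Full feature table.
#' @param features Feature subset (one or two of the identified
#'   biomarkers, typically).
#' @param kind Classifier kind.
#' @param plans List of `ehg_partition` objects (from
#'   [stabilized_selection()]'s `plans`, or fresh [stratified_holdout()]
#'   calls).
#' @param k_neighbors SMOTE neighbors.
#' @return An `ehg_evaluation`: `summary` (mean/sd per metric for test and
#'   train), `per_rep`, `roc_curves` (test-set ROC per repetition),
#'   `models`, `leak_audit`.
#' @export
repeated_evaluation <- function(table, features, kind, plans,
                                k_neighbors = 5L) {
  stopifnot(length(plans) >= 1L)
  per_rep <- vector("list", length(plans))
  rocs <- vector("list", length(plans))
  models <- vector("list", length(plans))
  audits <- vector("list", length(plans))
  for (i in seq_along(plans)) {
    plan <- plans[[i]]
    train <- table[table$record_id %in% plan$train_ids, , drop = FALSE]
    test <- table[table$record_id %in% plan$test_ids, , drop = FALSE]
    bal <- smote_oversample(train[c("record_id", "label", features)],
                            k_neighbors = k_neighbors,
                            seed = plan$seed + 500000L)
    audits[[i]] <- audit_leakage(attr(bal, "smote_provenance"),
                                 plan$train_ids)
    model <- train_classifier(bal, features, kind)
    models[[i]] <- model
    pr_test <- predict(model, test)
    pr_train <- predict(model, train)
    m_test <- suppressWarnings(confusion_metrics(test$label, pr_test$.pred))
    m_train <- suppressWarnings(
      confusion_metrics(train$label, pr_train$.pred))
    roc_test <- roc_auc(test$label, pr_test$.score)
    rocs[[i]] <- roc_test
    m_test$AUC <- roc_test$auc
    m_train$AUC <- roc_auc(train$label, pr_train$.score)$auc
    per_rep[[i]] <- dplyr::bind_rows(
      dplyr::mutate(m_test, rep = i, split = "test", .before = 1L),
      dplyr::mutate(m_train, rep = i, split = "train", .before = 1L))
  }
  per_rep <- dplyr::bind_rows(per_rep)
  metrics <- c("Se", "Sp", "PPV", "NPV", "CA", "AUC")
  summary <- per_rep |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric") |>
    dplyr::group_by(.data$split, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value[is.finite(.data$value)]),
      sd = if (sum(is.finite(.data$value)) > 1L) {
        sd(.data$value[is.finite(.data$value)])
      } else 0,
      n_undefined = sum(!is.finite(.data$value)),
      .groups = "drop")
  audit <- dplyr::summarise(dplyr::bind_rows(audits),
                            n_synthetic = sum(.data$n_synthetic),
                            n_violations = sum(.data$n_violations))
  structure(list(summary = summary, per_rep = per_rep,
                 roc_curves = rocs, models = models, features = features,
                 kind = kind, leak_audit = audit),
            class = "ehg_evaluation")
}

#' @export
print.ehg_evaluation <- function(x, ...) {
  cat(sprintf("<ehg_evaluation: %s on %s, %d reps>\n", x$kind,
              paste(x$features, collapse = " + "),
              length(x$roc_curves)))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Vertically averaged ROC curve
#'
#' Interpolates each repetition's ROC curve onto a common false positive
#' rate grid and averages the sensitivities pointwise, with per-point SD.
#'
#' @param curves List of `ehg_roc` objects.
#' @param grid_n Number of grid points (default 101).
#' @return An `ehg_avg_roc`: tibble `fpr`, `mean_tpr`, `sd_tpr`.
#' @export
average_roc <- function(curves, grid_n = 101L) {
  stopifnot(length(curves) >= 1L)
  grid <- seq(0, 1, length.out = grid_n)
  tprs <- vapply(curves, function(cv) {
    # sensitivity attained at false positive rate <= g (stepwise, so
    # degenerate step curves are not linearized away)
    vapply(grid, function(g) {
      max(cv$points$tpr[cv$points$fpr <= g + 1e-12])
    }, 1.0)
  }, numeric(grid_n))
  tprs <- matrix(tprs, nrow = grid_n)
  structure(list(points = tibble::tibble(
    fpr = grid,
    mean_tpr = rowMeans(tprs),
    sd_tpr = apply(tprs, 1L, function(v) {
      if (length(v) > 1L) sd(v) else 0
    }))), class = "ehg_avg_roc")
}

#' Average single-feature decision threshold
#'
#' Locates, for each trained single-feature model, the feature value where
#' the premature likelihood crosses 0.5 (bisection), and averages across
#' models. Models whose score does not cross 0.5 inside the range are
#' skipped with a warning.
#'
#' @param models List of single-feature `ehg_model` objects (possibly from
#'   several classifiers and repetitions).
#' @param range Numeric length-2 feature range to search.
#' @return An `ehg_boundary` with `mode = "threshold_1d"`, the average
#'   `threshold`, per-model thresholds, and the skipped-model count.
#' @export
average_threshold_1d <- function(models, range) {
  stopifnot(length(range) == 2L, range[1] < range[2])
  thresholds <- vapply(models, function(m) {
    stopifnot(length(m$features) == 1L)
    f <- function(v) {
      nd <- tibble::tibble(x = v)
      names(nd) <- m$features
      predict(m, nd)$.score - 0.5
    }
    lo <- range[1]
    hi <- range[2]
    if (sign(f(lo)) == sign(f(hi))) return(NA_real_)
    stats::uniroot(f, lower = lo, upper = hi, tol = 1e-8)$root
  }, 1.0)
  n_skipped <- sum(is.na(thresholds))
  if (n_skipped > 0L) {
    warning(n_skipped, " model(s) had no 0.5-likelihood crossing in range",
            call. = FALSE)
  }
  structure(list(mode = "threshold_1d",
                 threshold = mean(thresholds, na.rm = TRUE),
                 per_model = thresholds, n_skipped = n_skipped,
                 feature = models[[1L]]$features),
            class = "ehg_boundary")
}

#' Average two-feature decision boundary
#'
#' Scores every point of a feature-space grid with each model, averages
#' the premature-likelihood matrices, and extracts the 50%-likelihood
#' isoline.
#'
#' @param models List of two-feature `ehg_model` objects.
#' @param xlim,ylim Feature ranges (padded 10% by default when derived
#'   from data elsewhere).
#' @param n Grid resolution per axis (default 200).
#' @return An `ehg_boundary` with `mode = "isoline_2d"`: grid vectors, the
#'   mean likelihood matrix, and the 0.5-level contour segments.
#' @export
average_boundary_2d <- function(models, xlim, ylim, n = 200L) {
  stopifnot(length(models) >= 1L,
            all(vapply(models, function(m) length(m$features) == 2L, TRUE)))
  feats <- models[[1L]]$features
  gx <- seq(xlim[1], xlim[2], length.out = n)
  gy <- seq(ylim[1], ylim[2], length.out = n)
  grid <- tidyr::expand_grid(x = gx, y = gy)
  names(grid) <- feats
  score_mat <- matrix(0, nrow = n, ncol = n)
  for (m in models) {
    score_mat <- score_mat +
      matrix(predict(m, grid)$.score, nrow = n, byrow = TRUE)
  }
  score_mat <- score_mat / length(models)  # rows follow gx, cols gy
  contours <- grDevices::contourLines(gx, gy, score_mat, levels = 0.5)
  structure(list(mode = "isoline_2d", x = gx, y = gy,
                 likelihood = score_mat, contour = contours,
                 features = feats),
            class = "ehg_boundary")
}

#' Two-feature linear composite biomarker
#'
#' Weighted sum of the two headline biomarkers, the normalized peak
#' amplitude in band B0Lp (`PA_S3_B0Lp`) and the band-B3 median frequency
#' (`MF_S2_B3`): `score = 5.98 * pa - 4.02 * mf + 12.78`. A positive score
#' indicates danger of premature birth, and larger scores mean higher
#' premature probability; the hard label is the sign.
#'
#' @param pa Normalized peak amplitude values (dimensionless).
#' @param mf Band-B3 median frequency values (Hz).
#' @param w,b Discriminant weights and offset.
#' @return Tibble with `score` and `label` (+1 premature / -1 term).
#' @export
composite_biomarker <- function(pa, mf, w = c(5.98, -4.02), b = -12.78) {
  stopifnot(length(pa) == length(mf), all(is.finite(pa)),
            all(is.finite(mf)))
  score <- w[1] * pa + w[2] * mf - b
  tibble::tibble(score = score, label = sign(score))
}
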