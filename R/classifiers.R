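#' The five study classifiers
#'
#' @return Character vector of classifier kinds: pseudo-linear and
#'   pseudo-quadratic discriminants (Moore-Penrose pseudoinverse covariance,
#'   so training never fails on singular covariance), Gaussian Naive Bayes
#'   with empirical class priors, and SVMs with 3rd-order polynomial and RBF
#'   kernels.
#' @export
ehg_classifiers <- function() {
  c("lda", "qda", "nbayes", "svm_poly3", "svm_rbf")
}

label_levels <- c("term", "premature")

as_label_factor <- function(x) factor(x, levels = label_levels)

#' Train a classifier on a feature table
#'
#' Larger scores always mean "more premature-like"; classifiers without
#' calibrated posteriors (the SVMs) report a logistic squashing of their
#' decision value.
#'
#' @param table Feature table (typically SMOTE-balanced training rows).
#' @param features Character vector of feature column names to use.
#' @param kind One of [ehg_classifiers()].
#' @return An `ehg_model`; use `predict(model, table)` to get a tibble with
#'   `.score` (premature likelihood in \[0, 1\]) and `.pred`.
#' @export
train_classifier <- function(table, features,
                             kind = c("lda", "qda", "nbayes", "svm_poly3",
                                      "svm_rbf")) {
  kind <- match.arg(kind)
  check_two_classes(table)
  stopifnot(all(features %in% names(table)))
  X <- as.matrix(table[features])
  y <- as_label_factor(table$label)
  fit <- switch(kind,
    lda = gauss_disc_fit_cpp(X, as.integer(y) - 1L, FALSE),
    qda = gauss_disc_fit_cpp(X, as.integer(y) - 1L, TRUE),
    nbayes = e1071::naiveBayes(x = as.data.frame(X), y = y),
    svm_poly3 = suppressWarnings(
      e1071::svm(X, y, kernel = "polynomial", degree = 3, scale = TRUE)),
    svm_rbf = suppressWarnings(
      e1071::svm(X, y, kernel = "radial", scale = TRUE))
  )
  structure(list(kind = kind, fit = fit, features = features),
            class = "ehg_model")
}

#' @export
print.ehg_model <- function(x, ...) {
  cat(sprintf("<ehg_model %s on %s>\n", x$kind,
              paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Predict premature likelihood
#'
#' @param object An `ehg_model`.
#' @param newdata Feature table (or data frame with the model's feature
#'   columns).
#' @param ... Unused.
#' @return Tibble with `.score` (premature likelihood) and `.pred`
#'   (`"term"`/`"premature"`, thresholded at 0.5).
#' @export
predict.ehg_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$features])
  score <- switch(object$kind,
    lda = ,
    qda = {
      sc <- gauss_disc_score_cpp(object$fit, X)
      1 / (1 + exp(sc[, 1] - sc[, 2]))    # softmax over the two classes
    },
    nbayes = {
      p <- predict(object$fit, as.data.frame(X), type = "raw")
      p[, "premature"]
    },
    svm_poly3 = ,
    svm_rbf = {
      pr <- predict(object$fit, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # decision value is positive for the class named first in the colname
      sgn <- if (startsWith(colnames(dv)[1], "premature")) 1 else -1
      stats::plogis(sgn * dv[, 1])
    }
  )
  score <- unname(as.numeric(score))
  tibble::tibble(
    .score = score,
    .pred = ifelse(score > 0.5, "premature", "term")
  )
}
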