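test_that("confusion metrics follow the count definitions exactly", {
  lab <- c(rep("premature", 3), rep("term", 4))
  pred <- c("premature", "premature", "term",
            "premature", "term", "term", "term")
  m <- confusion_metrics(lab, pred)
  expect_equal(unlist(m[c("TP", "FN", "TN", "FP")]),
               c(TP = 2, FN = 1, TN = 3, FP = 1))
  expect_equal(m$Se, 2 / 3)
  expect_equal(m$Sp, 3 / 4)
  expect_equal(m$PPV, 2 / 3)
  expect_equal(m$NPV, 3 / 4)
  expect_equal(m$CA, 5 / 7)
  perfect <- confusion_metrics(lab, lab)
  expect_true(all(unlist(perfect[c("Se", "Sp", "PPV", "NPV", "CA")]) == 1))
  degen <- suppressWarnings(confusion_metrics(lab, rep("term", 7)))
  expect_equal(degen$Se, 0)
  expect_equal(degen$Sp, 1)
  expect_true(is.nan(degen$PPV))
  expect_error(confusion_metrics(character(), character()), "empty")
})

test_that("metric identities hold on random confusion counts", {
  withr::with_seed(77, {
    for (i in 1:20) {
      lab <- sample(c("premature", "term"), 40, replace = TRUE,
                    prob = c(0.3, 0.7))
      pred <- sample(c("premature", "term"), 40, replace = TRUE)
      if (length(unique(lab)) < 2) next
      m <- suppressWarnings(confusion_metrics(lab, pred))
      expect_equal(m$Se, m$TP / (m$TP + m$FN))
      expect_equal(m$Sp, m$TN / (m$TN + m$FP))
      expect_equal(m$CA, (m$TP + m$TN) / 40)
    }
  })
})

test_that("roc_auc equals the pair-counting oracle on random instances", {
  withr::with_seed(123, {
    for (i in 1:50) {
      n <- sample(6:25, 1)
      lab <- c("premature", "term",
               sample(c("premature", "term"), n - 2, replace = TRUE))
      scores <- round(rnorm(n), sample(0:2, 1))  # force some ties
      roc <- roc_auc(lab, scores)
      expect_equal(roc$auc, oracle_auc(lab, scores), tolerance = 1e-12)
      expect_equal(roc$points$fpr[1], 0)
      expect_equal(utils::tail(roc$points$tpr, 1), 1)
      expect_true(all(diff(roc$points$tpr) >= 0))
      expect_true(all(diff(roc$points$fpr) >= 0))
    }
  })
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(5, {
    lab <- sample(c("premature", "term"), 30, replace = TRUE)
    lab[1:2] <- c("premature", "term")
    s <- rnorm(30)
    a0 <- roc_auc(lab, s)$auc
    expect_equal(roc_auc(lab, exp(s))$auc, a0)
    expect_equal(roc_auc(lab, 5 * s - 2)$auc, a0)
  })
  expect_error(roc_auc(rep("term", 5), rnorm(5)), "both classes")
})

test_that("roc_auc agrees with pROC on a reference case", {
  skip_if_not_installed("pROC")
  withr::with_seed(6, {
    lab <- c(rep("premature", 15), rep("term", 25))
    s <- c(rnorm(15, 1), rnorm(25))
    ours <- roc_auc(lab, s)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = lab, predictor = s, levels = c("term", "premature"),
      direction = "<", quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("average ROC: identity, midpoint and monotonicity", {
  c1 <- structure(list(points = tibble::tibble(
    fpr = c(0, 0, 1), tpr = c(0, 1, 1)), auc = 1), class = "ehg_roc")
  c2 <- structure(list(points = tibble::tibble(
    fpr = c(0, 1, 1), tpr = c(0, 0, 1)), auc = 0), class = "ehg_roc")
  single <- average_roc(list(c1), grid_n = 5)
  expect_equal(single$points$mean_tpr, c(1, 1, 1, 1, 1))
  avg <- average_roc(list(c1, c2), grid_n = 5)
  expect_equal(avg$points$mean_tpr, c(0.5, 0.5, 0.5, 0.5, 1))
  expect_true(all(diff(avg$points$mean_tpr) >= -1e-12))
  expect_true(all(avg$points$sd_tpr >= 0))
})

test_that("repeated evaluation under Partition-Synthesis is leak-free", {
  tab <- toy_feature_table(n_min = 14, n_maj = 40, gap = 3, seed = 55)
  plans <- lapply(1:4, function(i) stratified_holdout(tab, seed = i))
  ev <- repeated_evaluation(tab, "signal", "lda", plans)
  expect_s3_class(ev, "ehg_evaluation")
  expect_equal(ev$leak_audit$n_violations, 0L)
  expect_gt(ev$leak_audit$n_synthetic, 0L)
  sm <- ev$summary
  expect_true(all(sm$mean[sm$metric != "AUC"] >= 0 &
                    sm$mean[sm$metric != "AUC"] <= 1))
  expect_true(all(sm$sd >= 0))
  # strong planted effect: test performance close to training performance
  gl <- glance(ev)
  expect_lt(abs(gl$auc_gap), 0.1)
  expect_gt(gl$auc_test, 0.9)
})

test_that("repeated evaluation with one plan equals single-run metrics", {
  tab <- toy_feature_table(n_min = 12, n_maj = 30, gap = 5, seed = 8)
  plan <- stratified_holdout(tab, seed = 3)
  ev <- repeated_evaluation(tab, "signal", "nbayes", list(plan))
  sm <- ev$summary
  expect_true(all(sm$sd == 0))
  expect_equal(nrow(ev$per_rep), 2L)  # one test row, one train row
})

test_that("1-D average threshold lands in the class gap", {
  tab <- toy_feature_table(n_min = 15, n_maj = 30, gap = 8, seed = 4)
  models <- lapply(c("lda", "qda", "nbayes"), function(k) {
    train_classifier(smote_oversample(tab, seed = 1), "signal", k)
  })
  b <- average_threshold_1d(models, range(tab$signal))
  expect_s3_class(b, "ehg_boundary")
  expect_equal(b$mode, "threshold_1d")
  gap_lo <- max(tab$signal[tab$label == "term"])
  gap_hi <- min(tab$signal[tab$label == "premature"])
  expect_gt(b$threshold, gap_lo)
  expect_lt(b$threshold, gap_hi)
  expect_equal(b$n_skipped, 0L)
})

test_that("2-D averaged LDA boundary approximates the analytic midline", {
  withr::with_seed(21, {
    n <- 60
    tab <- tibble::tibble(
      record_id = sprintf("g%03d", 1:(2 * n)),
      label = rep(c("term", "premature"), each = n),
      f1 = c(rnorm(n, 0), rnorm(n, 4)),
      f2 = c(rnorm(n, 0), rnorm(n, 4)))
  })
  model <- train_classifier(tab, c("f1", "f2"), "lda")
  b <- average_boundary_2d(list(model), xlim = c(-3, 7), ylim = c(-3, 7),
                           n = 80)
  expect_equal(b$mode, "isoline_2d")
  expect_gt(length(b$contour), 0)
  # equal spherical classes: boundary is f1 + f2 = 4 (checked inside the
  # data region; small empirical tilt is amplified at the grid corners)
  pts <- b$contour[[1]]
  core <- pts$x >= 0.5 & pts$x <= 3.5
  expect_true(any(core))
  expect_lt(max(abs(pts$x[core] + pts$y[core] - 4)), 0.6)
  # single model: averaged field equals that model's score field
  nd <- tibble::tibble(f1 = b$x[10], f2 = b$y[20])
  expect_equal(b$likelihood[10, 20], predict(model, nd)$.score,
               tolerance = 1e-9)
})

test_that("composite biomarker reproduces the printed discriminant", {
  # boundary point: 5.98*0.66 - 4.02*mf + 12.78 = 0  =>  mf = 4.16074...
  mf_star <- (5.98 * 0.66 + 12.78) / 4.02
  b <- composite_biomarker(0.66, mf_star)
  expect_equal(b$score, 0, tolerance = 1e-12)
  b2 <- composite_biomarker(1.0, 3.5)
  expect_equal(b2$score, 5.98 - 14.07 + 12.78)
  expect_equal(b2$label, 1)
  b3 <- composite_biomarker(0, 5.0)
  expect_equal(b3$score, -7.32, tolerance = 1e-12)
  expect_equal(b3$label, -1)
  many <- composite_biomarker(c(0.2, 0.9), c(4.5, 3.9))
  expect_equal(nrow(many), 2L)
  expect_error(composite_biomarker(NA, 1))
})
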