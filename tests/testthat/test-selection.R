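test_that("p-value sorting orders, tie-breaks, and falls back", {
  tab <- toy_feature_table()
  expect_equal(sort_by_pvalue(tab, c("signal", "noise1"),
                              pvalues = c(signal = 0.01, noise1 = 0.5)),
               c("signal", "noise1"))
  expect_equal(sort_by_pvalue(tab, c("b", "a"),
                              pvalues = c(a = 0.2, b = 0.2)),
               c("a", "b"))
  expect_warning(out <- sort_by_pvalue(tab, c("signal", "noise1"),
                                       pvalues = c(signal = 0.1)),
                 "falling back")
  expect_equal(out, c("noise1", "signal"))
  # data-driven sort puts the planted feature first
  expect_equal(sort_by_pvalue(tab)[1], "signal")
})

test_that("cv_mce is zero for separable data and reproducible", {
  tab <- toy_feature_table(gap = 10)
  for (kind in c("lda", "nbayes")) {
    expect_equal(cv_mce(tab, "signal", kind, seed = 3), 0, info = kind)
  }
  m1 <- cv_mce(tab, c("signal", "noise1"), "qda", seed = 5)
  m2 <- cv_mce(tab, c("signal", "noise1"), "qda", seed = 5)
  expect_identical(m1, m2)
})

test_that("cv_mce hovers near chance for label-independent features", {
  tab <- toy_feature_table(n_min = 30, n_maj = 30, gap = 0, seed = 31)
  m <- mean(vapply(1:5, function(i) {
    cv_mce(tab, c("signal", "noise1"), "lda", seed = i)
  }, 1.0))
  expect_gt(m, 0.3)
  expect_lt(m, 0.7)
})

test_that("SFS ranks a dominant feature first and is exhaustive", {
  tab <- toy_feature_table(gap = 8)
  feats <- sort_by_pvalue(tab)
  run <- sfs_run(tab, feats, "lda", seed = 2)
  expect_equal(run$selected[1], "signal")
  expect_equal(run$k_min, 1L)
  expect_length(run$mce_curve, length(feats))
  expect_setequal(run$selected, feats)
})

test_that("greedy step optimality holds against brute-force re-evaluation", {
  tab <- toy_feature_table(n_min = 14, n_maj = 28, gap = 1.2, seed = 17)
  feats <- sort_by_pvalue(tab)
  seed <- 4
  run <- sfs_run(tab, feats, "lda", seed = seed)
  cv <- ehgrisk:::build_cv_folds(tab, feats, k = 5, seed = seed,
                                 k_neighbors = 5)
  # at step 1 the chosen feature's MCE must be <= every alternative's
  first <- run$selected[1]
  mce_first <- ehgrisk:::cv_mce_folds(cv, first, "lda")
  for (f in setdiff(feats, first)) {
    expect_gte(ehgrisk:::cv_mce_folds(cv, f, "lda"), mce_first)
  }
  expect_equal(mce_first, run$mce_curve[1])
})

test_that("stabilized selection aggregates histogram bookkeeping correctly", {
  tab <- toy_feature_table(n_min = 12, n_maj = 30, gap = 6)
  sel <- stabilized_selection(tab, "lda", n_reps = 6, base_seed = 100)
  expect_s3_class(sel, "ehg_selection")
  # dominant feature appears in every repetition's selected subset
  h <- sel$histogram
  expect_equal(h$count[h$feature == "signal"], 6L)
  expect_true(all(h$count <= 6L))
  # sum of counts equals sum of k_min over runs
  expect_equal(sum(h$count), sum(sel$per_run$k_min))
  expect_length(sel$avg_mce, 4L)
  expect_equal(sel$m_final, which.min(sel$avg_mce))
  expect_equal(sel$final_subset, h$feature[seq_len(sel$m_final)])
  expect_length(sel$plans, 6L)
  expect_equal(sel$leak_audit$n_violations, 0L)
  # broom methods
  expect_s3_class(tidy(sel), "tbl_df")
  expect_equal(glance(sel)$m_final, sel$m_final)
})

test_that("selection is reproducible from the base seed", {
  tab <- toy_feature_table(gap = 2)
  s1 <- stabilized_selection(tab, "qda", n_reps = 3, base_seed = 9)
  s2 <- stabilized_selection(tab, "qda", n_reps = 3, base_seed = 9)
  expect_identical(s1$histogram, s2$histogram)
  expect_identical(s1$avg_mce, s2$avg_mce)
})

test_that("tally_top2 counts first and second places across runs", {
  tab <- toy_feature_table(gap = 8)
  sels <- lapply(1:3, function(i) {
    stabilized_selection(tab, "lda", n_reps = 4, base_seed = i * 50)
  })
  ty <- tally_top2(sels)
  expect_equal(ty$feature_a, "signal")
  expect_equal(sum(ty$first_place$n), 3L)
  expect_equal(sum(ty$second_place$n), 3L)
  expect_false(ty$feature_b == ty$feature_a)
  # recount from the histograms independently
  firsts <- vapply(sels, function(s) s$histogram$feature[1], "")
  expect_equal(ty$first_place$n[ty$first_place$feature == "signal"],
               sum(firsts == "signal"))
  expect_s3_class(tidy(ty), "tbl_df")
})
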