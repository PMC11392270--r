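test_that("generated records have the configured shape and determinism", {
  rec <- generate_record("term", fs = 20, duration_s = 1800, seed = 1)
  expect_equal(rec$n_samples, 36000L)
  expect_equal(colnames(rec$signals), c("S1", "S2", "S3"))
  r1 <- generate_record("premature", fs = 20, duration_s = 120, seed = 5)
  r2 <- generate_record("premature", fs = 20, duration_s = 120, seed = 5)
  expect_identical(r1$signals, r2$signals)
  r3 <- generate_record("premature", fs = 20, duration_s = 120, seed = 6)
  expect_false(identical(r1$signals, r3$signals))
  expect_lt(r1$meta$gestation_at_delivery, 37)
})

test_that("effect invariants keep the third harmonic inside B3", {
  expect_error(ehg_effects(mhr_base = 1.2, mhr_shift = 0.2), "B3")
  expect_error(ehg_effects(mhr_base = 1.7), "B3")
  expect_error(ehg_effects(fwl_peak_gain = 0.5))
  ok <- ehg_effects()
  expect_gte(3 * (ok$mhr_base - ok$mhr_shift), 3.5)
  expect_lte(3 * ok$mhr_base, 5.0)
})

test_that("generate_dataset honors group sizes and the master seed", {
  cfg <- ehg_synth_config(
    group_sizes = c(PL = 4, TL = 8, IL = 2, CL = 1, ICL = 1),
    duration_s = 120, seed = 42)
  col <- generate_dataset(cfg)
  expect_equal(length(col$records), 16L)
  gc <- group_counts(col)
  expect_equal(gc$n, c(4L, 8L, 2L, 1L, 1L))
  labels <- vapply(col$records, ehgrisk:::record_label, "")
  expect_equal(sum(labels == "premature"), 4L)
  col2 <- generate_dataset(cfg)
  expect_identical(col$records[[1]]$signals, col2$records[[1]]$signals)
  # default config mirrors the study's 32 premature vs 196 term imbalance
  def <- ehg_synth_config()
  expect_equal(unname(def$group_sizes[c("PL", "TL", "IL", "CL", "ICL")]),
               c(32, 132, 43, 8, 13))
})

test_that("planted effects separate classes on the headline features", {
  cfg <- ehg_synth_config(
    group_sizes = c(PL = 12, TL = 12, IL = 0, CL = 0, ICL = 0),
    duration_s = 180, seed = 314,
    effects = ehg_effects(fwl_peak_gain = 2))
  specs <- ehg_feature_specs(bands = c("B0Lp", "B3"))
  tab <- extract_feature_table(generate_dataset(cfg), specs)
  pa <- split(tab$PA_S3_B0Lp, tab$label)
  expect_gt(mean(pa$premature), mean(pa$term))
  mf <- split(tab$MF_S2_B3, tab$label)
  expect_lt(mean(mf$premature), mean(mf$term))
})

test_that("null configuration leaves the headline features exchangeable", {
  cfg <- ehg_synth_config(
    group_sizes = c(PL = 40, TL = 40, IL = 0, CL = 0, ICL = 0),
    duration_s = 120, seed = 2718,
    effects = ehg_effects(fwl_peak_gain = 1, mhr_shift = 0))
  specs <- ehg_feature_specs(features = c("PA", "MF"),
                             bands = c("B0Lp", "B3"))
  tab <- extract_feature_table(generate_dataset(cfg), specs)
  p <- wilcox.test(tab$PA_S3_B0Lp[tab$label == "premature"],
                   tab$PA_S3_B0Lp[tab$label == "term"], exact = FALSE)
  expect_gt(p$p.value, 0.01)
})

test_that("increasing the FWL gain does not shrink the PA separation", {
  seps <- vapply(c(1, 2.2, 4), function(g) {
    cfg <- ehg_synth_config(
      group_sizes = c(PL = 15, TL = 15, IL = 0, CL = 0, ICL = 0),
      duration_s = 120, seed = 99,
      effects = ehg_effects(fwl_peak_gain = g))
    specs <- ehg_feature_specs(features = "PA", bands = "B0Lp")
    tab <- extract_feature_table(generate_dataset(cfg), specs)
    mean(tab$PA_S3_B0Lp[tab$label == "premature"]) -
      mean(tab$PA_S3_B0Lp[tab$label == "term"])
  }, 1.0)
  expect_true(all(diff(seps) > -0.05))
  expect_gt(seps[3], seps[1])
})

test_that("write_fixture produces a loadable record tree", {
  dir <- withr::local_tempdir()
  cfg <- ehg_synth_config(
    group_sizes = c(PL = 2, TL = 3, IL = 1, CL = 1, ICL = 1),
    duration_s = 120, seed = 8)
  col <- generate_dataset(cfg)
  write_fixture(col, dir)
  loaded <- load_dataset(dir)
  expect_equal(group_counts(loaded), group_counts(col))
  expect_warning(
    write_fixture(new_col <- structure(list(records = list(),
                                            groups = character()),
                                       class = "ehg_collection"),
                  dir), "empty")
})
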