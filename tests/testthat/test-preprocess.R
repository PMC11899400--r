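test_that("LOESS drift correction removes drift and preserves the QC anchor", {
  sim <- generate_feature_table(n_groups = 4, n_reps = 3, n_qc = 8,
                                n_features = 120, n_dam = 10,
                                drift_amplitude = 0.5, noise_cv = 0.05,
                                seed = 31)
  res <- qc_loess_correct(sim$table)
  st <- res$qc_stats
  # QC RSD falls for (nearly) every drifted feature
  expect_gte(mean(st$rsd_after < st$rsd_before), 0.95)
  # median QC level preserved per feature (the normalization anchor)
  qc <- sim$table$group == "QC"
  raw_med <- apply(intensity_matrix(sim$table)[qc, ], 2, median)
  cor_med <- apply(intensity_matrix(res$table)[qc, ], 2, median)
  expect_equal(unname(cor_med / raw_med), rep(1, ncol(res$table$intensities)),
               tolerance = 0.05)
  # group structure unchanged in expectation: group means move only mildly
  g <- sim$table$group
  for (grp in c("G1", "G4")) {
    before <- colMeans(intensity_matrix(sim$table)[g == grp, ])
    after <- colMeans(intensity_matrix(res$table)[g == grp, ])
    expect_equal(unname(after / before), rep(1, length(before)),
                 tolerance = 0.5)
  }
})

test_that("constant QC intensities leave the table unchanged", {
  groups <- c("A", "A", "B", "B", rep("QC", 4))
  mat <- cbind(F1 = c(5, 6, 7, 8, 3, 3, 3, 3),
               F2 = c(2, 2, 4, 4, 10, 10, 10, 10))
  tab <- table_from_matrix(mat, groups)
  res <- qc_loess_correct(tab)
  expect_equal(intensity_matrix(res$table), mat, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(res$qc_stats$rsd_after, c(0, 0), tolerance = 1e-8)
})

test_that("drift correction requires at least 4 QC injections", {
  tab <- tiny_table(c(1, 2, 3, 4, 5), c("A", "A", "B", "QC", "QC"))
  expect_error(qc_loess_correct(tab), class = "insufficient_qc")
})

test_that("RSD filtering applies the sd/mean * 100 rule with default 30%", {
  # QC values {1,2,3}: sd = 1, mean = 2 -> RSD 50%, removed;
  # QC values {1,1,1}: RSD 0%, retained.
  groups <- c("A", "B", rep("QC", 3))
  mat <- cbind(stable = c(5, 6, 1, 1, 1), noisy = c(5, 6, 1, 2, 3))
  tab <- table_from_matrix(mat, groups)
  expect_message(out <- rsd_filter(tab), "removed 1 of 2")
  expect_identical(feature_ids(out), "stable")
  expect_identical(formals(rsd_filter)$max_rsd, 30)
  # at a permissive threshold the noisy feature survives
  expect_identical(sort(feature_ids(rsd_filter(tab, max_rsd = 50))),
                   c("noisy", "stable"))
  no_qc <- tiny_table(c(1, 2), c("A", "B"))
  expect_error(rsd_filter(no_qc), class = "invalid_input")
})

test_that("internal-standard normalization is a per-sample ratio", {
  groups <- c("A", "B")
  mat <- cbind(F1 = c(200, 300), IS = c(100, 150))
  tab <- table_from_matrix(mat, groups)
  out <- internal_standard_normalize(tab, "IS", is_concentration = 1)
  expect_identical(feature_ids(out), "F1")
  expect_equal(unname(intensity_matrix(out)[, "F1"]), c(2, 2))
  # doubling every intensity and the IS intensity leaves output unchanged
  tab2 <- table_from_matrix(2 * mat, groups)
  expect_equal(intensity_matrix(internal_standard_normalize(tab2, "IS")),
               intensity_matrix(out))
  bad <- table_from_matrix(cbind(F1 = c(1, 1), IS = c(1, 0)), groups)
  expect_error(internal_standard_normalize(bad, "IS"),
               class = "invalid_input")
  expect_error(internal_standard_normalize(bad, "IS"), "S2")
})

test_that("half-minimum imputation and log2 behave as specified", {
  tab <- table_from_matrix(cbind(F1 = c(4, 4, 4), F2 = c(0, 4, 8),
                                 dead = c(0, 0, 0)),
                           c("A", "A", "B"))
  expect_warning(out <- impute_and_log2(tab), "no positive values")
  mat <- intensity_matrix(out)
  expect_equal(unname(mat[, "F1"]), c(2, 2, 2))       # log2(4) = 2
  expect_equal(unname(mat[, "F2"]), c(1, 2, 3))       # 0 -> min(4,8)/2 = 2
  expect_false("dead" %in% colnames(mat))
  expect_true(all(is.finite(mat)))
  expect_identical(out$scale, "log2")
})

test_that("autoscaling yields mean 0 / sd 1, is idempotent, drops constants", {
  tab <- table_from_matrix(cbind(F1 = c(1, 2, 3), flat = c(7, 7, 7)),
                           c("A", "B", "B"))
  expect_warning(out <- autoscale(tab), "zero-variance")
  mat <- intensity_matrix(out)
  expect_equal(unname(mat[, "F1"]), c(-1, 0, 1))
  expect_false("flat" %in% colnames(mat))
  again <- autoscale(out)
  expect_equal(intensity_matrix(again), mat, tolerance = 1e-12)
})

test_that("on drift-free data the chain equals the chain without correction", {
  sim <- generate_feature_table(n_groups = 3, n_reps = 3, n_qc = 5,
                                n_features = 40, n_dam = 5,
                                drift_amplitude = 0, noise_cv = 0, seed = 13)
  # noiseless non-spiked features are constant and dropped by autoscaling
  with_corr <- suppressMessages(suppressWarnings(run_preprocess(sim$table)))
  without <- suppressMessages(suppressWarnings(
    run_preprocess(sim$table, correct_drift = FALSE)))
  expect_equal(intensity_matrix(with_corr$autoscaled),
               intensity_matrix(without$autoscaled), tolerance = 1e-6)
  # each stage's output satisfies the next stage's preconditions end to end
  expect_s3_class(with_corr$autoscaled, "feature_table")
  expect_identical(with_corr$autoscaled$scale, "autoscaled")
})

test_that("feature tables round-trip through CSV", {
  sim <- generate_feature_table(n_groups = 2, n_reps = 2, n_qc = 4,
                                n_features = 6, n_dam = 1, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(sim$table, path)
  back <- read_feature_table(path)
  expect_equal(back$intensities, sim$table$intensities, tolerance = 1e-12)
  expect_identical(back$group, sim$table$group)
  expect_identical(back$injection_order, sim$table$injection_order)
})
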