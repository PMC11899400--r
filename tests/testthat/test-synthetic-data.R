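test_that("feature-table generation is seeded, sized and structured as designed", {
  sim1 <- generate_feature_table(n_groups = 4, n_reps = 3, n_qc = 4,
                                 n_features = 50, n_dam = 5, seed = 7)
  sim2 <- generate_feature_table(n_groups = 4, n_reps = 3, n_qc = 4,
                                 n_features = 50, n_dam = 5, seed = 7)
  sim3 <- generate_feature_table(n_groups = 4, n_reps = 3, n_qc = 4,
                                 n_features = 50, n_dam = 5, seed = 8)

  expect_identical(sim1$table$intensities, sim2$table$intensities)
  expect_false(identical(sim1$table$intensities, sim3$table$intensities))
  # 4 groups x 3 reps + 4 QC = 16 rows
  expect_equal(nrow(sim1$table$intensities), 16L)
  expect_equal(sum(sim1$table$group == "QC"), 4L)
  expect_true(all(sim1$table$intensities > 0))
  expect_false(anyDuplicated(sim1$table$injection_order) > 0)
  # QC injections anchor the start and end of the run
  qc_ord <- sim1$table$injection_order[sim1$table$group == "QC"]
  expect_equal(min(qc_ord), 1L)
  expect_equal(max(qc_ord), 16L)
  # truth invariants
  expect_true(all(sim1$truth$dam_features$feature_id %in%
                    feature_ids(sim1$table)))
  expect_true(all(sim1$truth$drift_model$amplitude >= 0))
  expect_error(generate_feature_table(n_groups = 2, n_reps = 2),
               class = "invalid_argument")  # seed is mandatory
  expect_error(generate_feature_table(n_features = 3, n_dam = 5, seed = 1),
               class = "invalid_argument")
})

test_that("spiked log2 effects are recovered from the emitted matrix", {
  sim <- generate_feature_table(n_groups = 2, n_reps = 50, n_qc = 4,
                                n_features = 60, n_dam = 10,
                                effect_log2 = 2, drift_amplitude = 0,
                                noise_cv = 0.05, seed = 21)
  mat <- log2(intensity_matrix(sim$table))
  g <- sim$table$group
  tgt <- sim$truth$target_group
  ref <- setdiff(unique(g), c("QC", tgt))
  for (f in sim$truth$dam_features$feature_id) {
    d <- mean(mat[g == tgt, f]) - mean(mat[g == ref, f])
    se <- sqrt(var(mat[g == tgt, f]) / 50 + var(mat[g == ref, f]) / 50)
    expect_lt(abs(d - 2), 3 * se)
  }
  # noiseless, drift-free emission reproduces the truth exactly
  sim0 <- generate_feature_table(n_groups = 2, n_reps = 3, n_qc = 4,
                                 n_features = 20, n_dam = 4,
                                 effect_log2 = 1.5, drift_amplitude = 0,
                                 noise_cv = 0, seed = 3)
  mat0 <- log2(intensity_matrix(sim0$table))
  g0 <- sim0$table$group
  tgt0 <- sim0$truth$target_group
  ref0 <- setdiff(unique(g0), c("QC", tgt0))
  diffs <- colMeans(mat0[g0 == tgt0, , drop = FALSE]) -
    colMeans(mat0[g0 == ref0, , drop = FALSE])
  expect_equal(unname(diffs[sim0$truth$dam_features$feature_id]),
               rep(1.5, 4), tolerance = 1e-12)
  expect_equal(max(abs(diffs[setdiff(names(diffs),
                                     sim0$truth$dam_features$feature_id)])),
               0, tolerance = 1e-12)
})

test_that("QC rows carry the pooled mean profile under no drift and noise", {
  sim <- generate_feature_table(n_groups = 3, n_reps = 4, n_qc = 5,
                                n_features = 15, n_dam = 3,
                                drift_amplitude = 0, noise_cv = 0, seed = 9)
  mat <- intensity_matrix(sim$table)
  qc <- sim$table$group == "QC"
  pooled <- colMeans(mat[!qc, , drop = FALSE])
  for (i in which(qc)) {
    expect_equal(unname(mat[i, ]), unname(pooled), tolerance = 1e-10)
  }
})

test_that("odor table generation records a self-consistent OAV ranking", {
  out1 <- generate_odor_table(n_compounds = 12, n_groups = 3, seed = 5)
  out2 <- generate_odor_table(n_compounds = 12, n_groups = 3, seed = 6)
  expect_false(identical(out1$table$peak_area, out2$table$peak_area))
  for (g in unique(out1$table$group)) {
    sub <- out1$table[out1$table$group == g, ]
    recomputed <- sub$compound_id[order(sub$peak_area / sub$odor_threshold,
                                        decreasing = TRUE)]
    expect_identical(out1$truth$oav_ranking[[g]], recomputed)
  }
  # single compound: trivially the reference in every group
  one <- generate_odor_table(n_compounds = 1, n_groups = 2, seed = 1)
  roav <- compute_roav(one$table)
  expect_true(all(roav$is_reference))
  expect_true(all(roav$roav == 100))
})

test_that("assay curve generation matches the 4PL shape and its truth", {
  conc <- c(0.1, 0.25, 0.5, 1, 1.5, 2, 3, 4)
  cv0 <- generate_assay_curves("DPPH", true_ic50 = 1.2, hill_slope = 2,
                               concentrations = conc, noise_sd = 0, seed = 2)
  # noiseless curve passes through 50% exactly at the true IC50
  expect_equal(100 / (1 + (1.2 / 1.2)^2), 50)
  expect_equal(cv0$scavenging,
               100 / (1 + (1.2 / conc)^2), tolerance = 1e-12)
  expect_identical(cv0, generate_assay_curves("DPPH", 1.2, 2, conc,
                                              noise_sd = 0, seed = 2))
  expect_error(generate_assay_curves("DPPH", 10, 2, conc, seed = 1),
               class = "invalid_argument")
  # absorbances are consistent with the scavenging formula
  expect_equal(scavenging_activity(cv0$a_sample, cv0$a_0), cv0$scavenging,
               tolerance = 1e-12)
})

test_that("annotation maps are total, seeded and well-formed", {
  ids <- sprintf("F%03d", 1:40)
  ann <- generate_annotation(ids, n_superclasses = 6, n_pathways = 8,
                             seed = 4)
  expect_identical(sort(names(ann$superclass)), sort(ids))
  expect_false(anyNA(ann$superclass))
  expect_true(all(lengths(ann$pathways) >= 1))
  expect_true(all(unlist(ann$pathways) %in% ids))
  expect_identical(ann, generate_annotation(ids, 6, 8, seed = 4))
  # degenerate: no pathways -> empty map and empty enrichment downstream
  ann0 <- generate_annotation(ids, 6, 0, seed = 4)
  expect_length(ann0$pathways, 0)
  expect_equal(nrow(enrich_pathways(ids[1:5], ids, ann0)), 0)
})
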