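make_two_group_table <- function(seed, n_reps = 5, n_features = 40,
                                 n_dam = 6, effect = 2, noise = 0.1) {
  sim <- generate_feature_table(n_groups = 2, n_reps = n_reps, n_qc = 4,
                                n_features = n_features, n_dam = n_dam,
                                effect_log2 = effect, drift_amplitude = 0,
                                noise_cv = noise, seed = seed)
  list(table = ft_bio(sim$table), truth = sim$truth)
}

ft_bio <- function(tab) {
  keep <- tab$group != "QC"
  feature_table(tab$intensities[keep, , drop = FALSE], tab$sample_id[keep],
                tab$group[keep], tab$injection_order[keep])
}

test_that("exchangeable groups yield no DAM calls", {
  # group B literally duplicates group A: zero up, zero down
  set.seed(41)
  half <- matrix(rlnorm(4 * 20, 10, 0.5), 4, 20)
  dup <- table_from_matrix(rbind(half, half), rep(c("A", "B"), each = 4))
  dd <- pairwise_dam(dup, "A", "B")
  expect_equal(sum(dd$status != "ns"), 0)
  sim <- generate_feature_table(n_groups = 2, n_reps = 6, n_qc = 4,
                                n_features = 30, n_dam = 0,
                                drift_amplitude = 0, seed = 17)
  dams <- pairwise_dam(ft_bio(sim$table), "G1", "G2")
  # without any true effect, chance calls are rare; allow the 5% raw-p rate
  expect_lte(sum(dams$status != "ns"), ceiling(0.15 * nrow(dams)))
  expect_identical(formals(pairwise_dam)$vip_threshold, 1)
  expect_identical(formals(pairwise_dam)$p_threshold, 0.05)
})

test_that("spiked features are recovered with the VIP>1 & p<0.05 rule", {
  tg <- make_two_group_table(seed = 23, n_reps = 10, n_features = 100,
                             n_dam = 30)
  dams <- pairwise_dam(tg$table, "G1", "G2")
  truth_ids <- tg$truth$dam_features$feature_id
  called <- dams$feature_id[dams$status != "ns"]
  expect_gte(mean(truth_ids %in% called), 0.95)
  expect_lte(mean(setdiff(dams$feature_id, truth_ids) %in% called), 0.05)
  # effect is positive in G2 (the target group): spiked features are "up"
  expect_true(all(dams$status[dams$feature_id %in% truth_ids] == "up"))
})

test_that("swapping the groups flips fold changes and labels, not p-values", {
  tg <- make_two_group_table(seed = 29)
  ab <- pairwise_dam(tg$table, "G1", "G2")
  ba <- pairwise_dam(tg$table, "G2", "G1")
  expect_equal(ba$log2FC, -ab$log2FC, tolerance = 1e-10)
  expect_equal(ba$p_value, ab$p_value, tolerance = 1e-10)
  expect_identical(as.character(ba$status)[ab$status == "up"],
                   rep("down", sum(ab$status == "up")))
  # calls are invariant to feature column order
  perm <- sample(ncol(tg$table$intensities))
  shuffled <- feature_table(tg$table$intensities[, perm],
                            tg$table$sample_id, tg$table$group,
                            tg$table$injection_order)
  ab2 <- pairwise_dam(shuffled, "G1", "G2")
  ord <- match(ab$feature_id, ab2$feature_id)
  expect_equal(ab2$log2FC[ord], ab$log2FC, tolerance = 1e-10)
  expect_identical(as.character(ab2$status[ord]), as.character(ab$status))
})

test_that("degenerate features get the conventional p-values", {
  mat <- cbind(const_eq = rep(4, 8), const_ne = rep(c(2, 8), each = 4),
               noise = rnorm(8, 100, 5))
  tab <- table_from_matrix(mat, rep(c("A", "B"), each = 4))
  dams <- pairwise_dam(tab, "A", "B")
  expect_equal(dams$p_value[dams$feature_id == "const_eq"], 1)
  expect_equal(dams$p_value[dams$feature_id == "const_ne"], 0)
  expect_error(pairwise_dam(tab, "A", "missing"),
               class = "invalid_argument")
})

test_that("volcano tables partition records and transform p-values", {
  tg <- make_two_group_table(seed = 31)
  dams <- pairwise_dam(tg$table, "G1", "G2")
  v <- volcano_table(dams)
  counts <- attr(v, "counts")
  expect_equal(sum(counts), nrow(dams))
  expect_equal(v$neg_log10_p, -log10(dams$p_value))
  # p = 1 maps to y = 0
  expect_equal(volcano_table(data.frame(feature_id = "f",
                                        comparison = "A vs B",
                                        log2FC = 0, p_value = 1,
                                        q_value = 1, VIP = 0,
                                        status = factor("ns",
                                          c("up", "down", "ns"))))$neg_log10_p,
               0)
  expect_equal(nrow(volcano_table(dams[0, ])), 0)
})

test_that("upset integration computes disjoint intersection classes", {
  up <- integrate_comparisons(list(first = c("a", "b", "c"),
                                   second = c("b", "c", "d")))
  cls <- setNames(up$intersections$count, up$intersections$class)
  expect_equal(unname(cls["first"]), 1)
  expect_equal(unname(cls["second"]), 1)
  expect_equal(unname(cls["first & second"]), 2)
  # every feature sits in exactly one class
  expect_equal(sum(up$intersections$count), nrow(up$union))
  # identical sets: no exclusive classes
  same <- integrate_comparisons(list(x = c("a", "b"), y = c("a", "b")))
  expect_identical(same$intersections$class, "x & y")
  # prioritization: shared features first
  expect_equal(up$union$n_comparisons[1:2], c(2, 2))
  expect_true(all(up$union$consistent == (up$union$n_comparisons >= 2)))
  expect_error(integrate_comparisons(list(only = "a")),
               class = "invalid_argument")
})

test_that("superclass composition percentages are count-consistent", {
  ann <- structure(list(superclass = c(F1 = "Lipids", F2 = "Lipids",
                                       F3 = "Benzenoids"),
                        pathways = list()),
                   class = "annotation_map")
  comp <- superclass_composition(c("F1", "F2", "F3", "F9"), ann)
  expect_equal(sum(comp$percentage), 100, tolerance = 1e-10)
  expect_equal(comp$percentage[comp$superclass == "Lipids"], 50)
  expect_equal(comp$percentage[comp$superclass == "unclassified"], 25)
  expect_equal(comp$percentage, 100 * comp$count / sum(comp$count),
               tolerance = 0.01)
  # degenerate cases
  expect_equal(nrow(superclass_composition(character(0), ann)), 0)
  one <- superclass_composition(c("F1", "F2"), ann)
  expect_equal(one$percentage, 100)
})
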