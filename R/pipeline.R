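## End-to-end pipeline: simulate -> preprocess -> multivariate models ->
## DAM screening -> enrichment -> flavor -> assays -> cross-block
## correlation. Every stage is a thin call into the module functions, so
## the pipeline is fully determined by the configuration (including the
## seed) and reruns are numerically identical.

#' Default pipeline configuration
#'
#' The defaults emulate the acquisition design of a four-harvest tea
#' study: 4 groups x 3 replicates plus 6 pooled QC injections, log-normal
#' intensities with 10% biological/technical CV, moderate (30%) injection
#' order drift, a spiked differential subset with a 2-unit log2 effect,
#' 40 volatile compounds, and antioxidant potency increasing (IC50
#' decreasing) across harvests. Permutation testing uses 200 label
#' permutations with 7-fold cross-validation.
#'
#' @param seed Integer seed driving every random stage.
#' @return Named list of pipeline parameters.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = fm_check_seed(seed),
    # feature-table simulation
    n_groups = 4, n_reps = 3, n_qc = 6, n_features = 300, n_dam = 30,
    effect_log2 = 2, drift_amplitude = 0.3, noise_cv = 0.1,
    # preprocessing
    span = 0.75, max_rsd = 30,
    # chemometrics
    n_pca_components = 2, n_pls_components = 2, cv_k = 7, n_perm = 200,
    # DAM screening
    vip_threshold = 1, p_threshold = 0.05, min_comparisons = 2,
    # annotation / enrichment
    n_superclasses = 8, n_pathways = 12, q_threshold = 0.05,
    # flavoromics
    n_compounds = 40,
    # antioxidant assays: per-group true IC50s (mg/mL) decrease across
    # harvests; FRAP Fe2+ equivalents increase
    assay_concentrations = c(0.1, 0.25, 0.5, 1, 1.5, 2, 3, 4),
    dpph_ic50 = NULL, abts_ic50 = NULL, assay_noise_sd = 1,
    hill_slope = 2,
    frap_fe2 = NULL,
    frap_calibration = list(slope = 0.9893, intercept = -0.0999,
                            concentrations = seq(0.15, 1.5, length.out = 7)),
    frap_sample_mass = 1, frap_volume = 1
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(
      sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      class = unique(c(setdiff(class(e), c("error", "condition")),
                       "pipeline_stage_error"))))
  })
}

#' Run the full analysis pipeline on simulated data
#'
#' Chains all stages on synthetic data generated under
#' `config$seed` and returns (and optionally writes) every intermediate
#' and final result. Any stage failure aborts with an error naming the
#' stage and cause; results computed before the failure are retained in
#' `out_dir` when one is given.
#'
#' @param config Configuration list, see [default_pipeline_config()].
#' @param out_dir Optional output directory; tables are written as
#'   CSV/TSV, diagnostics as JSON, plus a plain-text run log.
#' @return A `pipeline_report` list with elements `truth`, `preprocess`,
#'   `pca`, `plsda`, `q2`, `permutation`, `dam` (per pair), `upset`,
#'   `superclass`, `enrichment`, `roav`, `key_compounds`, `radar`,
#'   `network`, `assays`, `correlations`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  cfg <- utils::modifyList(default_pipeline_config(config$seed %||% 1), config)
  seed <- fm_check_seed(cfg$seed)
  groups <- sprintf("G%d", seq_len(cfg$n_groups))
  if (is.null(cfg$dpph_ic50)) {
    cfg$dpph_ic50 <- seq(2.0, 0.8, length.out = cfg$n_groups)
  }
  if (is.null(cfg$abts_ic50)) {
    cfg$abts_ic50 <- seq(1.6, 0.6, length.out = cfg$n_groups)
  }
  if (is.null(cfg$frap_fe2)) {
    cfg$frap_fe2 <- seq(0.4, 1.2, length.out = cfg$n_groups)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  report <- list(config = cfg)
  save_csv <- function(obj, file) {
    if (!is.null(out_dir)) {
      utils::write.csv(as.data.frame(obj), file.path(out_dir, file),
                       row.names = FALSE)
    }
  }

  ## 1. simulate -------------------------------------------------------
  sim <- run_stage("simulate", {
    ft <- generate_feature_table(
      n_groups = cfg$n_groups, n_reps = cfg$n_reps, n_qc = cfg$n_qc,
      n_features = cfg$n_features, n_dam = cfg$n_dam,
      effect_log2 = cfg$effect_log2, drift_amplitude = cfg$drift_amplitude,
      noise_cv = cfg$noise_cv, seed = seed)
    odor <- generate_odor_table(cfg$n_compounds, cfg$n_groups,
                                seed = seed + 1L)
    curves <- list()
    for (i in seq_len(cfg$n_groups)) {
      curves[[paste0("DPPH_", groups[i])]] <- generate_assay_curves(
        "DPPH", cfg$dpph_ic50[i], cfg$hill_slope, cfg$assay_concentrations,
        noise_sd = cfg$assay_noise_sd, seed = seed + 100L + i)
      curves[[paste0("ABTS_", groups[i])]] <- generate_assay_curves(
        "ABTS", cfg$abts_ic50[i], cfg$hill_slope, cfg$assay_concentrations,
        noise_sd = cfg$assay_noise_sd, seed = seed + 200L + i)
    }
    list(ft = ft, odor = odor, curves = curves)
  })
  report$truth <- sim$ft$truth
  save_csv(sim$ft$table, "feature_table.csv")
  save_csv(sim$odor$table, "odor_table.csv")

  ## 2. preprocess -----------------------------------------------------
  prep <- run_stage("qc_loess_correct",
                    run_preprocess(sim$ft$table, span = cfg$span,
                                   max_rsd = cfg$max_rsd))
  report$preprocess <- prep
  save_csv(prep$qc_stats, "qc_stats.csv")

  auto_mat <- intensity_matrix(prep$autoscaled)
  labels <- prep$autoscaled$group
  bio <- labels != "QC"
  x_bio <- auto_mat[bio, , drop = FALSE]
  lab_bio <- factor(labels[bio])

  ## 3. chemometrics ---------------------------------------------------
  report$pca <- run_stage("pca",
                          fit_pca(auto_mat,
                                  min(cfg$n_pca_components,
                                      nrow(auto_mat) - 1L)))
  report$plsda <- run_stage("plsda",
                            fit_plsda(x_bio, lab_bio,
                                      cfg$n_pls_components))
  spec <- model_spec("plsda", cfg$n_pls_components)
  report$q2 <- run_stage("cross_validation",
                         cross_validate_q2(x_bio, lab_bio, spec,
                                           k = min(cfg$cv_k, nrow(x_bio)),
                                           seed = seed))
  report$permutation <- run_stage("permutation_test",
                                  permutation_test(x_bio, lab_bio, spec,
                                                   n_perm = cfg$n_perm,
                                                   k = min(cfg$cv_k,
                                                           nrow(x_bio)),
                                                   seed = seed))

  ## 4. DAM screening --------------------------------------------------
  bio_tab <- ft_subset_samples(prep$filtered, !is_qc(prep$filtered))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  dam <- run_stage("dam_screen", {
    out <- lapply(pairs, function(pr) {
      pairwise_dam(bio_tab, pr[1], pr[2],
                   vip_threshold = cfg$vip_threshold,
                   p_threshold = cfg$p_threshold)
    })
    names(out) <- vapply(pairs, paste, character(1), collapse = "_vs_")
    out
  })
  report$dam <- dam
  for (nm in names(dam)) save_csv(dam[[nm]], sprintf("dam_%s.csv", nm))

  report$upset <- run_stage("integrate_comparisons",
                            integrate_comparisons(dam,
                                                  cfg$min_comparisons))

  ## 5. annotation, superclasses, enrichment ---------------------------
  annotation <- run_stage("annotation",
                          generate_annotation(feature_ids(prep$filtered),
                                              cfg$n_superclasses,
                                              cfg$n_pathways,
                                              seed = seed + 2L))
  report$annotation <- annotation
  dam_union <- report$upset$union$feature_id
  report$superclass <- run_stage("superclass_composition",
                                 superclass_composition(dam_union,
                                                        annotation))
  report$enrichment <- run_stage("enrichment",
                                 enrich_pathways(dam_union,
                                                 feature_ids(prep$filtered),
                                                 annotation,
                                                 cfg$q_threshold))
  save_csv(report$superclass, "superclass_composition.csv")
  save_csv(report$enrichment, "enrichment.csv")

  ## 6. flavoromics ----------------------------------------------------
  report$roav <- run_stage("roav", compute_roav(sim$odor$table))
  report$key_compounds <- run_stage("key_compounds",
                                    select_key_compounds(report$roav))
  dmap <- descriptor_map_from_odor_table(sim$odor$table)
  report$radar <- run_stage("descriptor_radar",
                            descriptor_radar(report$key_compounds, dmap))
  report$network <- run_stage("flavor_network",
                              flavor_network(report$key_compounds, dmap))
  save_csv(report$roav, "roav.csv")
  save_csv(report$radar, "descriptor_radar.csv")
  if (!is.null(out_dir)) {
    utils::write.table(report$network$edges,
                       file.path(out_dir, "flavor_network_edges.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  ## 7. antioxidant assays ---------------------------------------------
  report$assays <- run_stage("assays", {
    ic50 <- lapply(sim$curves, estimate_ic50)
    cal_conc <- cfg$frap_calibration$concentrations
    cal_abs <- cfg$frap_calibration$slope * cal_conc +
      cfg$frap_calibration$intercept
    cal <- fit_calibration(cal_conc, cal_abs)
    frap_abs <- cfg$frap_calibration$slope * cfg$frap_fe2 +
      cfg$frap_calibration$intercept
    frap <- frap_value(frap_abs, cal, cfg$frap_sample_mass, cfg$frap_volume)
    list(ic50 = ic50, calibration = cal,
         frap = stats::setNames(frap, groups),
         curves = sim$curves)
  })

  ## 8. cross-block correlation (group-level means) --------------------
  report$correlations <- run_stage("correlation", {
    anti <- data.frame(
      dpph_ic50 = vapply(groups, function(g)
        report$assays$ic50[[paste0("DPPH_", g)]]$ic50, numeric(1)),
      abts_ic50 = vapply(groups, function(g)
        report$assays$ic50[[paste0("ABTS_", g)]]$ic50, numeric(1)),
      frap = unname(report$assays$frap))

    top_feat <- utils::head(report$upset$union$feature_id, 5)
    lmat <- intensity_matrix(prep$log2)
    lgrp <- prep$log2$group
    metab <- as.data.frame(lapply(stats::setNames(top_feat, top_feat),
      function(f) vapply(groups, function(g) mean(lmat[lgrp == g, f]),
                         numeric(1))))

    roav_mean <- tapply(report$roav$roav, report$roav$compound_id, mean)
    top_vc <- names(sort(roav_mean, decreasing = TRUE))[
      seq_len(min(5, length(roav_mean)))]
    flav <- vapply(top_vc, function(vc) {
      vapply(groups, function(g) {
        v <- report$roav$roav[report$roav$compound_id == vc &
                                report$roav$group == g]
        if (length(v)) v[1] else NA_real_
      }, numeric(1))
    }, numeric(length(groups)))
    flav <- as.data.frame(flav)

    blocks <- list(antioxidant = anti, metabolite = metab, flavor = flav)
    list(pearson = correlation_matrix(blocks, "pearson"),
         spearman = correlation_matrix(blocks, "spearman"))
  })
  save_csv(report$correlations$pearson, "correlations_pearson.csv")

  if (!is.null(out_dir)) {
    write_truth_json(report$truth, file.path(out_dir, "truth.json"))
    jsonlite::write_json(
      list(seed = seed,
           package_version = as.character(utils::packageVersion("flavormet")),
           r2y = report$plsda$R2Y, q2 = report$q2,
           permutation_p = report$permutation$p_value,
           n_dam_union = nrow(report$upset$union),
           n_key_compounds = nrow(report$key_compounds)),
      file.path(out_dir, "diagnostics.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_lines <- c(
      sprintf("flavormet %s", utils::packageVersion("flavormet")),
      sprintf("seed: %d", seed),
      sprintf("config: %s",
              jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  features retained: %d of %d\n",
              ncol(x$preprocess$filtered$intensities),
              x$config$n_features))
  cat(sprintf("  PLS-DA R2Y %.3f, Q2 %.3f (perm p(Q2) = %.4g)\n",
              x$plsda$R2Y, x$q2, x$permutation$p_value$Q2))
  cat(sprintf("  DAM union: %d features; key flavor compounds: %d\n",
              nrow(x$upset$union), nrow(x$key_compounds)))
  invisible(x)
}
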