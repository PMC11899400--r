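## Synthetic study generator.
##
## Emulates the acquisition design of a four-harvest untargeted metabolomics
## study: g groups x r biological replicates plus pooled QC injections, with
## log-normal feature abundances, a spiked differential subset with a known
## log2 effect, and smooth multiplicative injection-order drift. The
## recorded ground truth makes every downstream stage testable.

# Canonical chemical superclasses used for toy annotation.
.fm_superclasses <- c(
  "Lipids and lipid-like molecules",
  "Organic acids and derivatives",
  "Benzenoids",
  "Phenylpropanoids and polyketides",
  "Organoheterocyclic compounds",
  "Organic oxygen compounds",
  "Organic nitrogen compounds",
  "Nucleosides, nucleotides, and analogues",
  "Alkaloids and derivatives",
  "Organosulfur compounds",
  "Hydrocarbons"
)

# Sensory descriptor dictionary emulating a flavor-compound database.
.fm_descriptors <- c(
  "sweet", "green", "fruity", "floral", "woody", "herbal", "fresh",
  "waxy", "medicinal", "bitter", "mushroom", "fatty", "citrus",
  "earthy", "almond", "honey"
)

#' Simulate a sample-by-feature intensity table with known ground truth
#'
#' Generates `n_groups * n_reps` biological injections plus `n_qc` pooled-QC
#' injections. Feature abundances are log-normal; `n_dam` randomly chosen
#' features carry an additive `effect_log2` shift (on the log2 scale) in the
#' last group, making every pairwise comparison against that group a spiked
#' contrast with known truth. All rows are multiplied by a smooth per-feature
#' injection-order drift (a linear trend plus one low-frequency sinusoid,
#' amplitude `drift_amplitude`) and log-normal noise with coefficient of
#' variation `noise_cv`. QC rows carry the pooled mean profile of all
#' biological samples, as an equal-volume pooled QC would.
#'
#' QC injections are placed at the start, the end, and evenly through the
#' run, so the drift smoother has support across the whole injection order.
#'
#' @param n_groups,n_reps,n_qc,n_features,n_dam Design counts (all >= 1;
#'   `n_dam <= n_features`).
#' @param effect_log2 True log2 effect of spiked features in the last group.
#' @param drift_amplitude Peak relative amplitude of the multiplicative
#'   drift, in `[0, 0.9]`. 0 disables drift.
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   noise (>= 0).
#' @param seed Mandatory integer seed.
#'
#' @return A list with elements `table` (a [feature_table()]) and `truth`
#'   (class `synthetic_truth`: spiked features and effects, per-feature
#'   drift parameters, the affected group).
#' @export
generate_feature_table <- function(n_groups = 4, n_reps = 3, n_qc = 6,
                                   n_features = 200, n_dam = 20,
                                   effect_log2 = 2, drift_amplitude = 0.3,
                                   noise_cv = 0.1, seed) {
  seed <- fm_check_seed(seed)
  n_groups <- fm_count(n_groups, "n_groups")
  n_reps <- fm_count(n_reps, "n_reps")
  n_qc <- fm_count(n_qc, "n_qc")
  n_features <- fm_count(n_features, "n_features")
  n_dam <- fm_count(n_dam, "n_dam", min = 0L)
  fm_assert(n_dam <= n_features, "'n_dam' must not exceed 'n_features'")
  fm_assert(noise_cv >= 0, "'noise_cv' must be >= 0")
  fm_assert(drift_amplitude >= 0 && drift_amplitude <= 0.9,
            "'drift_amplitude' must lie in [0, 0.9]")

  set.seed(seed)
  n_samples <- n_groups * n_reps
  n_total <- n_samples + n_qc
  groups <- sprintf("G%d", seq_len(n_groups))
  target_group <- groups[n_groups]

  qc_order <- qc_positions(n_total, n_qc)
  sample_order <- sample(setdiff(seq_len(n_total), qc_order))

  feature_id <- sprintf("F%04d", seq_len(n_features))
  mu_log2 <- stats::runif(n_features, 10, 20)
  dam_idx <- if (n_dam > 0) sort(sample.int(n_features, n_dam)) else integer(0)

  # Expected (noiseless, drift-free) intensity per group.
  group_log2 <- matrix(rep(mu_log2, each = n_groups), nrow = n_groups,
                       dimnames = list(groups, feature_id))
  group_log2[target_group, dam_idx] <- group_log2[target_group, dam_idx] +
    effect_log2
  group_expect <- 2^group_log2
  pooled <- colMeans(group_expect[rep(seq_len(n_groups), each = n_reps), ,
                                  drop = FALSE])

  # Per-feature smooth multiplicative drift: linear + one sinusoid.
  drift <- data.frame(
    feature_id = feature_id,
    amplitude = drift_amplitude * stats::runif(n_features, 0.5, 1),
    frequency = stats::runif(n_features, 0.5, 1.5),
    phase = stats::runif(n_features, 0, 2 * pi),
    linear_weight = 0.6, sine_weight = 0.4,
    stringsAsFactors = FALSE
  )
  drift_factor <- function(order) {
    # rows = features, one column per requested order
    lin <- (order - 1) / max(n_total - 1, 1) * 2 - 1
    vapply(seq_along(order), function(i) {
      f <- 1 + drift$amplitude * (drift$linear_weight * lin[i] +
             drift$sine_weight *
               sin(2 * pi * drift$frequency * order[i] / n_total + drift$phase))
      pmax(f, 0.05)
    }, numeric(n_features))
  }

  sdlog <- sqrt(log1p(noise_cv^2))
  noise <- function(n_rows) {
    if (sdlog == 0) return(matrix(1, n_rows, n_features))
    matrix(exp(stats::rnorm(n_rows * n_features, -sdlog^2 / 2, sdlog)),
           n_rows, n_features)
  }

  grp <- rep(groups, each = n_reps)
  sample_expect <- group_expect[grp, , drop = FALSE]
  sample_mat <- sample_expect * t(drift_factor(sample_order)) * noise(n_samples)
  qc_mat <- matrix(pooled, n_qc, n_features, byrow = TRUE) *
    t(drift_factor(qc_order)) * noise(n_qc)

  mat <- rbind(sample_mat, qc_mat)
  colnames(mat) <- feature_id
  ids <- c(sprintf("%s_r%d", grp, rep(seq_len(n_reps), n_groups)),
           sprintf("QC_%d", seq_len(n_qc)))

  tab <- feature_table(mat, ids, c(grp, rep("QC", n_qc)),
                       c(sample_order, qc_order))
  truth <- structure(
    list(dam_features = data.frame(feature_id = feature_id[dam_idx],
                                   effect_log2 = rep(effect_log2,
                                                     length(dam_idx)),
                                   group = rep(target_group, length(dam_idx)),
                                   stringsAsFactors = FALSE),
         drift_model = drift,
         target_group = target_group,
         reference_groups = setdiff(groups, target_group),
         mu_log2 = stats::setNames(mu_log2, feature_id),
         design = list(n_groups = n_groups, n_reps = n_reps, n_qc = n_qc,
                       noise_cv = noise_cv, drift_amplitude = drift_amplitude,
                       seed = seed)),
    class = "synthetic_truth")
  list(table = tab, truth = truth)
}

## Start/end anchored, evenly interleaved QC positions within 1..n_total.
qc_positions <- function(n_total, n_qc) {
  fm_assert(n_qc <= n_total, "more QC injections than run positions")
  if (n_qc == 1) return(1L)
  pos <- unique(round(seq(1, n_total, length.out = n_qc)))
  free <- setdiff(seq_len(n_total), pos)
  while (length(pos) < n_qc) {  # collisions only when n_qc ~ n_total
    pos <- sort(c(pos, free[1]))
    free <- free[-1]
  }
  as.integer(sort(pos))
}

#' Simulate a volatile-compound odor table
#'
#' Each compound gets a positive odor threshold, log-normal peak areas per
#' group, and 1–4 sensory descriptors drawn from a bundled descriptor
#' dictionary (descriptors are a compound property and shared across
#' groups). The true odor-activity (Peak/T) ranking per group is recorded.
#'
#' @param n_compounds,n_groups Design counts (>= 1).
#' @param seed Mandatory integer seed.
#' @return List with `table` (class `odor_table`, columns `compound_id`,
#'   `group`, `peak_area`, `odor_threshold`, `descriptors`) and `truth`
#'   (recorded per-group OAV ranking).
#' @export
generate_odor_table <- function(n_compounds = 40, n_groups = 4, seed) {
  seed <- fm_check_seed(seed)
  n_compounds <- fm_count(n_compounds, "n_compounds")
  n_groups <- fm_count(n_groups, "n_groups")
  set.seed(seed)

  compound_id <- sprintf("VC%03d", seq_len(n_compounds))
  groups <- sprintf("G%d", seq_len(n_groups))
  threshold <- 10^stats::runif(n_compounds, -2, 1)
  base_area <- 10^stats::runif(n_compounds, 4, 7)
  descr <- vapply(seq_len(n_compounds), function(i) {
    paste(sample(.fm_descriptors, sample.int(4, 1)), collapse = ";")
  }, character(1))

  tab <- do.call(rbind, lapply(groups, function(g) {
    data.frame(compound_id = compound_id, group = g,
               peak_area = base_area * exp(stats::rnorm(n_compounds, 0, 0.5)),
               odor_threshold = threshold, descriptors = descr,
               stringsAsFactors = FALSE)
  }))
  class(tab) <- c("odor_table", "data.frame")

  ranking <- lapply(stats::setNames(groups, groups), function(g) {
    sub <- tab[tab$group == g, ]
    sub$compound_id[order(sub$peak_area / sub$odor_threshold,
                          decreasing = TRUE)]
  })
  truth <- structure(list(oav_ranking = ranking,
                          design = list(seed = seed)),
                     class = "synthetic_truth")
  list(table = tab, truth = truth)
}

#' Simulate an antioxidant dose-response curve
#'
#' Scavenging follows a four-parameter-logistic shape rising from 0 to 100%
#' with its 50% point at `true_ic50`; Gaussian noise is added and the result
#' clipped to `[0, 100]`. Absorbances consistent with the scavenging
#' formula (control absorbance 1.0) are emitted so the assay module can
#' recompute scavenging from raw readings.
#'
#' @param assay Assay label (e.g. `"DPPH"` or `"ABTS"`).
#' @param true_ic50 True 50% scavenging concentration (mg/mL); must lie
#'   within the span of `concentrations`.
#' @param hill_slope Hill slope of the logistic (> 0).
#' @param concentrations Strictly increasing positive concentrations (mg/mL).
#' @param noise_sd Gaussian noise standard deviation on the percent scale.
#' @param seed Mandatory integer seed.
#' @return An `assay_curve` data.frame (`assay`, `concentration`,
#'   `a_sample`, `a_0`, `scavenging`) with the truth in
#'   `attr(, "true_ic50")`.
#' @export
generate_assay_curves <- function(assay, true_ic50, hill_slope = 2,
                                  concentrations, noise_sd = 0, seed) {
  seed <- fm_check_seed(seed)
  fm_assert(is.numeric(concentrations) && length(concentrations) >= 2 &&
              all(concentrations > 0) && all(diff(concentrations) > 0),
            "'concentrations' must be positive and strictly increasing")
  fm_assert(is.numeric(true_ic50) && length(true_ic50) == 1 && true_ic50 > 0,
            "'true_ic50' must be a single positive concentration")
  fm_assert(true_ic50 >= min(concentrations) &&
              true_ic50 <= max(concentrations),
            "'true_ic50' must lie within the concentration span")
  fm_assert(hill_slope > 0, "'hill_slope' must be > 0")
  fm_assert(noise_sd >= 0, "'noise_sd' must be >= 0")
  set.seed(seed)

  scav <- 100 / (1 + (true_ic50 / concentrations)^hill_slope)
  if (noise_sd > 0) scav <- scav + stats::rnorm(length(scav), 0, noise_sd)
  scav <- pmin(pmax(scav, 0), 100)
  a0 <- 1
  curve <- data.frame(assay = assay, concentration = concentrations,
                      a_sample = a0 * (1 - scav / 100), a_0 = a0,
                      scavenging = scav, stringsAsFactors = FALSE)
  class(curve) <- c("assay_curve", "data.frame")
  attr(curve, "true_ic50") <- true_ic50
  attr(curve, "hill_slope") <- hill_slope
  curve
}

#' Simulate feature annotation: superclasses and overlapping pathways
#'
#' Every feature is assigned exactly one chemical superclass (from a
#' bundled taxonomy); pathways are overlapping random subsets of features,
#' emulating a pathway-membership map.
#'
#' @param feature_ids Non-empty character vector of feature ids.
#' @param n_superclasses Number of superclasses to draw from (>= 1).
#' @param n_pathways Number of pathways (>= 0; 0 gives an empty map).
#' @param seed Mandatory integer seed.
#' @return An `annotation_map`: list with `superclass` (named character
#'   vector, one entry per feature) and `pathways` (named list of feature id
#'   vectors, each of size >= 1).
#' @export
generate_annotation <- function(feature_ids, n_superclasses = 8,
                                n_pathways = 12, seed) {
  seed <- fm_check_seed(seed)
  fm_assert(length(feature_ids) >= 1, "'feature_ids' must be non-empty")
  n_superclasses <- fm_count(n_superclasses, "n_superclasses")
  n_pathways <- fm_count(n_pathways, "n_pathways", min = 0L)
  set.seed(seed)

  classes <- if (n_superclasses <= length(.fm_superclasses)) {
    .fm_superclasses[seq_len(n_superclasses)]
  } else {
    c(.fm_superclasses,
      sprintf("Superclass %d",
              seq_len(n_superclasses - length(.fm_superclasses))))
  }
  weights <- stats::rgamma(n_superclasses, shape = 2)
  superclass <- stats::setNames(
    sample(classes, length(feature_ids), replace = TRUE,
           prob = weights / sum(weights)),
    feature_ids)

  nf <- length(feature_ids)
  pathways <- stats::setNames(lapply(seq_len(n_pathways), function(i) {
    size <- sample.int(max(1L, min(nf, max(3L, ceiling(nf / 5)))), 1)
    size <- max(size, 1L)
    sort(sample(feature_ids, size))
  }), if (n_pathways > 0) sprintf("path%02d", seq_len(n_pathways)) else NULL)
  if (n_pathways == 0) pathways <- stats::setNames(list(), character(0))

  structure(list(superclass = superclass, pathways = pathways),
            class = "annotation_map")
}

#' Write synthetic ground truth as JSON
#' @param truth A `synthetic_truth` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
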