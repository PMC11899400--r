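## Two-step differential-metabolite (DAM) screening: per-pair OPLS-DA VIP
## plus per-feature t-tests on log2 intensities, then cross-comparison
## integration with upset-style disjoint intersection counts.

#' Pairwise differential-metabolite screening
#'
#' For one pair of groups: fits an OPLS-DA model on the autoscaled log2
#' intensities to obtain VIP scores, runs a two-sided t-test per feature on
#' the log2 intensities, and computes the fold change on the raw (pre-log)
#' group means. A feature is called `up` (higher in `group_b`) or `down`
#' when `VIP > vip_threshold` and `p < p_threshold`; otherwise `ns`.
#' Benjamini-Hochberg q-values are reported alongside but do not enter the
#' default call, mirroring the conventional raw-p criterion.
#'
#' @param table A raw-scale [feature_table()] (drift-corrected/filtered).
#' @param group_a,group_b Group labels present in `table` with >= 2
#'   replicates each. Fold changes and `up`/`down` are oriented as
#'   `group_b` over `group_a`.
#' @param vip_threshold,p_threshold Screening thresholds (defaults 1 and
#'   0.05).
#' @param n_orthogonal Orthogonal components for the OPLS-DA VIP model.
#' @param var_equal Use the pooled-variance Student t-test (default) or
#'   Welch (`FALSE`).
#' @return A `dam_table` data.frame: `feature_id`, `comparison`, `log2FC`,
#'   `p_value`, `q_value`, `VIP`, `status` (`up`/`down`/`ns`).
#' @export
pairwise_dam <- function(table, group_a, group_b, vip_threshold = 1,
                         p_threshold = 0.05, n_orthogonal = 0,
                         var_equal = TRUE) {
  fm_assert(inherits(table, "feature_table"), "'table' must be a feature_table")
  for (g in c(group_a, group_b)) {
    if (sum(table$group == g) < 2) {
      fm_stop(sprintf("group '%s' must be present with >= 2 replicates", g),
              "invalid_argument")
    }
  }
  rows <- table$group %in% c(group_a, group_b)
  sub <- ft_subset_samples(table, rows)
  labels <- factor(sub$group, levels = c(group_a, group_b))

  raw <- intensity_matrix(sub)
  log2_tab <- impute_and_log2(sub)
  lmat <- intensity_matrix(log2_tab)
  kept <- colnames(lmat)
  raw <- raw[, kept, drop = FALSE]

  a <- labels == group_a
  b <- labels == group_b
  log2fc <- log2(colMeans(raw[b, , drop = FALSE]) /
                   colMeans(raw[a, , drop = FALSE]))
  pvals <- two_sample_t(lmat[a, , drop = FALSE], lmat[b, , drop = FALSE],
                        var_equal = var_equal)

  # VIP from the pairwise OPLS-DA on autoscaled log2 data; constant
  # features carry no discriminant weight and get VIP 0.
  auto <- suppressWarnings(autoscale(log2_tab))
  amat <- intensity_matrix(auto)
  vip <- stats::setNames(numeric(length(kept)), kept)
  if (ncol(amat) >= 1) {
    # degenerate case (groups carry no discriminable signal): VIP stays 0
    fit <- tryCatch(fit_oplsda(amat, labels, n_orthogonal = n_orthogonal),
                    flavormet_error = function(e) NULL)
    if (!is.null(fit)) vip[colnames(amat)] <- fit$vip
  }

  sig <- vip > vip_threshold & pvals < p_threshold
  status <- rep("ns", length(kept))
  status[sig & log2fc > 0] <- "up"
  status[sig & log2fc < 0] <- "down"

  out <- data.frame(feature_id = kept,
                    comparison = paste(group_a, "vs", group_b),
                    log2FC = unname(log2fc), p_value = unname(pvals),
                    q_value = stats::p.adjust(unname(pvals), method = "BH"),
                    VIP = unname(vip),
                    status = factor(status, levels = c("up", "down", "ns")),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("dam_table", "data.frame")
  out
}

## Vectorized two-sample t-test on columns. Degenerate features (zero
## variance in both groups) get p = 1 when the means are equal, p = 0
## otherwise.
two_sample_t <- function(xa, xb, var_equal = TRUE) {
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- apply(xa, 2, stats::var); vb <- apply(xb, 2, stats::var)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (mb - ma) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  zero <- !is.finite(tstat)
  p[zero] <- ifelse(abs(mb[zero] - ma[zero]) < .Machine$double.eps^0.5, 1, 0)
  p
}

#' Volcano-plot table for one comparison
#'
#' @param records A `dam_table` from a single comparison.
#' @return Data.frame with `feature_id`, `log2FC`, `neg_log10_p`, `status`;
#'   per-status counts in `attr(, "counts")`.
#' @export
volcano_table <- function(records) {
  if (NROW(records) == 0) {
    out <- data.frame(feature_id = character(0), log2FC = numeric(0),
                      neg_log10_p = numeric(0),
                      status = factor(character(0),
                                      levels = c("up", "down", "ns")))
    attr(out, "counts") <- c(up = 0L, down = 0L, ns = 0L)
    return(out)
  }
  fm_assert(length(unique(records$comparison)) == 1,
            "volcano_table expects records from a single comparison")
  out <- data.frame(feature_id = records$feature_id,
                    log2FC = records$log2FC,
                    neg_log10_p = -log10(records$p_value),
                    status = records$status,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "counts") <- table(records$status)
  out
}

#' Integrate DAM calls across comparisons (upset semantics)
#'
#' Computes exact disjoint intersection-class counts over the comparisons'
#' DAM sets (each feature is counted in exactly the class of comparisons
#' that flagged it) and a prioritized union: features sorted by the number
#' of comparisons in which they are differential.
#'
#' @param dam_sets Named list (>= 2 entries) of either `dam_table`s (the
#'   `up`/`down` rows are taken) or character vectors of feature ids.
#' @param min_comparisons Minimum number of comparisons for a feature to
#'   count as consistently altered (default 2).
#' @return An `upset_summary`: `intersections` (data.frame `class`,
#'   `count`; classes are `&`-joined comparison names) and `union`
#'   (data.frame `feature_id`, `n_comparisons`, `comparisons`,
#'   `consistent`, sorted by descending `n_comparisons`).
#' @export
integrate_comparisons <- function(dam_sets, min_comparisons = 2) {
  fm_assert(is.list(dam_sets) && length(dam_sets) >= 2,
            "'dam_sets' must be a named list of >= 2 comparisons")
  if (is.null(names(dam_sets)) || any(!nzchar(names(dam_sets)))) {
    names(dam_sets) <- sprintf("comparison%d", seq_along(dam_sets))
  }
  sets <- lapply(dam_sets, function(s) {
    if (inherits(s, "data.frame")) {
      unique(s$feature_id[s$status %in% c("up", "down")])
    } else unique(as.character(s))
  })
  features <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) features %in% s,
                   logical(length(features)))
  member <- matrix(member, nrow = length(features),
                   dimnames = list(features, names(sets)))

  cls <- apply(member, 1, function(m) paste(colnames(member)[m],
                                            collapse = " & "))
  counts <- if (length(cls)) table(cls) else table(character(0))
  intersections <- data.frame(class = names(counts),
                              count = as.integer(counts),
                              row.names = NULL, stringsAsFactors = FALSE)
  intersections <- intersections[order(-intersections$count,
                                       intersections$class), , drop = FALSE]

  n_comp <- rowSums(member)
  union <- data.frame(
    feature_id = features,
    n_comparisons = as.integer(n_comp),
    comparisons = vapply(seq_along(features), function(i)
      paste(colnames(member)[member[i, ]], collapse = ";"), character(1)),
    consistent = n_comp >= min_comparisons,
    row.names = NULL, stringsAsFactors = FALSE)
  union <- union[order(-union$n_comparisons, union$feature_id), , drop = FALSE]
  rownames(union) <- rownames(intersections) <- NULL
  structure(list(intersections = intersections, union = union,
                 comparisons = names(sets)),
            class = "upset_summary")
}

#' @export
print.upset_summary <- function(x, ...) {
  cat(sprintf("<upset_summary> %d comparisons, %d features in union\n",
              length(x$comparisons), nrow(x$union)))
  print(utils::head(x$intersections, 10))
  invisible(x)
}

#' Superclass composition of a DAM set
#'
#' @param dam_union Character vector of DAM feature ids (or an
#'   `upset_summary`, whose union is taken).
#' @param annotation An `annotation_map` (see [generate_annotation()]) or a
#'   named character vector feature -> superclass. Unannotated features are
#'   bucketed as `"unclassified"`.
#' @return Data.frame `superclass`, `count`, `percentage` sorted by
#'   descending percentage; percentages sum to 100.
#' @export
superclass_composition <- function(dam_union, annotation) {
  if (inherits(dam_union, "upset_summary")) {
    dam_union <- dam_union$union$feature_id
  }
  if (length(dam_union) == 0) {
    return(data.frame(superclass = character(0), count = integer(0),
                      percentage = numeric(0)))
  }
  sc_map <- if (inherits(annotation, "annotation_map")) {
    annotation$superclass
  } else annotation
  sc <- sc_map[dam_union]
  sc[is.na(sc)] <- "unclassified"
  counts <- sort(table(sc), decreasing = TRUE)
  data.frame(superclass = names(counts), count = as.integer(counts),
             percentage = 100 * as.integer(counts) / length(dam_union),
             row.names = NULL, stringsAsFactors = FALSE)
}
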