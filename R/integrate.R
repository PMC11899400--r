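## Cross-block integration: correlation of antioxidant, flavor and
## metabolite variables over shared observations, and deterministic
## hierarchical clustering for heatmap rendering.

#' Cross-block correlation table
#'
#' Computes pairwise correlations (with two-sided p-values) between the
#' variables of named blocks measured on the same observations —
#' typically group-level means, so antioxidant endpoints (one value per
#' group) can be correlated with metabolite and flavor variables.
#' Constant variables are excluded with a warning; pairs with fewer than
#' 3 complete observations are skipped.
#'
#' @param blocks Named list of data.frames/matrices with identical row
#'   order (shared observations) — e.g.
#'   `list(antioxidant = ..., metabolite = ...)`.
#' @param method `"pearson"` or `"spearman"`.
#' @param within_blocks Also emit pairs within the same block
#'   (default `FALSE`: between-block pairs only).
#' @return A `correlation_table` data.frame (one row per unordered pair):
#'   `variable_a`, `block_a`, `variable_b`, `block_b`, `r`, `p_value`,
#'   `method`, `n`.
#' @export
correlation_matrix <- function(blocks, method = c("pearson", "spearman"),
                               within_blocks = FALSE) {
  method <- match.arg(method)
  fm_assert(is.list(blocks) && length(blocks) >= 1 &&
              !is.null(names(blocks)),
            "'blocks' must be a named list of data.frames")
  mats <- lapply(blocks, function(b) as.matrix(as.data.frame(b)))
  n_obs <- unique(vapply(mats, nrow, integer(1)))
  fm_assert(length(n_obs) == 1, "all blocks must share the same observations")
  fm_assert(n_obs >= 3, "correlations need >= 3 shared observations")

  combined <- do.call(cbind, mats)
  block_of <- rep(names(blocks), vapply(mats, ncol, integer(1)))
  vars <- colnames(combined)
  fm_assert(!anyDuplicated(vars), "variable names must be unique across blocks")

  keep <- apply(combined, 2, function(v) stats::sd(v, na.rm = TRUE) > 0)
  if (any(!keep)) {
    warning(sprintf("correlation_matrix: excluded %d constant variable(s): %s",
                    sum(!keep), paste(vars[!keep], collapse = ", ")))
  }
  combined <- combined[, keep, drop = FALSE]
  block_of <- block_of[keep]
  vars <- vars[keep]

  rows <- list()
  for (i in seq_along(vars)) {
    for (j in seq_along(vars)) {
      if (j <= i) next
      if (!within_blocks && block_of[i] == block_of[j]) next
      ok <- stats::complete.cases(combined[, c(i, j)])
      if (sum(ok) < 3) {
        warning(sprintf("correlation_matrix: skipped %s ~ %s (< 3 observations)",
                        vars[i], vars[j]))
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(combined[ok, i], combined[ok, j],
                        method = method, exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        variable_a = vars[i], block_a = block_of[i],
        variable_b = vars[j], block_b = block_of[j],
        r = unname(ct$estimate), p_value = ct$p.value,
        method = method, n = sum(ok), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable_a = character(0), block_a = character(0),
               variable_b = character(0), block_b = character(0),
               r = numeric(0), p_value = numeric(0),
               method = character(0), n = integer(0))
  rownames(out) <- NULL
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Hierarchical clustering orderings for a heatmap
#'
#' Deterministic agglomerative clustering of rows and columns; returns the
#' leaf orderings and merge heights needed to render a clustered heatmap.
#'
#' @param matrix Numeric matrix (e.g. autoscaled DAM intensities), >= 1
#'   row.
#' @param linkage `"ward"` (Ward.D2) or `"average"`.
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @return A `cluster_heatmap` list: `row_order`, `col_order`,
#'   `row_heights`, `col_heights`, and the underlying `hclust` objects
#'   (`NULL` for single-row/column inputs).
#' @export
cluster_heatmap <- function(matrix, linkage = c("ward", "average"),
                            distance = c("euclidean", "correlation")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  matrix <- as.matrix(matrix)
  fm_assert(nrow(matrix) >= 1, "'matrix' must have >= 1 row")
  hc_method <- if (linkage == "ward") "ward.D2" else "average"
  dist_fun <- function(m) {
    if (distance == "euclidean") stats::dist(m)
    else stats::as.dist(1 - stats::cor(t(m)))
  }
  cluster_axis <- function(m) {
    if (nrow(m) < 2) {
      return(list(order = seq_len(nrow(m)), heights = numeric(0),
                  hclust = NULL))
    }
    hc <- stats::hclust(dist_fun(m), method = hc_method)
    list(order = hc$order, heights = hc$height, hclust = hc)
  }
  rows <- cluster_axis(matrix)
  cols <- cluster_axis(t(matrix))
  structure(list(row_order = rows$order, col_order = cols$order,
                 row_heights = rows$heights, col_heights = cols$heights,
                 row_hclust = rows$hclust, col_hclust = cols$hclust),
            class = "cluster_heatmap")
}
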