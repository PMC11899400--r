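#' Sample-by-feature intensity table with acquisition metadata
#'
#' The central container of the pipeline: a numeric matrix of peak
#' intensities (rows = injections, columns = features) together with the
#' per-injection metadata that drift correction needs — group label (pooled
#' quality-control injections carry the reserved label `"QC"`) and injection
#' order.
#'
#' @param intensities Numeric matrix, samples in rows, features in columns.
#'   Column names are feature ids (generated when absent).
#' @param sample_id Character vector of unique sample identifiers.
#' @param group Character vector of group labels; pooled QC injections must
#'   be labelled `"QC"`.
#' @param injection_order Integer vector of unique, positive acquisition
#'   positions.
#' @param feature_meta Optional `data.frame` of per-feature annotation with
#'   a `feature_id` column.
#' @param scale Intensity scale: `"raw"` values must be non-negative;
#'   `"log2"` and `"autoscaled"` tables may hold negative values.
#'
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(intensities, sample_id, group, injection_order,
                          feature_meta = NULL, scale = "raw") {
  fm_assert(is.matrix(intensities) && is.numeric(intensities),
            "'intensities' must be a numeric matrix")
  n <- nrow(intensities)
  fm_assert(length(sample_id) == n && length(group) == n &&
              length(injection_order) == n,
            "metadata vectors must match nrow(intensities)")
  fm_assert(!anyDuplicated(sample_id), "sample ids must be unique")
  fm_assert(!anyDuplicated(injection_order), "injection orders must be unique")
  fm_assert(all(injection_order >= 1 & injection_order == floor(injection_order)),
            "injection orders must be positive integers")
  scale <- match.arg(scale, c("raw", "log2", "autoscaled"))
  if (scale == "raw") {
    fm_assert(all(is.na(intensities) | intensities >= 0),
              "raw intensities must be non-negative", "invalid_input")
  }
  if (is.null(colnames(intensities))) {
    colnames(intensities) <- sprintf("F%04d", seq_len(ncol(intensities)))
  }
  rownames(intensities) <- as.character(sample_id)
  if (!is.null(feature_meta)) {
    fm_assert(is.data.frame(feature_meta) && "feature_id" %in% names(feature_meta),
              "'feature_meta' must be a data.frame with a feature_id column")
  }
  structure(
    list(intensities = intensities,
         sample_id = as.character(sample_id),
         group = as.character(group),
         injection_order = as.integer(injection_order),
         feature_meta = feature_meta,
         scale = scale),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d injections x %d features (%s scale)\n",
              nrow(x$intensities), ncol(x$intensities), x$scale))
  tab <- table(x$group)
  cat("  groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Extract the intensity matrix of a feature table
#' @param table A [feature_table()].
#' @return Numeric matrix (samples x features).
#' @export
intensity_matrix <- function(table) {
  fm_assert(inherits(table, "feature_table"), "'table' must be a feature_table")
  table$intensities
}

#' Feature identifiers of a feature table
#' @param table A [feature_table()].
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(table) colnames(intensity_matrix(table))

is_qc <- function(table) table$group == "QC"

## Internal rebuilders that preserve metadata.
ft_set_intensities <- function(table, mat, scale = table$scale) {
  feature_table(mat, table$sample_id, table$group, table$injection_order,
                feature_meta = ft_subset_meta(table, colnames(mat)),
                scale = scale)
}

ft_subset_meta <- function(table, keep_ids) {
  fm <- table$feature_meta
  if (is.null(fm)) return(NULL)
  fm[match(keep_ids, fm$feature_id), , drop = FALSE]
}

ft_keep_features <- function(table, keep) {
  ft_set_intensities(table, table$intensities[, keep, drop = FALSE])
}

ft_subset_samples <- function(table, rows) {
  feature_table(table$intensities[rows, , drop = FALSE],
                table$sample_id[rows], table$group[rows],
                table$injection_order[rows],
                feature_meta = table$feature_meta, scale = table$scale)
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  cbind(data.frame(sample_id = x$sample_id, group = x$group,
                   injection_order = x$injection_order,
                   stringsAsFactors = FALSE),
        as.data.frame(x$intensities))
}

#' Read / write feature tables as CSV
#'
#' The on-disk layout is one row per injection with leading columns
#' `sample_id`, `group`, `injection_order` followed by one column per
#' feature; QC injections are identified by `group == "QC"`.
#'
#' @param table A [feature_table()].
#' @param path File path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns a [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param scale Intensity scale of the stored table (see [feature_table()]).
#' @export
read_feature_table <- function(path, scale = "raw") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  fm_assert(all(c("sample_id", "group", "injection_order") %in% names(df)),
            "feature table CSV must have sample_id, group, injection_order columns",
            "invalid_input")
  meta_cols <- c("sample_id", "group", "injection_order")
  mat <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  storage.mode(mat) <- "double"
  feature_table(mat, df$sample_id, df$group, df$injection_order, scale = scale)
}
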