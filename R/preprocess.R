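## Preprocessing chain: pooled-QC LOESS drift correction -> QC-RSD filter ->
## (optional) internal-standard normalization -> half-minimum imputation +
## log2 -> autoscaling. Each stage takes and returns a feature_table so the
## chain order stays configurable.

#' Pooled-QC LOESS injection-order drift correction (QC-RLSC)
#'
#' For every feature, a locally weighted linear regression (tricube weights,
#' degree 1) of the QC intensities on injection order estimates the
#' instrument drift curve. Every injection's intensity is multiplied by
#' `median(fitted at QC orders) / fitted(drift at its own order)`, which
#' removes the drift while preserving the median QC level of the feature.
#' Predictions beyond the outermost QC injections are clamped to the
#' nearest QC order (no extrapolation).
#'
#' Features whose fitted drift is non-positive anywhere (or whose smoother
#' fails) fall back to no correction and are flagged in the returned
#' statistics.
#'
#' @param table A raw-scale [feature_table()] with at least 4 QC rows.
#' @param span LOESS span in `(0, 1]`; 0.75 is the QC-RLSC convention.
#' @return List with `table` (corrected [feature_table()]) and `qc_stats`
#'   (data.frame: `feature_id`, `rsd_before`, `rsd_after` — QC RSD in
#'   percent — and `fallback`).
#' @export
qc_loess_correct <- function(table, span = 0.75) {
  fm_assert(inherits(table, "feature_table"), "'table' must be a feature_table")
  fm_assert(span > 0 && span <= 1, "'span' must lie in (0, 1]")
  qc <- is_qc(table)
  if (sum(qc) < 4) {
    fm_stop(sprintf("drift correction needs >= 4 QC injections, found %d",
                    sum(qc)), "insufficient_qc")
  }
  mat <- intensity_matrix(table)
  order_all <- table$injection_order
  order_qc <- order_all[qc]
  # clamped evaluation grid: nearest-QC extrapolation
  order_eval <- pmin(pmax(order_all, min(order_qc)), max(order_qc))

  corrected <- mat
  fallback <- logical(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    yqc <- mat[qc, j]
    # loess emits numerical notices (pseudoinverse etc.) on small QC sets;
    # genuine failures surface as errors or invalid predictions below
    fit <- tryCatch(
      suppressWarnings(
        stats::loess(yqc ~ order_qc, span = span, degree = 1,
                     family = "gaussian",
                     control = stats::loess.control(surface = "direct"))),
      error = function(e) NULL)
    pred <- if (is.null(fit)) NULL else
      tryCatch(suppressWarnings(
        stats::predict(fit, data.frame(order_qc = order_eval))),
        error = function(e) NULL)
    if (is.null(pred) || anyNA(pred) || any(pred <= 0)) {
      fallback[j] <- TRUE
      next  # leave the feature uncorrected (global median anchor unchanged)
    }
    ref <- stats::median(pred[qc])
    corrected[, j] <- mat[, j] * ref / pred
  }
  if (any(fallback)) {
    message(sprintf("qc_loess_correct: %d feature(s) fell back to no correction (non-positive or failed drift fit)",
                    sum(fallback)))
  }
  out <- ft_set_intensities(table, corrected)
  qc_stats <- data.frame(
    feature_id = colnames(mat),
    rsd_before = apply(mat[qc, , drop = FALSE], 2, rsd_percent),
    rsd_after = apply(corrected[qc, , drop = FALSE], 2, rsd_percent),
    fallback = fallback,
    row.names = NULL, stringsAsFactors = FALSE)
  list(table = out, qc_stats = qc_stats)
}

#' Filter features by QC relative standard deviation
#'
#' Removes features whose QC-sample RSD (sample standard deviation / mean
#' x 100) exceeds `max_rsd` percent. Features whose QC mean is not positive
#' cannot be assessed and are removed as well.
#'
#' @param table A raw-scale [feature_table()] containing QC rows.
#' @param max_rsd Maximum tolerated QC RSD in percent (default 30).
#' @return Filtered [feature_table()]; the number of removed features is
#'   reported via `message()` and stored in `attr(, "n_removed")`.
#' @export
rsd_filter <- function(table, max_rsd = 30) {
  fm_assert(inherits(table, "feature_table"), "'table' must be a feature_table")
  qc <- is_qc(table)
  if (!any(qc)) fm_stop("RSD filtering requires QC rows", "invalid_input")
  rsd <- apply(intensity_matrix(table)[qc, , drop = FALSE], 2, rsd_percent)
  keep <- !is.na(rsd) & rsd <= max_rsd
  message(sprintf("rsd_filter: removed %d of %d features (QC RSD > %g%%)",
                  sum(!keep), length(keep), max_rsd))
  out <- ft_keep_features(table, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Internal-standard relative quantification
#'
#' Converts intensities to relative amounts: each intensity is divided by
#' the internal-standard intensity of its sample and multiplied by the
#' known internal-standard amount. The internal-standard feature itself is
#' removed from the output.
#'
#' @param table A raw-scale [feature_table()].
#' @param is_feature Feature id of the internal standard; must be positive
#'   in every sample.
#' @param is_concentration Known amount of the internal standard (default 1,
#'   i.e. pure ratio).
#' @return Normalized [feature_table()] without the internal standard.
#' @export
internal_standard_normalize <- function(table, is_feature,
                                        is_concentration = 1) {
  fm_assert(inherits(table, "feature_table"), "'table' must be a feature_table")
  mat <- intensity_matrix(table)
  fm_assert(is_feature %in% colnames(mat),
            sprintf("internal standard '%s' not found", is_feature))
  is_vals <- mat[, is_feature]
  bad <- which(!is.finite(is_vals) | is_vals <= 0)
  if (length(bad)) {
    fm_stop(sprintf("internal standard '%s' is not positive in sample(s): %s",
                    is_feature,
                    paste(table$sample_id[bad], collapse = ", ")),
            "invalid_input")
  }
  out <- mat[, setdiff(colnames(mat), is_feature), drop = FALSE] /
    is_vals * is_concentration
  ft_set_intensities(table, out)
}

#' Half-minimum imputation and log2 transformation
#'
#' Zeros and missing values of each feature are replaced by half the
#' smallest positive value observed for that feature; all values are then
#' log2-transformed. Features with no positive value at all are dropped
#' with a warning. The output contains no non-finite values.
#'
#' @param table A raw-scale [feature_table()].
#' @return A log2-scale [feature_table()].
#' @export
impute_and_log2 <- function(table) {
  fm_assert(inherits(table, "feature_table"), "'table' must be a feature_table")
  mat <- intensity_matrix(table)
  fm_assert(ncol(mat) >= 1 && nrow(mat) >= 1, "'table' must be non-empty")
  all_zero <- apply(mat, 2, function(v) !any(is.finite(v) & v > 0))
  if (any(all_zero)) {
    warning(sprintf("impute_and_log2: dropped %d feature(s) with no positive values",
                    sum(all_zero)))
    mat <- mat[, !all_zero, drop = FALSE]
  }
  out <- apply(mat, 2, function(v) {
    half_min <- min(v[is.finite(v) & v > 0]) / 2
    v[!is.finite(v) | v <= 0] <- half_min
    log2(v)
  })
  out <- matrix(out, nrow = nrow(mat), dimnames = dimnames(mat))
  ft_set_intensities(table, out, scale = "log2")
}

#' Autoscaling (unit-variance scaling)
#'
#' Mean-centers every feature and divides by its sample standard deviation,
#' so each retained feature has mean 0 and standard deviation 1 across
#' samples. Zero-variance features cannot be scaled and are dropped with a
#' warning.
#'
#' @param table A [feature_table()] with >= 2 samples (any scale).
#' @return An autoscaled [feature_table()].
#' @export
autoscale <- function(table) {
  fm_assert(inherits(table, "feature_table"), "'table' must be a feature_table")
  mat <- intensity_matrix(table)
  fm_assert(nrow(mat) >= 2, "autoscaling requires >= 2 samples")
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("autoscale: dropped %d zero-variance feature(s)",
                    sum(sds == 0)))
    mat <- mat[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  out <- scale(mat, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  ft_set_intensities(table, out, scale = "autoscaled")
}

#' Run the default preprocessing chain
#'
#' Applies, in order: [qc_loess_correct()], [rsd_filter()], optional
#' [internal_standard_normalize()], [impute_and_log2()], [autoscale()].
#' Intermediate tables are returned so downstream stages can pick the scale
#' they need (raw filtered intensities for fold changes, log2 for t-tests,
#' autoscaled for multivariate models).
#'
#' @param table A raw-scale [feature_table()].
#' @param span LOESS span for drift correction.
#' @param max_rsd QC RSD threshold in percent.
#' @param is_feature Optional internal-standard feature id (NULL skips the
#'   normalization step).
#' @param is_concentration Internal-standard amount.
#' @param correct_drift Set `FALSE` to skip drift correction (e.g. for
#'   drift-free data).
#' @return A `preprocess_result` list: `corrected`, `filtered`, `log2`,
#'   `autoscaled` feature tables plus `qc_stats`.
#' @export
run_preprocess <- function(table, span = 0.75, max_rsd = 30,
                           is_feature = NULL, is_concentration = 1,
                           correct_drift = TRUE) {
  if (correct_drift) {
    corr <- qc_loess_correct(table, span = span)
    corrected <- corr$table
    qc_stats <- corr$qc_stats
  } else {
    corrected <- table
    qc_stats <- NULL
  }
  filtered <- rsd_filter(corrected, max_rsd = max_rsd)
  if (!is.null(is_feature)) {
    filtered <- internal_standard_normalize(filtered, is_feature,
                                            is_concentration)
  }
  log2_tab <- impute_and_log2(filtered)
  auto_tab <- autoscale(log2_tab)
  structure(list(corrected = corrected, filtered = filtered,
                 log2 = log2_tab, autoscaled = auto_tab,
                 qc_stats = qc_stats),
            class = "preprocess_result")
}
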