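# Small in-code fixtures shared across test files.

# A minimal feature table built by hand: `qc` rows carry the given QC
# values for a single feature, biological rows the given sample values.
tiny_table <- function(values, groups, orders = seq_along(values),
                       feature_id = "F1") {
  mat <- matrix(values, ncol = 1, dimnames = list(NULL, feature_id))
  feature_table(mat, sprintf("S%d", seq_along(values)), groups, orders)
}

# Multi-feature table from a matrix with explicit groups/orders.
table_from_matrix <- function(mat, groups, orders = seq_len(nrow(mat))) {
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("F%d", seq_len(ncol(mat)))
  }
  feature_table(mat, sprintf("S%d", seq_len(nrow(mat))), groups, orders)
}

# Hand-built odor table: one row per compound x group.
tiny_odor_table <- function(compound_id, group, peak_area, odor_threshold,
                            descriptors = NA_character_) {
  df <- data.frame(compound_id = compound_id, group = group,
                   peak_area = peak_area, odor_threshold = odor_threshold,
                   descriptors = descriptors, stringsAsFactors = FALSE)
  class(df) <- c("odor_table", "data.frame")
  df
}

# Exact hypergeometric upper tail by combinatorial enumeration, used as
# the independent oracle for the enrichment test.
hyper_tail_enum <- function(k, m, N, n) {
  ks <- max(0, n - (N - m)):min(m, n)
  probs <- vapply(ks, function(x) {
    choose(m, x) * choose(N - m, n - x) / choose(N, n)
  }, numeric(1))
  sum(probs[ks >= k])
}
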