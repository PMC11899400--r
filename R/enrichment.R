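## Pathway over-representation analysis (ORA) of a DAM set against a
## pathway-membership map, with the one-sided hypergeometric upper-tail
## test and Benjamini-Hochberg correction.

#' Hypergeometric pathway over-representation analysis
#'
#' For each pathway with `m` members in the background of `N` detected
#' features, the probability of observing at least the `k` hits found in a
#' DAM list of size `n` is the hypergeometric upper tail `P[X >= k]`.
#' P-values are corrected across tested pathways with Benjamini-Hochberg.
#'
#' @param dam_list Character vector of differential feature ids; must be a
#'   subset of `background`.
#' @param background Character vector: all annotated features that survived
#'   preprocessing (the detected universe).
#' @param pathway_map Named list of pathway member vectors, or an
#'   `annotation_map` (its `pathways` element is used). Members outside the
#'   background are ignored; pathways with no background members are
#'   skipped with a warning.
#' @param q_threshold Significance threshold on the q-value (default 0.05).
#' @return An `enrichment_table` data.frame sorted by p-value:
#'   `pathway_id`, `k` (hits), `m` (pathway size in background), `n` (DAM
#'   list size), `N` (background size), `p_value`, `q_value`,
#'   `enrichment_ratio` (`k` over its expectation `n*m/N`), `significant`.
#' @export
enrich_pathways <- function(dam_list, background, pathway_map,
                            q_threshold = 0.05) {
  fm_assert(length(background) > 0, "'background' must be non-empty")
  background <- unique(as.character(background))
  dam_list <- unique(as.character(dam_list))
  fm_assert(all(dam_list %in% background),
            "'dam_list' must be a subset of 'background'")
  if (inherits(pathway_map, "annotation_map")) {
    pathway_map <- pathway_map$pathways
  }
  fm_assert(is.list(pathway_map), "'pathway_map' must be a named list")

  N <- length(background)
  n <- length(dam_list)
  rows <- lapply(names(pathway_map), function(pid) {
    members <- intersect(unique(pathway_map[[pid]]), background)
    if (length(members) == 0) {
      warning(sprintf("enrich_pathways: pathway '%s' has no background members; skipped",
                      pid))
      return(NULL)
    }
    m <- length(members)
    k <- length(intersect(dam_list, members))
    p <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    expected <- n * m / N
    data.frame(pathway_id = pid, k = k, m = m, n = n, N = N,
               p_value = p,
               enrichment_ratio = if (expected > 0) k / expected else NA_real_,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(pathway_id = character(0), k = integer(0),
                      m = integer(0), n = integer(0), N = integer(0),
                      p_value = numeric(0), q_value = numeric(0),
                      enrichment_ratio = numeric(0), significant = logical(0))
    class(out) <- c("enrichment_table", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value <= q_threshold
  out <- out[order(out$p_value, out$pathway_id),
             c("pathway_id", "k", "m", "n", "N", "p_value", "q_value",
               "enrichment_ratio", "significant")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Read a pathway-membership map from a two-column TSV
#'
#' Expected columns: `pathway_id`, `feature_id` (one row per membership).
#'
#' @param path TSV file path.
#' @return Named list of feature id vectors.
#' @export
read_pathway_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  fm_assert(all(c("pathway_id", "feature_id") %in% names(df)),
            "pathway map TSV needs columns pathway_id, feature_id",
            "invalid_input")
  lapply(split(df$feature_id, df$pathway_id), unique)
}
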