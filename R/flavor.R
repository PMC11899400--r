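## Flavoromics: relative odor activity values (ROAV), key-compound
## selection, Kovats retention indices, descriptor radar grading and the
## compound-descriptor bipartite network.

#' Relative odor activity values (ROAV)
#'
#' The odor activity value of a compound is its peak area divided by its
#' odor threshold (`OAV = Peak / T`); ROAV rescales OAVs so the reference
#' compound scores exactly 100. In the default mode the reference is the
#' compound with the largest OAV in scope and
#' `ROAV_B = 100 * OAV_B / OAV_A`, so all values lie in `(0, 100]` and the
#' ROAV ranking equals the OAV ranking. The `literal_eq3` mode instead
#' uses the product form `ROAV_B = 100 * (Peak_B * T_B) / (Peak_A * T_A)`
#' with the smallest-threshold compound as reference; it is provided for
#' comparison with that convention, and the reference still scores 100.
#'
#' @param table An `odor_table` (or data.frame) with columns
#'   `compound_id`, `group`, `peak_area`, `odor_threshold`. All thresholds
#'   must be positive; groups without any positive peak area are skipped
#'   with a warning.
#' @param mode `"default"` (OAV ratio) or `"literal_eq3"` (product form).
#' @param reference_scope `"per_group"` (a reference per sample group, the
#'   default) or `"global"` (one reference across the whole table).
#' @return A `roav_table` data.frame: `compound_id`, `group`, `oav`,
#'   `roav`, `is_reference`, `is_key` (`roav > 1`, strict).
#' @export
compute_roav <- function(table, mode = c("default", "literal_eq3"),
                         reference_scope = c("per_group", "global")) {
  mode <- match.arg(mode)
  reference_scope <- match.arg(reference_scope)
  need <- c("compound_id", "group", "peak_area", "odor_threshold")
  fm_assert(is.data.frame(table) && all(need %in% names(table)),
            paste("odor table needs columns:", paste(need, collapse = ", ")))
  if (any(!is.finite(table$odor_threshold) | table$odor_threshold <= 0)) {
    fm_stop("all odor thresholds must be positive", "invalid_input")
  }
  fm_assert(all(table$peak_area >= 0), "peak areas must be >= 0",
            "invalid_input")

  score <- function(df) {  # reference statistic per mode
    if (mode == "default") df$peak_area / df$odor_threshold
    else df$peak_area * df$odor_threshold
  }
  pick_reference <- function(df) {
    if (mode == "default") {
      which.max(df$peak_area / df$odor_threshold)
    } else {
      # smallest odor threshold; ties broken by larger peak area
      cand <- which(df$odor_threshold == min(df$odor_threshold))
      cand[which.max(df$peak_area[cand])]
    }
  }

  groups <- unique(table$group)
  global_ref_value <- NULL
  if (reference_scope == "global") {
    ok <- table$peak_area > 0
    fm_assert(any(ok), "no compound with positive peak area", "invalid_input")
    ref_row <- table[ok, , drop = FALSE][pick_reference(table[ok, , drop = FALSE]), ]
    global_ref_value <- score(ref_row)
    global_ref_id <- ref_row$compound_id
    global_ref_group <- ref_row$group
  }

  out <- lapply(groups, function(g) {
    df <- table[table$group == g, , drop = FALSE]
    if (!any(df$peak_area > 0)) {
      warning(sprintf("compute_roav: group '%s' has no positive peak area; skipped", g))
      return(NULL)
    }
    if (reference_scope == "per_group") {
      pos <- df[df$peak_area > 0, , drop = FALSE]
      ref_idx <- pick_reference(pos)
      ref_value <- score(pos)[ref_idx]
      is_ref <- df$compound_id == pos$compound_id[ref_idx]
    } else {
      ref_value <- global_ref_value
      # the global reference is one (compound, group) row
      is_ref <- df$compound_id == global_ref_id & g == global_ref_group
    }
    roav <- 100 * score(df) / ref_value
    data.frame(compound_id = df$compound_id, group = g,
               oav = df$peak_area / df$odor_threshold, roav = roav,
               is_reference = is_ref,
               is_key = roav > 1,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("roav_table", "data.frame")
  out
}

#' Select key flavor compounds by ROAV
#'
#' A compound is a key flavor compound when its ROAV strictly exceeds the
#' threshold (default 1); a ROAV of exactly 1 is not key.
#'
#' @param records A `roav_table` from [compute_roav()].
#' @param threshold ROAV threshold (default 1, strict inequality).
#' @return The key-compound rows, with per-group key counts in
#'   `attr(, "key_counts")`.
#' @export
select_key_compounds <- function(records, threshold = 1) {
  fm_assert(is.data.frame(records) && all(c("roav", "group") %in%
                                            names(records)),
            "'records' must come from compute_roav()")
  key <- records[records$roav > threshold, , drop = FALSE]
  rownames(key) <- NULL
  counts <- table(factor(key$group, levels = unique(records$group)))
  attr(key, "key_counts") <- counts
  key
}

#' Kovats retention index by linear interpolation
#'
#' `RI = 100 * (n + (rt - rt_n) / (rt_(n+1) - rt_n))` for the pair of
#' n-alkanes (carbon numbers `n`, `n+1`) bracketing the analyte retention
#' time. Retention times outside the alkane span are an error: no
#' extrapolation.
#'
#' @param rt Analyte retention time(s) in minutes.
#' @param alkane_rts Named numeric vector of alkane retention times; names
#'   are carbon numbers (e.g. `c("7" = 1.8, ..., "30" = 55)`). Times must
#'   be strictly increasing with carbon number.
#' @return Data.frame `rt`, `lower_carbon`, `upper_carbon`, `ri`.
#' @export
retention_index <- function(rt, alkane_rts) {
  fm_assert(!is.null(names(alkane_rts)) && length(alkane_rts) >= 2,
            "'alkane_rts' must be a named vector (carbon number -> minutes)")
  carbons <- as.numeric(names(alkane_rts))
  fm_assert(!anyNA(carbons), "alkane names must be carbon numbers")
  ord <- order(carbons)
  carbons <- carbons[ord]
  times <- as.numeric(alkane_rts[ord])
  if (any(diff(times) <= 0)) {
    fm_stop("alkane retention times must be strictly increasing with carbon number",
            "invalid_input")
  }
  out_of_span <- rt < times[1] | rt > times[length(times)]
  if (any(out_of_span)) {
    fm_stop(sprintf("retention time(s) %s outside the alkane span [%g, %g]; no extrapolation",
                    paste(rt[out_of_span], collapse = ", "),
                    times[1], times[length(times)]),
            "out_of_range")
  }
  res <- lapply(rt, function(r) {
    i <- findInterval(r, times, rightmost.closed = TRUE)
    if (times[i] == r) {
      data.frame(rt = r, lower_carbon = carbons[i], upper_carbon = carbons[i],
                 ri = 100 * carbons[i])
    } else {
      frac <- (r - times[i]) / (times[i + 1] - times[i])
      data.frame(rt = r, lower_carbon = carbons[i],
                 upper_carbon = carbons[i + 1],
                 ri = 100 * (carbons[i] + frac * (carbons[i + 1] - carbons[i])))
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

## Normalize a descriptor map to a named list compound -> descriptors.
as_descriptor_map <- function(descriptor_map) {
  if (is.data.frame(descriptor_map)) {
    fm_assert(all(c("compound_id", "descriptor") %in% names(descriptor_map)),
              "descriptor data.frame needs columns compound_id, descriptor")
    return(lapply(split(descriptor_map$descriptor,
                        descriptor_map$compound_id), unique))
  }
  fm_assert(is.list(descriptor_map) && !is.null(names(descriptor_map)),
            "'descriptor_map' must be a named list or data.frame")
  descriptor_map
}

#' Build a descriptor map from an odor table
#' @param table An `odor_table` with a semicolon-joined `descriptors`
#'   column.
#' @return Named list compound -> character vector of descriptors.
#' @export
descriptor_map_from_odor_table <- function(table) {
  fm_assert(all(c("compound_id", "descriptors") %in% names(table)),
            "odor table needs compound_id and descriptors columns")
  first <- table[!duplicated(table$compound_id), ]
  stats::setNames(lapply(strsplit(first$descriptors, ";", fixed = TRUE),
                         function(d) unique(trimws(d[nzchar(d)]))),
                  first$compound_id)
}

#' Descriptor radar grades per group
#'
#' Counts, per group, how many key compounds carry each descriptor
#' (compounds without a descriptor entry fall into `"unknown"`), then maps
#' counts to grades 1–5 by equal-width binning between the minimum and
#' maximum count within the group; the most frequent descriptor always
#' gets grade 5.
#'
#' @param key_compounds Data.frame with `compound_id` and `group` (e.g.
#'   from [select_key_compounds()]).
#' @param descriptor_map Named list compound -> descriptors, or a
#'   data.frame (`compound_id`, `descriptor`).
#' @return Data.frame `group`, `descriptor`, `count`, `grade` (empty when
#'   there are no key compounds).
#' @export
descriptor_radar <- function(key_compounds, descriptor_map) {
  dmap <- as_descriptor_map(descriptor_map)
  if (NROW(key_compounds) == 0) {
    return(data.frame(group = character(0), descriptor = character(0),
                      count = integer(0), grade = integer(0)))
  }
  out <- lapply(unique(key_compounds$group), function(g) {
    ids <- key_compounds$compound_id[key_compounds$group == g]
    descr <- unlist(lapply(ids, function(id) {
      d <- dmap[[id]]
      if (is.null(d) || length(d) == 0) "unknown" else d
    }))
    counts <- table(descr)
    lo <- min(counts); hi <- max(counts)
    grade <- if (hi == lo) rep(5L, length(counts)) else {
      pmin(1L + as.integer(floor(4 * (as.integer(counts) - lo) / (hi - lo))), 5L)
    }
    data.frame(group = g, descriptor = names(counts),
               count = as.integer(counts), grade = grade,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Compound-descriptor bipartite flavor network
#'
#' One node per key compound and per descriptor; one edge per
#' (compound, descriptor) incidence. Compounds with no descriptors are
#' kept as isolated nodes.
#'
#' @inheritParams descriptor_radar
#' @return A `flavor_network`: `nodes` (`id`, `type`), `edges`
#'   (`compound_id`, `descriptor`), `degree` (`id`, `type`, `degree`).
#' @export
flavor_network <- function(key_compounds, descriptor_map) {
  dmap <- as_descriptor_map(descriptor_map)
  compounds <- unique(key_compounds$compound_id)
  edges <- do.call(rbind, lapply(compounds, function(id) {
    d <- dmap[[id]]
    if (is.null(d) || length(d) == 0) return(NULL)
    data.frame(compound_id = id, descriptor = d, stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(compound_id = character(0),
                        descriptor = character(0))
  }
  descriptors <- unique(edges$descriptor)
  nodes <- rbind(
    data.frame(id = compounds,
               type = rep("compound", length(compounds)),
               stringsAsFactors = FALSE),
    data.frame(id = descriptors,
               type = rep("descriptor", length(descriptors)),
               stringsAsFactors = FALSE))
  deg <- c(table(factor(edges$compound_id, levels = compounds)),
           table(factor(edges$descriptor, levels = descriptors)))
  degree <- data.frame(id = nodes$id, type = nodes$type,
                       degree = as.integer(deg[nodes$id]),
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, degree = degree),
            class = "flavor_network")
}

#' @export
print.flavor_network <- function(x, ...) {
  cat(sprintf("<flavor_network> %d compounds, %d descriptors, %d edges\n",
              sum(x$nodes$type == "compound"),
              sum(x$nodes$type == "descriptor"), nrow(x$edges)))
  invisible(x)
}

#' Write / read odor tables as CSV
#' @param table An `odor_table`.
#' @param path File path.
#' @return `path` invisibly, or the read `odor_table`.
#' @export
write_odor_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_odor_table
#' @export
read_odor_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "group", "peak_area", "odor_threshold")
  fm_assert(all(need %in% names(df)),
            paste("odor table CSV needs columns:",
                  paste(need, collapse = ", ")), "invalid_input")
  class(df) <- c("odor_table", "data.frame")
  df
}
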