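#' Per-sample composition summary
#'
#' Accumulates reads per sample into four categories — `unassigned`
#' (domain-level), `mitochondria`, `chloroplast`, `other` (everything with a
#' resolved, non-organelle lineage) — and reports fractions of the sample
#' total. Features missing from `assignments` are treated as Unassigned with a
#' warning. Zero-read samples are flagged (`zero_total`) and their fractions
#' reported as `NA`.
#'
#' @param table feature table (integer matrix, features x samples).
#' @param assignments assignment table from [classify_sequences()] (or any data
#'   frame with `feature_id`, `is_mitochondrion`, `is_chloroplast`,
#'   `unassigned` columns).
#' @return data frame: `sample_id`, `total`, `p_unassigned`, `p_mitochondria`,
#'   `p_chloroplast`, `p_other`, `zero_total`.
#' @export
composition_summary <- function(table, assignments) {
  table <- validate_feature_table(table)
  cat_by_feature <- feature_categories(rownames(table), assignments)
  totals <- colSums(table)
  acc <- rowsum(table, group = cat_by_feature)  # categories x samples
  get <- function(category) {
    if (category %in% rownames(acc)) acc[category, ] else rep(0, ncol(table))
  }
  zero <- totals == 0
  frac <- function(x) ifelse(zero, NA_real_, x / totals)
  data.frame(sample_id = colnames(table), total = unname(totals),
             p_unassigned = unname(frac(get("unassigned"))),
             p_mitochondria = unname(frac(get("mitochondria"))),
             p_chloroplast = unname(frac(get("chloroplast"))),
             p_other = unname(frac(get("other"))),
             zero_total = unname(zero),
             stringsAsFactors = FALSE)
}

# category per feature: unassigned / mitochondria / chloroplast / other
feature_categories <- function(feature_ids, assignments) {
  idx <- match(feature_ids, assignments$feature_id)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " feature(s) missing from assignments; ",
            "treated as Unassigned")
  mito <- ifelse(is.na(idx), FALSE, assignments$is_mitochondrion[idx])
  chlo <- ifelse(is.na(idx), FALSE, assignments$is_chloroplast[idx])
  unas <- ifelse(is.na(idx), TRUE, assignments$unassigned[idx])
  ifelse(mito, "mitochondria",
         ifelse(chlo, "chloroplast",
                ifelse(unas, "unassigned", "other")))
}

FLOW_LABELS <- c("Unassigned", "Mitochondria", "Chloroplast",
                 "Bacteria", "Archaea", "Eukaryota", "other")

# flow label of a feature at the requested level; organelle labels override.
flow_labels <- function(feature_ids, assignments, level = "domain") {
  stopifnot(level %in% RANK_NAMES)
  idx <- match(feature_ids, assignments$feature_id)
  if (anyNA(idx))
    stop("assignments do not cover features: ",
         paste(head(feature_ids[is.na(idx)], 5), collapse = ", "))
  lineages <- attr(assignments, "lineages")
  lab <- vapply(seq_along(feature_ids), function(i) {
    row <- idx[i]
    if (assignments$is_mitochondrion[row]) return("Mitochondria")
    if (assignments$is_chloroplast[row]) return("Chloroplast")
    if (assignments$unassigned[row]) return("Unassigned")
    value <- if (!is.null(lineages))
      lineages[[assignments$feature_id[row]]]$ranks[[level]]
    else if (level == "domain") assignments$domain[row]
    else stop("rank-level flows need the lineages attribute on assignments")
    if (value == "") return("other")   # resolved lineage, unresolved at level
    if (level == "domain" && !value %in% c("Bacteria", "Archaea", "Eukaryota"))
      return("other")
    value
  }, character(1))
  lab
}

#' Read-mass flow between two sets of assignments
#'
#' Each feature contributes its total read count across all samples to the
#' cell (label under base assignments, label under extended assignments),
#' labels computed at the requested rank with organelle labels overriding (a
#' mitochondrial lineage maps to `"Mitochondria"` regardless of level). Total
#' flow mass equals the table's grand total.
#'
#' @param assign_base,assign_ext assignment tables covering the table's
#'   features.
#' @param table feature table.
#' @param level rank at which to label non-organelle lineages (default
#'   `"domain"`).
#' @return data frame: `label_from`, `label_to`, `mass` (only non-empty cells).
#' @export
reclassification_flow <- function(assign_base, assign_ext, table,
                                  level = "domain") {
  table <- validate_feature_table(table)
  from <- flow_labels(rownames(table), assign_base, level)
  to <- flow_labels(rownames(table), assign_ext, level)
  mass <- rowSums(table)
  agg <- stats::aggregate(list(mass = mass),
                          by = list(label_from = from, label_to = to), FUN = sum)
  agg <- agg[order(-agg$mass, agg$label_from, agg$label_to), ]
  rownames(agg) <- NULL
  agg
}

#' Remove organelle features from a feature table
#'
#' Rows whose assigned lineage is mitochondrial or chloroplastic are dropped;
#' retained counts are untouched (no renormalisation) and all-zero rows among
#' the retained features are kept.
#'
#' @inheritParams composition_summary
#' @return the filtered feature table.
#' @export
filter_organelles <- function(table, assignments) {
  table <- validate_feature_table(table)
  category <- feature_categories(rownames(table), assignments)
  table[!category %in% c("mitochondria", "chloroplast"), , drop = FALSE]
}

#' Per-sample fold-change in unknown (Unassigned) reads
#'
#' fold = p_unassigned(base) / p_unassigned(extended), per sample. An extended
#' value of 0 with base > 0 gives `Inf` and counts as above threshold; samples
#' with base = 0 (or zero total reads in either summary) are excluded from the
#' threshold-count denominator.
#'
#' @param base,ext [composition_summary()] tables over the same samples.
#' @param threshold fold threshold for the headline count (default 10,
#'   mirroring ">= 10-fold" reporting).
#' @return list: `per_sample` data frame (`sample_id`, `p_base`, `p_ext`,
#'   `fold`, `counted`), `n_above` (samples with fold >= threshold),
#'   `n_evaluated` (denominator), `threshold`.
#' @export
unknown_fold_change <- function(base, ext, threshold = 10) {
  if (!setequal(base$sample_id, ext$sample_id))
    stop("sample sets differ: ",
         paste(head(c(setdiff(base$sample_id, ext$sample_id),
                      setdiff(ext$sample_id, base$sample_id)), 5),
               collapse = ", "))
  ext <- ext[match(base$sample_id, ext$sample_id), ]
  p_base <- base$p_unassigned
  p_ext <- ext$p_unassigned
  evaluable <- !is.na(p_base) & !is.na(p_ext) & p_base > 0
  fold <- ifelse(evaluable, ifelse(p_ext == 0, Inf, p_base / p_ext), NA_real_)
  counted <- evaluable & fold >= threshold
  list(per_sample = data.frame(sample_id = base$sample_id,
                               p_base = p_base, p_ext = p_ext, fold = fold,
                               counted = counted, stringsAsFactors = FALSE),
       n_above = sum(counted),
       n_evaluated = sum(evaluable),
       threshold = threshold)
}
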