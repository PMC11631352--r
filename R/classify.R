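#' Classification parameters
#'
#' Defaults mirror the documented defaults of the consensus and naive-Bayes
#' classifiers the workflow reimplements, plus the positive-filter thresholds
#' (65% identity, 50% coverage) of the SortMeRNA-style screen.
#'
#' @param perc_identity minimum global-query identity for an accepted hit.
#' @param maxaccepts maximum accepted hits per query.
#' @param min_consensus fraction of accepted hits that must share a label for a
#'   rank to be kept.
#' @param k word size for the naive-Bayes classifier.
#' @param alpha additive smoothing for k-mer likelihoods.
#' @param confidence posterior threshold for naive-Bayes rank truncation.
#' @param filter_identity,filter_coverage positive-filter thresholds
#'   (boundary inclusive).
#' @param prefilter_k,prefilter_candidates shared k-mer prefilter: candidates
#'   are the `prefilter_candidates` references sharing the most distinct
#'   `prefilter_k`-mers with the query (ties broken by reference id ascending).
#' @return a `classify_params` object.
#' @export
classify_params <- function(perc_identity = 0.80, maxaccepts = 10L,
                            min_consensus = 0.51, k = 7L, alpha = 0.001,
                            confidence = 0.70, filter_identity = 0.65,
                            filter_coverage = 0.50, prefilter_k = 8L,
                            prefilter_candidates = 50L) {
  stopifnot(perc_identity > 0, perc_identity <= 1,
            min_consensus > 0, min_consensus <= 1,
            filter_identity > 0, filter_identity <= 1,
            filter_coverage > 0, filter_coverage <= 1,
            maxaccepts >= 1L, k >= 4L, alpha > 0,
            prefilter_k >= 4L, prefilter_candidates >= 1L)
  structure(list(perc_identity = perc_identity, maxaccepts = as.integer(maxaccepts),
                 min_consensus = min_consensus, k = as.integer(k), alpha = alpha,
                 confidence = confidence, filter_identity = filter_identity,
                 filter_coverage = filter_coverage,
                 prefilter_k = as.integer(prefilter_k),
                 prefilter_candidates = as.integer(prefilter_candidates)),
            class = "classify_params")
}

# Sorted unique k-mer code sets, one per sequence (C++; non-ACGT windows skip).
kmer_code_sets <- function(seqs, k) {
  .kmer_code_sets_cpp(toupper(seqs), as.integer(k))
}

# Indices (into ref ids) of the top shared-kmer candidates.
prefilter_candidates_for <- function(query, ref_codes, ref_ids, params) {
  qc <- kmer_code_sets(query, params$prefilter_k)[[1]]
  shared <- .shared_kmer_counts_cpp(qc, ref_codes)
  ord <- order(-shared, ref_ids, method = "radix")
  ord[seq_len(min(params$prefilter_candidates, length(ord)))]
}

#' Search a reference database for top hits
#'
#' Candidates are prefiltered by shared `prefilter_k`-mer count (top
#' `prefilter_candidates`, ties by reference id ascending), aligned with the
#' query-global semi-global aligner, and sorted by identity descending then
#' reference id ascending. Only hits with identity >= `perc_identity` are
#' retained, truncated to `maxaccepts`.
#'
#' @param query single named sequence (named character) or one-row data frame
#'   (`id`, `seq`).
#' @param db a `reference_db`.
#' @param params a [classify_params()].
#' @param min_identity overrides the acceptance cutoff (used by the positive
#'   filter, which accepts all hits); `NULL` means `params$perc_identity`.
#' @param mode alignment end-gap mode (see [semiglobal_align()]).
#' @param max_hits overrides `params$maxaccepts`.
#' @return data frame of hits: `query_id`, `ref_id`, `identity`, `coverage`,
#'   `score`.
#' @export
search_reference <- function(query, db, params = classify_params(),
                             min_identity = NULL, mode = "query_global",
                             max_hits = NULL) {
  if (is.data.frame(query)) query <- setNames(query$seq, query$id)
  stopifnot(length(query) == 1L)
  empty <- data.frame(query_id = character(0), ref_id = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  if (length(db$seqs) == 0L) return(empty)
  min_identity <- min_identity %||% params$perc_identity
  max_hits <- max_hits %||% params$maxaccepts
  ids <- names(db$seqs)
  codes <- db_kmer_index(db, params$prefilter_k)
  cand <- prefilter_candidates_for(unname(query), codes, ids, params)
  aln <- align_batch(unname(query), unname(db$seqs[cand]), mode = mode)
  hits <- data.frame(query_id = names(query), ref_id = ids[cand],
                     identity = aln$identity, coverage = aln$coverage,
                     score = aln$score, stringsAsFactors = FALSE)
  hits <- hits[order(-hits$identity, hits$ref_id, method = "radix"), ]
  hits <- hits[hits$identity >= min_identity, , drop = FALSE]
  rownames(hits) <- NULL
  head(hits, max_hits)
}

# Cache the reference k-mer code index on the db object (memoisation via
# attribute; recomputed when k differs).
db_kmer_index <- function(db, k) {
  cache <- attr(db, "kmer_index")
  if (!is.null(cache) && identical(attr(cache, "k"), k)) return(cache)
  codes <- kmer_code_sets(unname(db$seqs), k)
  attr(codes, "k") <- k
  codes
}

# Precompute and attach the prefilter index; returns the db. Worth calling
# once before classifying many queries against the same db.
index_reference <- function(db, params = classify_params()) {
  attr(db, "kmer_index") <- db_kmer_index(db, params$prefilter_k)
  db
}

#' Consensus (top-hit plurality) taxonomy classification
#'
#' If the search returns no accepted hits the query is `Unassigned` with score
#' 0. Otherwise, for each rank from domain downward the fraction of accepted
#' hits sharing the plurality label is computed; ranks are kept while that
#' fraction >= `min_consensus` (plurality ties fail the rank), and the lineage
#' truncates at the first failing rank. The score is the consensus fraction at
#' the deepest kept rank.
#'
#' @inheritParams search_reference
#' @return a `classification`: list with `feature_id`, `lineage`, `score`,
#'   `method`.
#' @export
classify_consensus <- function(query, db, params = classify_params()) {
  if (is.data.frame(query)) query <- setNames(query$seq, query$id)
  hits <- search_reference(query, db, params)
  unassigned <- new_lineage("Unassigned", db$dialect)
  if (nrow(hits) == 0L)
    return(new_classification(names(query), unassigned, 0, "consensus"))
  mat <- lineage_rank_matrix(db$lineages[hits$ref_id])
  n <- nrow(mat)
  on_path <- rep(TRUE, n)   # hits whose lineage matches the kept labels so far
  labels <- character(0)
  score <- NA_real_
  for (r in seq_len(7L)) {
    lab <- mat[on_path, r]
    tab <- table(lab)
    top <- max(tab)
    winners <- names(tab)[tab == top]
    frac <- top / n         # consensus fraction relative to ALL accepted hits
    # plurality tie, empty plurality label, or insufficient consensus -> stop
    if (length(winners) != 1L || winners == "" || frac < params$min_consensus)
      break
    labels <- c(labels, winners)
    score <- frac
    on_path <- on_path & mat[, r] == winners
  }
  if (length(labels) == 0L)
    return(new_classification(names(query), unassigned, 0, "consensus"))
  new_classification(names(query), new_lineage(labels, db$dialect),
                     score, "consensus")
}

new_classification <- function(feature_id, lineage, score, method) {
  structure(list(feature_id = feature_id, lineage = lineage,
                 score = score, method = method),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat("<classification [", x$method, "]> ", x$feature_id, ": ",
      format_lineage(x$lineage), " (score ", signif(x$score, 3), ")\n", sep = "")
  invisible(x)
}

# ranks (7 cols) for a list of lineages
lineage_rank_matrix <- function(lineages) {
  m <- t(vapply(lineages, function(l) l$ranks, character(7)))
  if (length(lineages) == 1L) m <- matrix(m, nrow = 1,
                                          dimnames = list(NULL, RANK_NAMES))
  m
}

#' Classify many sequences, returning an assignment table
#'
#' Convenience wrapper used by the audit workflow and the command line: runs
#' [classify_consensus()] (or the naive-Bayes classifier) over a set of
#' sequences and returns one row per feature with the formatted lineage, the
#' derived organelle flags, and the domain-level label.
#'
#' @param queries data frame (`id`, `seq`) or named character vector.
#' @param db a `reference_db` (consensus) — for `method = "naive_bayes"` a
#'   trained model is built from `db` unless one is supplied via `model`.
#' @param params a [classify_params()].
#' @param method `"consensus"` or `"naive_bayes"`.
#' @param model optional pre-trained [train_naive_bayes()] model.
#' @return data frame: `feature_id`, `taxon`, `score`, `method`,
#'   `is_mitochondrion`, `is_chloroplast`, `unassigned`, `domain`; the parsed
#'   lineages are attached as attribute `lineages`.
#' @export
classify_sequences <- function(queries, db, params = classify_params(),
                               method = c("consensus", "naive_bayes"),
                               model = NULL) {
  method <- match.arg(method)
  if (is.data.frame(queries)) queries <- setNames(queries$seq, queries$id)
  db <- index_reference(db, params)
  if (method == "naive_bayes" && is.null(model))
    model <- train_naive_bayes(db, params)
  out <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    q <- queries[i]
    out[[i]] <- if (method == "consensus")
      classify_consensus(q, db, params)
    else
      classify_naive_bayes(model, q, params)
  }
  assignment_table(out)
}

#' Assemble classifications into an assignment table
#' @param classifications list of `classification` objects.
#' @return the data frame documented in [classify_sequences()].
#' @export
assignment_table <- function(classifications) {
  lineages <- lapply(classifications, `[[`, "lineage")
  df <- data.frame(
    feature_id = vapply(classifications, `[[`, character(1), "feature_id"),
    taxon = vapply(lineages, format_lineage, character(1)),
    score = vapply(classifications, `[[`, numeric(1), "score"),
    method = vapply(classifications, `[[`, character(1), "method"),
    is_mitochondrion = vapply(lineages, `[[`, logical(1), "is_mitochondrion"),
    is_chloroplast = vapply(lineages, `[[`, logical(1), "is_chloroplast"),
    unassigned = vapply(lineages, is_unassigned, logical(1)),
    domain = vapply(lineages, function(l) l$ranks[["domain"]], character(1)),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "lineages") <- setNames(lineages, df$feature_id)
  df
}

#' Positive identity/coverage screen
#'
#' A query is kept iff some screen sequence aligns with identity >=
#' `filter_identity` and query coverage >= `filter_coverage` (both boundaries
#' inclusive), under the ends-free overlap aligner. This reproduces the
#' SortMeRNA-style positive filter (65% identity / 50% coverage by default)
#' that some denoising pipelines apply against a trusted 16S reference set.
#' The partition preserves input order. No identity acceptance cutoff is
#' applied during the search itself.
#'
#' @param queries data frame (`id`, `seq`) or named character vector.
#' @param screen_db data frame (`id`, `seq`), named character vector, or
#'   `reference_db` of trusted reference sequences (non-empty).
#' @param params a [classify_params()].
#' @return list with `kept` and `discarded` (same representation as input
#'   queries, as a data frame), plus a logical vector `keep` named by id.
#' @export
positive_filter <- function(queries, screen_db, params = classify_params()) {
  if (is.data.frame(queries)) queries <- setNames(queries$seq, queries$id)
  if (inherits(screen_db, "reference_db")) screen_db <- screen_db$seqs
  if (is.data.frame(screen_db)) screen_db <- setNames(screen_db$seq, screen_db$id)
  if (length(screen_db) == 0L) stop("screen_db must be non-empty")
  ids <- names(screen_db)
  codes <- kmer_code_sets(unname(screen_db), params$prefilter_k)
  keep <- logical(length(queries))
  for (i in seq_along(queries)) {
    cand <- prefilter_candidates_for(unname(queries[i]), codes, ids, params)
    aln <- align_batch(unname(queries[i]), unname(screen_db[cand]),
                       mode = "overlap")
    keep[i] <- any(aln$identity >= params$filter_identity &
                   aln$coverage >= params$filter_coverage)
  }
  names(keep) <- names(queries)
  df <- data.frame(id = names(queries), seq = unname(queries),
                   stringsAsFactors = FALSE)
  list(kept = df[keep, , drop = FALSE],
       discarded = df[!keep, , drop = FALSE],
       keep = keep)
}
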