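#' Semi-global pairwise alignment with identity and coverage
#'
#' Optimal alignment under match +1, mismatch -1, linear gap -2 scoring, with
#' free terminal gaps. Two end-gap modes are provided because the two places
#' the toolkit aligns have different semantics:
#'
#' * `"overlap"` (default): terminal gaps free on both ends of both sequences.
#'   This is the SortMeRNA-like screen geometry: the aligned region may cover
#'   only part of the query, and `coverage` (aligned query positions / query
#'   length) is informative. Used by [positive_filter()].
#' * `"query_global"`: the full query is aligned (query terminal gaps
#'   penalised), reference overhangs free. This reproduces the global-query
#'   identity of usearch/vsearch-style taxonomy search: on unrelated sequences
#'   the ends-free-both optimum is a tiny near-perfect fragment whose identity
#'   says nothing, so classification search must not use it. Used by
#'   [search_reference()]. `coverage` is 1 by construction.
#'
#' Identity = matches / alignment columns, counting internal gap columns and
#' excluding terminal overhangs; a match is an IUPAC set intersection (so a
#' degenerate reference base matches any base in its set).
#'
#' @param a query DNA string (non-empty).
#' @param b reference DNA string (non-empty; degenerate codes allowed).
#' @param match,mismatch,gap scoring parameters.
#' @param mode `"overlap"` or `"query_global"`.
#' @return list with `score`, `identity`, `coverage`, `matches`, `columns`.
#' @export
semiglobal_align <- function(a, b, match = 1, mismatch = -1, gap = -2,
                             mode = c("overlap", "query_global")) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence in alignment")
  res <- align_batch(a, b, mode = mode, match = match, mismatch = mismatch,
                     gap = gap)
  as.list(res[1, c("score", "identity", "coverage", "matches", "columns")])
}

# Vectorised over references: one query against a character vector of refs.
align_batch <- function(query, refs, mode = c("overlap", "query_global"),
                        match = 1, mismatch = -1, gap = -2) {
  mode <- match.arg(mode)
  if (!nzchar(query) || any(!nzchar(refs))) stop("empty sequence in alignment")
  .align_batch_cpp(toupper(query), toupper(refs),
                   query_global = (mode == "query_global"),
                   match = match, mismatch = mismatch, gap = gap)
}
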