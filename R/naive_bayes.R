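#' Train the k-mer multinomial naive-Bayes classifier
#'
#' Classes are the distinct full lineages of the training database. For each
#' class, overlapping k-mer counts (as written; no reverse complement; windows
#' containing non-ACGT letters are ignored) are pooled over the class's
#' sequences, additively smoothed with `alpha` over the full 4^k vocabulary and
#' normalised to a multinomial log-likelihood vector. Priors are uniform over
#' classes. Rank confidence at prediction time comes from aggregating class
#' posteriors up the taxonomy (closed-form, deterministic), not from bootstrap
#' resampling.
#'
#' @param db a `reference_db` (non-empty).
#' @param params a [classify_params()] (`k`, `alpha`).
#' @return a `nb_model`: `classes` (formatted lineage strings), `log_prior`,
#'   `log_lik` (classes x 4^k), `rank_labels` (classes x 7), `dialect`, `k`.
#' @export
train_naive_bayes <- function(db, params = classify_params()) {
  stopifnot(inherits(db, "reference_db"))
  if (length(db$seqs) == 0L) stop("training database is empty")
  k <- params$k
  lens <- nchar(db$seqs)
  short <- lens < k
  if (any(short))
    warning(sum(short), " training sequence(s) shorter than k = ", k,
            " skipped: ", paste(head(names(db$seqs)[short], 5), collapse = ", "))
  if (all(short)) stop("all training sequences are shorter than k = ", k)
  keep <- names(db$seqs)[!short]
  tax <- vapply(db$lineages[keep], format_lineage, character(1))
  classes <- sort(unique(tax), method = "radix")
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(unname(db$seqs[keep])), width = k)
  pooled <- rowsum(counts, group = match(tax, classes))
  # rowsum drops absent groups only if a class lost all members; cannot happen
  smoothed <- pooled + params$alpha
  log_lik <- log(smoothed / rowSums(smoothed))
  rank_labels <- lineage_rank_matrix(
    lapply(classes, parse_lineage, dialect = db$dialect))
  structure(list(classes = classes,
                 log_prior = rep(-log(length(classes)), length(classes)),
                 log_lik = log_lik, rank_labels = rank_labels,
                 dialect = db$dialect, k = k),
            class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat("<nb_model> ", length(x$classes), " classes, k = ", x$k,
      " (", ncol(x$log_lik), " words) [", x$dialect, "]\n", sep = "")
  invisible(x)
}

#' Classify a sequence with the naive-Bayes model
#'
#' Class posteriors are proportional to prior x product of word likelihoods
#' over the query's k-mers (computed in the log domain and normalised). Rank
#' confidence is obtained by walking the taxonomy greedily: at each rank the
#' label with the largest summed posterior (within the path chosen so far) is
#' taken, and the lineage truncates at the deepest rank whose confidence is
#' still >= `params$confidence`. An empty label cannot be kept. A query
#' shorter than k is `Unassigned` with score 0 (with a warning).
#'
#' @param model a [train_naive_bayes()] model.
#' @param query single named sequence (named character) or one-row data frame.
#' @param params a [classify_params()].
#' @return a `classification` (method `"naive_bayes"`).
#' @export
classify_naive_bayes <- function(model, query, params = classify_params()) {
  stopifnot(inherits(model, "nb_model"))
  if (is.data.frame(query)) query <- setNames(query$seq, query$id)
  stopifnot(length(query) == 1L)
  unassigned <- new_lineage("Unassigned", model$dialect)
  if (nchar(query) < model$k) {
    warning("query ", names(query), " shorter than k = ", model$k,
            "; returning Unassigned")
    return(new_classification(names(query), unassigned, 0, "naive_bayes"))
  }
  q <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(unname(query)), width = model$k)[1, ]
  log_post <- model$log_prior + as.numeric(model$log_lik %*% q)
  log_post <- log_post - max(log_post)
  post <- exp(log_post) / sum(exp(log_post))

  labels <- character(0)
  score <- 0
  active <- rep(TRUE, length(post))
  for (r in seq_len(7L)) {
    lab <- model$rank_labels[, r]
    mass <- tapply(post[active], lab[active], sum)
    winner <- names(mass)[which.max(mass)]
    conf <- max(mass)
    if (winner == "" || conf < params$confidence) break
    labels <- c(labels, winner)
    score <- conf
    active <- active & lab == winner
  }
  if (length(labels) == 0L)
    return(new_classification(names(query), unassigned, 0, "naive_bayes"))
  new_classification(names(query), new_lineage(labels, model$dialect),
                     score, "naive_bayes")
}
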