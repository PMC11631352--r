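#' Reference database of sequences with taxonomy
#'
#' A `reference_db` couples uppercase IUPAC DNA sequences with parsed lineages
#' in a single dialect, and tracks provenance: `"base"` for entries of the
#' original release, `"added"` for organelle sequences merged in by
#' [extend_reference()].
#'
#' @param seqs named character vector of sequences (names are ids) or a data
#'   frame with `id` and `seq` columns as returned by [read_fasta()].
#' @param lineages named list of `lineage` objects, or a named character vector
#'   of raw lineage strings to parse (keyed by id).
#' @param dialect `"silva"` or `"greengenes"`.
#' @param provenance optional named character vector (`"base"`/`"added"`);
#'   defaults to all `"base"`.
#' @return A `reference_db` object with fields `seqs`, `lineages`,
#'   `provenance`, `dialect`.
#' @export
reference_db <- function(seqs, lineages, dialect, provenance = NULL) {
  check_dialect(dialect)
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$id)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named by id")
  if (anyDuplicated(names(seqs)))
    stop("duplicate ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- setNames(chartr("U", "T", toupper(seqs)), names(seqs))
  if (is.character(lineages))
    lineages <- lapply(lineages, parse_lineage, dialect = dialect)
  if (!setequal(names(lineages), names(seqs)))
    stop("sequence ids and taxonomy ids differ: ",
         paste(head(c(setdiff(names(seqs), names(lineages)),
                      setdiff(names(lineages), names(seqs))), 5), collapse = ", "))
  lineages <- lineages[names(seqs)]
  ok <- vapply(lineages, function(l)
    inherits(l, "lineage") && identical(l$dialect, dialect), logical(1))
  if (!all(ok)) stop("all lineages must share the db dialect (", dialect, ")")
  if (is.null(provenance)) provenance <- setNames(rep("base", length(seqs)), names(seqs))
  if (!setequal(names(provenance), names(seqs)) ||
      !all(provenance %in% c("base", "added")))
    stop("provenance must map every id to \"base\" or \"added\"")
  structure(list(seqs = seqs, lineages = lineages,
                 provenance = provenance[names(seqs)], dialect = dialect),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  n_mito <- sum(vapply(x$lineages, `[[`, logical(1), "is_mitochondrion"))
  n_chlo <- sum(vapply(x$lineages, `[[`, logical(1), "is_chloroplast"))
  cat("<reference_db> ", length(x$seqs), " entries [", x$dialect, "]; ",
      sum(x$provenance == "added"), " added; ",
      n_mito, " mitochondrial, ", n_chlo, " chloroplast\n", sep = "")
  invisible(x)
}

#' @export
length.reference_db <- function(x) length(x$seqs)

db_taxonomy_strings <- function(db) {
  vapply(db$lineages, format_lineage, character(1))
}

#' Merge organelle sequences into a base reference
#'
#' Each organelle record is amplicon-extracted with `primers` (records where no
#' amplicon is found are skipped and counted), assigned the dialect-specific
#' organelle lineage (with host genus/species appended when `host_labels`
#' provides them), and inserted with provenance `"added"`. A record whose
#' extracted sequence and lineage both match an existing entry is skipped; an
#' id collision with a different sequence keeps the record under a suffixed id
#' (`"<id>.dupN"`) with a warning. Base entries are never modified.
#'
#' @param base a `reference_db`.
#' @param organelle data frame of organelle records (`id`, `seq`), full-length
#'   or pre-trimmed (still flanked by primer sites).
#' @param kind `"mitochondria"` or `"chloroplast"`.
#' @param primers a [primer_pair()].
#' @param host_labels optional named list/vector: id -> c(genus, species).
#' @param trunc_len optional fixed length: amplicons are truncated from their
#'   5' end to `trunc_len` and shorter amplicons discarded (mirrors pipelines
#'   that trim reads to 100 nt). Default off.
#' @return A new `reference_db`; the input is unchanged. The summary counts
#'   (`n_in`, `n_extracted`, `n_added`, `n_skipped`) are attached as attribute
#'   `summary` and logged via `message()`.
#' @export
extend_reference <- function(base, organelle, kind, primers = primer_pair(),
                             host_labels = NULL, trunc_len = NULL) {
  stopifnot(inherits(base, "reference_db"))
  kind <- match.arg(kind, c("mitochondria", "chloroplast"))
  if (is.data.frame(organelle)) {
    org_ids <- organelle$id
    org_seqs <- setNames(toupper(organelle$seq), org_ids)
  } else {
    org_seqs <- setNames(chartr("U", "T", toupper(organelle)), names(organelle))
    org_ids <- names(org_seqs)
  }
  n_in <- length(org_seqs)
  seqs <- base$seqs
  lineages <- base$lineages
  provenance <- base$provenance
  existing_tax <- vapply(lineages, format_lineage, character(1))
  n_extracted <- 0L
  n_added <- 0L
  n_skipped <- 0L
  for (id in org_ids) {
    amp <- extract_amplicon(setNames(org_seqs[[id]], id), primers)
    if (is.null(amp)) next
    seq <- unname(amp)
    if (!is.null(trunc_len)) {
      if (nchar(seq) < trunc_len) next
      seq <- substr(seq, 1L, trunc_len)
    }
    n_extracted <- n_extracted + 1L
    host <- if (!is.null(host_labels)) host_labels[[id]] else NULL
    lin <- organelle_lineage(kind, base$dialect, host = host)
    tax <- format_lineage(lin)
    # content duplicate: identical sequence AND lineage already present
    same_seq <- names(seqs)[seqs == seq]
    if (length(same_seq) > 0 && any(existing_tax[same_seq] == tax)) {
      n_skipped <- n_skipped + 1L
      next
    }
    new_id <- id
    if (new_id %in% names(seqs)) {
      n <- 1L
      while (paste0(id, ".dup", n) %in% names(seqs)) n <- n + 1L
      new_id <- paste0(id, ".dup", n)
      warning("id collision for \"", id, "\": added as \"", new_id, "\"")
    }
    seqs[[new_id]] <- seq
    lineages[[new_id]] <- lin
    provenance[[new_id]] <- "added"
    existing_tax[[new_id]] <- tax
    n_added <- n_added + 1L
  }
  out <- reference_db(seqs, lineages, base$dialect, provenance)
  summary <- c(n_in = n_in, n_extracted = n_extracted,
               n_added = n_added, n_skipped = n_skipped)
  message(sprintf(
    "extend_reference [%s]: %d in, %d extracted, %d added, %d skipped as duplicates",
    kind, n_in, n_extracted, n_added, n_skipped))
  attr(out, "summary") <- summary
  out
}

#' Write a reference database to FASTA + taxonomy TSV
#'
#' Writes `<prefix>.fasta` (80-column bodies, provenance recorded in the
#' header description) and `<prefix>.tax.tsv` (two columns, no header, first
#' line the sidecar comment `#dialect=<d>`), entries in lexicographic id order
#' so output is deterministic. [read_reference()] reconstructs the database
#' exactly.
#'
#' @param db a `reference_db`.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_reference <- function(db, prefix) {
  stopifnot(inherits(db, "reference_db"))
  ids <- sort(names(db$seqs), method = "radix")
  fa <- paste0(prefix, ".fasta")
  tax <- paste0(prefix, ".tax.tsv")
  desc <- if (length(ids)) paste0("provenance=", unname(db$provenance[ids]))
          else character(0)
  write_fasta(data.frame(id = ids, seq = unname(db$seqs[ids]), desc = desc,
                         stringsAsFactors = FALSE), fa)
  con <- file(tax, "w")
  on.exit(close(con))
  writeLines(paste0("#dialect=", db$dialect), con)
  if (length(ids) > 0) {
    strings <- vapply(db$lineages[ids], format_lineage, character(1))
    writeLines(paste(ids, strings, sep = "\t"), con)
  }
  invisible(c(fasta = fa, taxonomy = tax))
}

#' Read a reference database written by [write_reference()]
#' @param prefix path prefix used at write time.
#' @param dialect override for the dialect when no `#dialect=` sidecar comment
#'   is present (e.g. taxonomy files from other tools).
#' @return a `reference_db`.
#' @export
read_reference <- function(prefix, dialect = NULL) {
  seqs <- read_fasta(paste0(prefix, ".fasta"))
  tax <- read_taxonomy_table(paste0(prefix, ".tax.tsv"))
  dialect <- dialect %||% attr(tax, "dialect")
  if (is.null(dialect))
    stop("no #dialect= sidecar comment found; pass dialect= explicitly")
  prov <- ifelse(grepl("provenance=added", seqs$desc, fixed = TRUE),
                 "added", "base")
  missing <- setdiff(seqs$id, names(tax))
  if (length(missing) > 0)
    stop("ids present in FASTA but absent from taxonomy: ",
         paste(head(missing, 5), collapse = ", "))
  reference_db(setNames(seqs$seq, seqs$id),
               lapply(as.list(tax)[seqs$id], parse_lineage, dialect = dialect),
               dialect,
               setNames(prov, seqs$id))
}
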