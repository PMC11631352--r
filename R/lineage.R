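#' @name lineage
#' @title Taxonomic lineages in SILVA or Greengenes dialect
#'
#' @description
#' A lineage is an ordered vector of seven rank labels (domain, phylum, class,
#' order, family, genus, species), possibly empty from some rank downwards
#' (no gaps mid-lineage). Two string dialects are supported: `silva`
#' (`d__` domain prefix) and `greengenes` (`k__` kingdom prefix). Organelle
#' status is derived, never stored in the input: a lineage is mitochondrial iff
#' some rank label equals "Mitochondria" case-insensitively, chloroplastic iff
#' some label equals "Chloroplast" case-insensitively.
#'
#' The all-empty lineage formats as the literal sentinel `"Unassigned"`, the
#' label the wrapped annotation pipelines emit for domain-level failures.
NULL

RANK_NAMES <- c("domain", "phylum", "class", "order", "family", "genus", "species")

rank_prefixes <- function(dialect) {
  first <- if (dialect == "silva") "d__" else "k__"
  c(first, "p__", "c__", "o__", "f__", "g__", "s__")
}

check_dialect <- function(dialect) {
  if (!is.character(dialect) || length(dialect) != 1L ||
      !dialect %in% c("silva", "greengenes"))
    stop("dialect must be \"silva\" or \"greengenes\"")
  dialect
}

new_lineage <- function(labels, dialect) {
  labels <- as.character(labels)
  length(labels) <- 7L
  labels[is.na(labels)] <- ""
  names(labels) <- RANK_NAMES
  # enforce no gaps: once empty, all deeper ranks empty
  empty <- which(labels == "")
  if (length(empty) > 0 && any(labels[seq(min(empty), 7L)] != ""))
    stop("lineage has a gap: empty rank followed by a non-empty rank")
  is_mito <- any(tolower(labels) == "mitochondria")
  is_chlo <- any(tolower(labels) == "chloroplast")
  if (is_mito && is_chlo)
    stop("lineage flagged as both mitochondrial and chloroplast")
  structure(list(ranks = labels, dialect = dialect,
                 is_mitochondrion = is_mito, is_chloroplast = is_chlo),
            class = "lineage")
}

#' Parse a lineage string
#'
#' @param raw semicolon-separated lineage string with rank prefixes
#'   (`d__`/`k__`, `p__`, ..., `s__`); whitespace around separators is
#'   tolerated. The literal `"Unassigned"` (any case) parses to a lineage whose
#'   domain slot holds that sentinel.
#' @param dialect `"silva"` or `"greengenes"`.
#' @return A `lineage` object: `$ranks` (named character of 7), `$dialect`,
#'   `$is_mitochondrion`, `$is_chloroplast`.
#' @examples
#' parse_lineage("k__Bacteria; p__Cyanobacteria; c__Chloroplast", "greengenes")
#' @export
parse_lineage <- function(raw, dialect) {
  check_dialect(dialect)
  if (!is.character(raw) || length(raw) != 1L) stop("raw must be a single string")
  raw <- trimws(raw)
  if (raw == "" ) return(new_lineage(character(0), dialect))
  if (tolower(raw) == "unassigned")
    return(new_lineage("Unassigned", dialect))
  fields <- trimws(strsplit(raw, ";", fixed = TRUE)[[1]])
  # trailing ";" produces an empty final field; drop trailing empties
  while (length(fields) > 0 && fields[length(fields)] == "")
    fields <- fields[-length(fields)]
  if (length(fields) > 7L)
    stop("more than 7 rank fields in lineage: ", raw)
  prefixes <- rank_prefixes(dialect)
  labels <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[i]
    if (!startsWith(f, prefixes[i]))
      stop("unknown rank prefix at position ", i, ": \"", f,
           "\" (expected \"", prefixes[i], "\")")
    labels[i] <- trimws(substring(f, nchar(prefixes[i]) + 1L))
  }
  # empty prefixed slots ("g__") become empty labels; strip any that leave gaps
  new_lineage(labels, dialect)
}

#' Format a lineage as a dialect string
#'
#' Greengenes dialect emits trailing empty ranks as bare prefixes
#' (`"g__; s__"`); SILVA dialect omits them. The all-empty lineage formats as
#' `"Unassigned"`; `format_lineage(parse_lineage(x, d), d)` is the identity on
#' canonical strings.
#'
#' @param lin a `lineage`.
#' @param dialect target dialect; defaults to the lineage's own.
#' @return a single string.
#' @export
format_lineage <- function(lin, dialect = lin$dialect) {
  stopifnot(inherits(lin, "lineage"))
  check_dialect(dialect)
  labels <- lin$ranks
  if (all(labels == "") || tolower(labels[["domain"]]) == "unassigned")
    return("Unassigned")
  prefixes <- rank_prefixes(dialect)
  if (dialect == "silva") {
    keep <- seq_len(max(which(labels != "")))
    paste0(prefixes[keep], labels[keep], collapse = "; ")
  } else {
    paste0(prefixes, labels, collapse = "; ")
  }
}

#' @export
print.lineage <- function(x, ...) {
  cat("<lineage [", x$dialect, "]> ", format_lineage(x), "\n", sep = "")
  if (x$is_mitochondrion) cat("  flagged: mitochondrion\n")
  if (x$is_chloroplast) cat("  flagged: chloroplast\n")
  invisible(x)
}

#' Is a lineage unassigned at domain level?
#'
#' TRUE for the all-empty lineage and for the `"Unassigned"` sentinel. Lineages
#' resolved to any real domain (even with nothing deeper) are not unknown.
#' @param lin a `lineage`.
#' @export
is_unassigned <- function(lin) {
  stopifnot(inherits(lin, "lineage"))
  lin$ranks[["domain"]] == "" || tolower(lin$ranks[["domain"]]) == "unassigned"
}

# Truncate a lineage to its first `depth` ranks (0 = all-empty/Unassigned).
truncate_lineage <- function(lin, depth) {
  labels <- lin$ranks
  if (depth < 7L) labels[seq.int(depth + 1L, 7L)] <- ""
  new_lineage(labels, lin$dialect)
}

# Dialect-specific lineage under which added organelle records are filed,
# mirroring where each base release already places organelles. Host genus and
# species, when known, are appended at the two deepest remaining ranks.
organelle_lineage <- function(kind, dialect, host = NULL) {
  kind <- match.arg(kind, c("mitochondria", "chloroplast"))
  check_dialect(dialect)
  labels <- if (kind == "mitochondria") {
    if (dialect == "silva")
      c("Bacteria", "Proteobacteria", "Alphaproteobacteria", "Rickettsiales",
        "Mitochondria")
    else
      c("Bacteria", "Proteobacteria", "Alphaproteobacteria", "Rickettsiales",
        "mitochondria")
  } else {
    if (dialect == "silva")
      c("Bacteria", "Cyanobacteria", "Cyanobacteriia", "Chloroplast")
    else
      c("Bacteria", "Cyanobacteria", "Chloroplast")
  }
  if (!is.null(host)) {
    # host genus/species fill the next available ranks (no mid-lineage gaps)
    host <- as.character(host)
    host <- host[nzchar(host)]
    labels <- head(c(labels, host), 7L)
  }
  new_lineage(labels, dialect)
}
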