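#' Read a FASTA file
#'
#' Wraps `Biostrings::readBStringSet` with the validation the rest of the
#' toolkit relies on: ids must be unique, sequences are uppercased, RNA `U` is
#' mapped to `T`, and a sequence line before the first `>` header is a parse
#' error naming the offending line.
#'
#' @param path FASTA file.
#' @return A data frame with columns `id` (first whitespace-delimited token of
#'   the header), `seq` (uppercase IUPAC DNA), `desc` (remainder of the
#'   header, possibly empty). Zero rows for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      desc = character(0), stringsAsFactors = FALSE))
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA: sequence data before first '>' header at line ",
         nonblank[1], " of ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop("duplicate sequence ids in ", path, ": ", paste(dups, collapse = ", "))
  }
  seqs <- chartr("u", "U", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTMRWSYKVHDBN]", seqs)
  if (any(bad))
    stop("non-IUPAC DNA characters in sequences: ",
         paste(ids[bad][seq_len(min(5, sum(bad)))], collapse = ", "))
  data.frame(id = unname(ids), seq = unname(seqs), desc = unname(desc),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs data frame with `id`, `seq` and optionally `desc` columns.
#' @param path output file.
#' @param width line width for sequence bodies (default 80).
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  set <- Biostrings::BStringSet(seqs$seq)
  desc <- if ("desc" %in% names(seqs)) seqs$desc else rep("", nrow(seqs))
  names(set) <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Read a two-column taxonomy table
#'
#' Tab-separated feature id / lineage string pairs, as emitted by common
#' amplicon pipelines. An optional header row whose first cell starts with
#' `"Feature ID"` or `"#"` is skipped; `#dialect=` comment lines are exposed as
#' an attribute. Later columns (e.g. confidence) are ignored.
#'
#' @param path TSV file.
#' @return Named character vector of raw lineage strings keyed by feature id,
#'   with attribute `dialect` if a `#dialect=` comment was present.
#' @export
read_taxonomy_table <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  dialect <- NULL
  dl <- grep("^#dialect=", lines, value = TRUE)
  if (length(dl) > 0) dialect <- sub("^#dialect=", "", dl[1])
  keep <- !grepl("^#", lines) & trimws(lines) != ""
  lines <- lines[keep]
  rows <- which(keep)
  if (length(lines) > 0 &&
      grepl("^(Feature ID|feature id|Feature id)", lines[1])) {
    lines <- lines[-1]; rows <- rows[-1]
  }
  if (length(lines) == 0L) {
    out <- character(0)
    attr(out, "dialect") <- dialect
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 2L))
    stop("taxonomy row with fewer than 2 columns at line ",
         rows[which(ncols < 2L)[1]], " of ", path)
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  tax <- trimws(vapply(parts, `[[`, "", 2L))
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- setNames(tax, ids)
  attr(out, "dialect") <- dialect
  out
}

#' Read a feature table (features x samples TSV)
#'
#' First header cell is `#OTU ID` (or any first column of feature ids);
#' remaining columns are sample ids with integer counts.
#'
#' @param path TSV file.
#' @return Integer matrix, rownames = feature ids, colnames = sample ids.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) < 1L) stop("empty feature table: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  body <- lapply(lines[-1], function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  ids <- vapply(body, `[[`, "", 1L)
  counts <- t(vapply(body, function(p) as.numeric(p[-1]),
                     numeric(length(samples))))
  if (length(samples) == 1L) counts <- matrix(counts, ncol = 1L)
  validate_feature_table(matrix(as.integer(round(counts)),
                                nrow = length(ids),
                                dimnames = list(ids, samples)))
}

#' Write a feature table TSV
#' @param table integer matrix (features x samples).
#' @param path output file.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#OTU ID", colnames(table)), collapse = "\t"), con)
  if (nrow(table) > 0) {
    body <- apply(cbind(rownames(table), table), 1L, paste, collapse = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

validate_feature_table <- function(table) {
  if (!is.matrix(table)) stop("feature table must be a matrix")
  if (is.null(rownames(table)) || is.null(colnames(table)))
    stop("feature table needs feature ids (rownames) and sample ids (colnames)")
  if (ncol(table) < 1L) stop("feature table needs at least one sample")
  if (anyDuplicated(rownames(table))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(table))) stop("duplicate sample ids")
  if (any(table < 0)) stop("negative counts in feature table")
  storage.mode(table) <- "integer"
  table
}

#' Read sample metadata TSV (`#SampleID` first column)
#' @param path TSV file.
#' @return data frame with column `sample_id` plus the metadata columns.
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(md)[1] <- "sample_id"
  md
}
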