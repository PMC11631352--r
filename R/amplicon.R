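IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"), D = c("A", "G", "T"),
  B = c("C", "G", "T"), N = c("A", "C", "G", "T"))

#' Reverse complement (IUPAC-aware)
#' @param seq DNA string(s).
#' @return reverse complement string(s), degenerate codes complemented too.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Degenerate PCR primer pair
#'
#' Defaults are the V4 primers as printed in Earth Microbiome Project-style
#' protocols: 515f `GTGTGCCAGCMGCCGCGGTAA` and 806r `GGACTACHVGGGTWTCTAAT`
#' (the reverse primer is given 5'->3' on the opposite strand, as
#' conventionally written).
#'
#' @param forward,reverse IUPAC degenerate primer strings (length >= 10).
#' @param min_amplicon_len,max_amplicon_len accepted inter-primer lengths.
#' @param max_mismatch mismatches tolerated per primer site (default 0:
#'   exact IUPAC-degenerate matching).
#' @return a `primer_pair` object.
#' @export
primer_pair <- function(forward = "GTGTGCCAGCMGCCGCGGTAA",
                        reverse = "GGACTACHVGGGTWTCTAAT",
                        min_amplicon_len = 100L, max_amplicon_len = 500L,
                        max_mismatch = 0L) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (nchar(forward) < 10L || nchar(reverse) < 10L)
    stop("primers must be at least 10 nt")
  if (!(min_amplicon_len < max_amplicon_len))
    stop("min_amplicon_len must be < max_amplicon_len")
  if (max_mismatch < 0L) stop("max_mismatch must be non-negative")
  structure(list(forward = forward, reverse = reverse,
                 min_amplicon_len = as.integer(min_amplicon_len),
                 max_amplicon_len = as.integer(max_amplicon_len),
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_pair")
}

# All IUPAC-degenerate matches of `primer` in `seq` (start positions),
# tolerating `max_mismatch` mismatching positions.
match_primer <- function(primer, seq, max_mismatch = 0L) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(primer),
                                Biostrings::DNAString(seq),
                                max.mismatch = max_mismatch, fixed = FALSE)
  IRanges::start(m)
}

#' Extract the amplified region from a sequence
#'
#' Deterministic in-silico PCR: the forward primer is located (IUPAC-degenerate
#' match, `max_mismatch` tolerated) on either strand; on the primer-bearing
#' strand the reverse-complement of the reverse primer is sought downstream of
#' the leftmost forward site, and the nearest site giving an inter-primer
#' length within `[min_amplicon_len, max_amplicon_len]` is chosen. The
#' inter-primer subsequence (primers excluded) is returned, on the
#' primer-bearing strand. Absence of a hit is a `NULL` return, not an error.
#'
#' @param rec a single named sequence (named character of length 1) or a
#'   one-row data frame with `id` and `seq`.
#' @param primers a [primer_pair()].
#' @return named character of length 1 (name = input id), or `NULL`.
#' @export
extract_amplicon <- function(rec, primers = primer_pair()) {
  if (is.data.frame(rec)) rec <- setNames(rec$seq, rec$id)
  stopifnot(length(rec) == 1L, !is.null(names(rec)))
  id <- names(rec)
  rrc <- revcomp(primers$reverse)
  flen <- nchar(primers$forward)
  for (seq in c(toupper(unname(rec)), revcomp(toupper(unname(rec))))) {
    fhits <- match_primer(primers$forward, seq, primers$max_mismatch)
    if (length(fhits) == 0L) next
    fstart <- fhits[1]                       # leftmost forward site
    amp_from <- fstart + flen
    rhits <- match_primer(rrc, seq, primers$max_mismatch)
    rhits <- rhits[rhits >= amp_from]        # downstream reverse sites
    if (length(rhits) == 0L) next
    lens <- rhits - amp_from                 # inter-primer lengths
    ok <- lens >= primers$min_amplicon_len & lens <= primers$max_amplicon_len
    if (!any(ok)) next
    rstart <- rhits[ok][1]                   # nearest in-bounds site
    return(setNames(substr(seq, amp_from, rstart - 1L), id))
  }
  NULL
}
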