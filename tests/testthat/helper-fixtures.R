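# Shared fixtures, all built in code.

# Toy primers for deterministic in-silico PCR tests (spec-sized: >= 10 nt).
toy_primers <- function(min_len = 4L, max_len = 100L, max_mismatch = 0L) {
  primer_pair("ACGTACGTAC", "TTGGCCAATT", min_len, max_len, max_mismatch)
}

# Wrap a core sequence in the toy primer sites so extract_amplicon finds it.
wrap_in_primers <- function(core, primers = toy_primers(),
                            flank5 = "AAAA", flank3 = "TTTT") {
  paste0(flank5, primers$forward, core, revcomp(primers$reverse), flank3)
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Small bacterial reference: two genera in each of two phyla, one species each
# plus a third species in genus 1 for consensus tests.
tiny_db <- function(dialect = "silva", seq_len = 80L, seed = 101L) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    g1 <- random_dna_str(seq_len)
    g2 <- random_dna_str(seq_len)
    mut <- function(s, n) {
      chars <- strsplit(s, "")[[1]]
      pos <- sample(seq_along(chars), n)
      chars[pos] <- vapply(chars[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      paste(chars, collapse = "")
    }
    seqs <- c(a1 = g1, a2 = mut(g1, 2L), a3 = mut(g1, 3L), b1 = g2)
    pre <- if (dialect == "silva") "d__" else "k__"
    tax <- c(
      a1 = paste0(pre, "Bacteria; p__P1; c__C1; o__O1; f__F1; g__G1; s__S1"),
      a2 = paste0(pre, "Bacteria; p__P1; c__C1; o__O1; f__F1; g__G1; s__S2"),
      a3 = paste0(pre, "Bacteria; p__P1; c__C1; o__O1; f__F1; g__G2; s__S3"),
      b1 = paste0(pre, "Bacteria; p__P2; c__C2; o__O2; f__F2; g__G3; s__S4"))
    reference_db(seqs, tax, dialect)
  })
}

# A random canonical lineage of random depth (labels never empty mid-lineage).
random_lineage_string <- function(dialect) {
  depth <- sample.int(7L, 1L)
  labels <- replicate(depth, paste0("X", paste(sample(letters, 5, TRUE),
                                               collapse = "")))
  format_lineage(new_lineage_for_test(labels, dialect), dialect)
}

new_lineage_for_test <- function(labels, dialect) {
  parse_lineage(paste0(rank_prefixes_for_test(dialect)[seq_along(labels)],
                       labels, collapse = "; "), dialect)
}

rank_prefixes_for_test <- function(dialect) {
  c(if (dialect == "silva") "d__" else "k__",
    "p__", "c__", "o__", "f__", "g__", "s__")
}

# Tiny simulation spec for fast unit tests.
tiny_spec <- function(...) {
  sim_spec(n_phyla = 2L, genera_per_phylum = 2L, species_per_genus = 2L,
           seq_len = 150L, organelle_pool_size = 4L,
           n_samples_per_group = 3L, reads_per_sample = 60L,
           sequencing_error_rate = 0.002, seed = 7L, ...)
}

# Assignment table from explicit lineage strings (audit-module fixtures).
assignments_from_strings <- function(ids, strings, dialect = "silva",
                                     method = "consensus") {
  assignment_table(Map(function(id, s)
    organaudit:::new_classification(id, parse_lineage(s, dialect), 1, method),
    ids, strings))
}
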