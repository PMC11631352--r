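test_that("semiglobal_align computes identity and coverage as defined", {
  set.seed(21)
  a <- random_dna_str(100)
  res <- semiglobal_align(a, a)
  expect_equal(res$identity, 1.0)
  expect_equal(res$coverage, 1.0)
  expect_equal(res$score, 100)

  # exact substring: free terminal gaps give identity 1, coverage 1
  sub <- substr(a, 26, 75)
  res <- semiglobal_align(sub, a)
  expect_equal(res$identity, 1.0)
  expect_equal(res$coverage, 1.0)

  # one substitution in 100, no indels
  b <- a
  substr(b, 40, 40) <- setdiff(c("A", "C", "G", "T"), substr(a, 40, 40))[1]
  expect_equal(semiglobal_align(a, b, mode = "query_global")$identity, 0.99)

  # IUPAC set intersection counts as a match
  expect_equal(semiglobal_align("ACGTA", "ACGTM")$identity, 1.0)
  expect_equal(semiglobal_align("ACGTG", "ACGTM")$identity, 0.8)

  expect_error(semiglobal_align("", "ACGT"), "empty")
})

test_that("alignment scores match the Biostrings dynamic-programming oracle", {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = TRUE)
  oracle <- function(a, b, type) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = type,
      gapOpening = 0, gapExtension = 2, substitutionMatrix = sm,
      scoreOnly = TRUE)
  }
  set.seed(22)
  for (i in 1:25) {
    a <- random_dna_str(sample(30:150, 1))
    b <- random_dna_str(sample(30:150, 1))
    expect_equal(semiglobal_align(a, b, mode = "overlap")$score,
                 oracle(a, b, "overlap"))
    expect_equal(semiglobal_align(a, b, mode = "query_global")$score,
                 oracle(a, b, "global-local"))
  }
})

test_that("search_reference ranks, thresholds, and tie-breaks hits", {
  db <- tiny_db()
  q <- setNames(db$seqs[["a1"]], "q")
  hits <- search_reference(q, db)
  expect_equal(hits$ref_id[1], "a1")
  expect_equal(hits$identity[1], 1.0)

  empty <- reference_db(setNames(character(0), character(0)), list(), "silva")
  expect_equal(nrow(search_reference(q, empty)), 0L)

  # two refs with equal identity are ordered by ref id ascending
  dup <- reference_db(c(z9 = db$seqs[["a1"]], a0 = db$seqs[["a1"]]),
                      c(z9 = "d__Bacteria", a0 = "d__Bacteria"), "silva")
  hits <- search_reference(q, dup)
  expect_equal(hits$ref_id, c("a0", "z9"))

  # maxaccepts truncation
  p1 <- classify_params(maxaccepts = 1)
  expect_equal(nrow(search_reference(q, db, p1)), 1L)
})

test_that("prefiltered search equals exhaustive alignment on small dbs", {
  set.seed(23)
  seqs <- setNames(vapply(1:50, function(i) random_dna_str(120), ""),
                   sprintf("r%02d", 1:50))
  # make some refs similar to the query so hits pass the identity cutoff
  q <- setNames(seqs[["r10"]], "q")
  for (id in c("r20", "r30")) {
    s <- seqs[[id]]
    x <- unname(q); substr(x, 5, 9) <- substr(s, 5, 9)
    seqs[[id]] <- x
  }
  db <- reference_db(seqs, setNames(
    sprintf("d__Bacteria; p__P%d", seq_along(seqs)), names(seqs)), "silva")
  params <- classify_params(maxaccepts = 50)

  hits <- search_reference(q, db, params)
  # independent exhaustive route: align against every reference, same ordering
  aln <- organaudit:::align_batch(unname(q), unname(seqs),
                                  mode = "query_global")
  exhaustive <- data.frame(ref_id = names(seqs), identity = aln$identity)
  exhaustive <- exhaustive[order(-exhaustive$identity, exhaustive$ref_id,
                                 method = "radix"), ]
  exhaustive <- exhaustive[exhaustive$identity >= params$perc_identity, ]
  expect_equal(hits$ref_id, exhaustive$ref_id)
  expect_equal(hits$identity, exhaustive$identity)
})

test_that("classify_consensus keeps ranks by plurality consensus", {
  db <- tiny_db()
  params <- classify_params()

  # verbatim query with maxaccepts = 1 returns exactly that entry's lineage
  q <- setNames(db$seqs[["b1"]], "q")
  cls <- classify_consensus(q, db, classify_params(maxaccepts = 1))
  expect_identical(format_lineage(cls$lineage),
                   format_lineage(db$lineages[["b1"]]))
  expect_equal(cls$score, 1.0)

  # two accepted hits agreeing through family, split at genus: the genus
  # fraction is 1/2 < 0.51, so the lineage truncates after family
  two <- reference_db(
    c(h1 = db$seqs[["a1"]], h2 = db$seqs[["a1"]]),
    c(h1 = "d__B; p__P; c__C; o__O; f__F; g__G1; s__S1",
      h2 = "d__B; p__P; c__C; o__O; f__F; g__G2; s__S2"), "silva")
  cls <- classify_consensus(setNames(db$seqs[["a1"]], "q"), two, params)
  expect_identical(format_lineage(cls$lineage), "d__B; p__P; c__C; o__O; f__F")
  expect_equal(cls$score, 1.0)   # consensus fraction at family

  # no hit reaches perc_identity -> Unassigned with score 0
  far <- setNames(random_dna_str(80), "far")
  cls <- classify_consensus(far, db, params)
  expect_true(is_unassigned(cls$lineage))
  expect_equal(cls$score, 0)

  # determinism
  c1 <- classify_consensus(q, db, params)
  c2 <- classify_consensus(q, db, params)
  expect_identical(format_lineage(c1$lineage), format_lineage(c2$lineage))
  expect_identical(c1$score, c2$score)
})

test_that("raising min_consensus never deepens the consensus lineage", {
  db <- tiny_db()
  depth_of <- function(cls) sum(cls$lineage$ranks != "")
  for (id in names(db$seqs)) {
    q <- setNames(db$seqs[[id]], "q")
    prev <- 8L
    for (mc in c(0.3, 0.51, 0.7, 0.9, 1.0)) {
      d <- depth_of(classify_consensus(q, db, classify_params(min_consensus = mc)))
      expect_lte(d, prev)
      prev <- d
    }
  }
})

test_that("positive_filter applies inclusive identity and coverage bounds", {
  set.seed(24)
  screen <- setNames(c(random_dna_str(100), random_dna_str(100)),
                     c("s1", "s2"))

  # identical query is kept
  res <- positive_filter(setNames(screen[["s1"]], "q"), screen)
  expect_true(res$keep[["q"]])

  # exactly 35 evenly spread interior mismatches: identity 0.65, kept
  # (boundary inclusive); 36 mismatches: identity 0.64 < 0.65, discarded
  make_mm <- function(n_mm) {
    x <- screen[["s1"]]
    pos <- round(seq(3, 97, length.out = n_mm))
    for (p in pos)
      substr(x, p, p) <- setdiff(c("A", "C", "G", "T"), substr(x, p, p))[1]
    x
  }
  q65 <- setNames(make_mm(35), "q65")
  q64 <- setNames(make_mm(36), "q64")
  res <- positive_filter(c(q65, q64), screen["s1"])
  aln65 <- semiglobal_align(unname(q65), screen[["s1"]])
  expect_equal(aln65$identity, 0.65)
  expect_equal(aln65$coverage, 1.0)
  expect_true(res$keep[["q65"]])
  expect_false(res$keep[["q64"]])

  # high identity on a short overlap fails the coverage threshold: a 40-nt
  # reference bounds the aligned query span at 40/100 = 0.4 < 0.5
  short_ref <- setNames(substr(screen[["s1"]], 1, 40), "short")
  frag <- setNames(paste0(short_ref, random_dna_str(60)), "frag")
  aln <- semiglobal_align(unname(frag), unname(short_ref))
  expect_equal(aln$identity, 1.0)
  expect_lte(aln$coverage, 0.45)
  expect_false(positive_filter(frag, short_ref)$keep[["frag"]])

  # partition preserves input order
  qs <- c(setNames(screen[["s2"]], "z"), q64, setNames(screen[["s1"]], "a"))
  res <- positive_filter(qs, screen)
  expect_identical(res$kept$id, c("z", "a"))
  expect_identical(res$discarded$id, "q64")

  expect_error(positive_filter(qs, character(0)), "non-empty")
})
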