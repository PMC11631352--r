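test_that("read_fasta parses records, wraps, and validates", {
  f <- withr::local_tempfile(fileext = ".fasta")

  writeLines(c(">a", "ACGT"), f)
  out <- read_fasta(f)
  expect_equal(out$id, "a")
  expect_equal(out$seq, "ACGT")

  writeLines(c(">a", "AC", "GT", ">b desc here", "tttt"), f)
  out <- read_fasta(f)
  expect_equal(out$seq, c("ACGT", "TTTT"))   # wrapped lines concatenated, uppercased
  expect_equal(out$desc, c("", "desc here"))

  writeLines(c(">u", "ACGU"), f)
  expect_equal(read_fasta(f)$seq, "ACGT")    # U -> T

  writeLines(character(0), f)
  expect_equal(nrow(read_fasta(f)), 0L)

  writeLines(c("ACGT", ">a", "ACGT"), f)
  expect_error(read_fasta(f), "line 1")

  writeLines(c(">a", "AC", ">a", "GT"), f)
  expect_error(read_fasta(f), "duplicate")
})

test_that("read_taxonomy_table handles headers, errors on bad rows", {
  f <- withr::local_tempfile(fileext = ".tsv")

  writeLines("f1\tk__Bacteria; p__Proteobacteria", f)
  out <- read_taxonomy_table(f)
  expect_equal(unname(out["f1"]), "k__Bacteria; p__Proteobacteria")

  writeLines(c("Feature ID\tTaxon", "f1\td__Bacteria\t0.99"), f)
  out <- read_taxonomy_table(f)
  expect_equal(length(out), 1L)              # header skipped, 3rd column ignored
  expect_equal(unname(out["f1"]), "d__Bacteria")

  writeLines(character(0), f)
  expect_equal(length(read_taxonomy_table(f)), 0L)

  writeLines(c("f1\td__Bacteria", "lonely"), f)
  expect_error(read_taxonomy_table(f), "line 2")

  writeLines(c("f1\tx", "f1\ty"), f)
  expect_error(read_taxonomy_table(f), "duplicate")

  writeLines(c("#dialect=greengenes", "f1\tk__Bacteria"), f)
  expect_equal(attr(read_taxonomy_table(f), "dialect"), "greengenes")
})

test_that("parse_lineage resolves dialects, organelle flags, sentinels", {
  l <- parse_lineage("k__Bacteria; p__Cyanobacteria; c__Chloroplast",
                     "greengenes")
  expect_equal(unname(l$ranks[["class"]]), "Chloroplast")
  expect_true(l$is_chloroplast)
  expect_false(l$is_mitochondrion)

  l <- parse_lineage(paste0("d__Bacteria;p__Proteobacteria;",
                            "c__Alphaproteobacteria;o__Rickettsiales;",
                            "f__Mitochondria"), "silva")
  expect_true(l$is_mitochondrion)
  expect_false(l$is_chloroplast)

  l <- parse_lineage("Unassigned", "silva")
  expect_equal(unname(l$ranks[["domain"]]), "Unassigned")
  expect_true(all(l$ranks[-1] == ""))
  expect_false(l$is_mitochondrion || l$is_chloroplast)
  expect_true(is_unassigned(l))

  # empty prefixed slots become empty labels
  l <- parse_lineage("k__Bacteria; p__P; c__; o__; f__; g__; s__", "greengenes")
  expect_equal(sum(l$ranks != ""), 2L)

  expect_error(parse_lineage("q__Wat", "silva"), "prefix")
  expect_error(parse_lineage(paste(rep("d__x", 8), collapse = ";"), "silva"),
               "7 rank")
})

test_that("lineage formatting round-trips in both dialects", {
  # silva omits trailing empties; greengenes emits bare prefixes
  l <- parse_lineage("d__Bacteria; p__P1", "silva")
  expect_equal(format_lineage(l), "d__Bacteria; p__P1")
  l <- parse_lineage("k__Bacteria; p__P1", "greengenes")
  expect_equal(format_lineage(l),
               "k__Bacteria; p__P1; c__; o__; f__; g__; s__")
  expect_equal(format_lineage(parse_lineage("Unassigned", "silva")),
               "Unassigned")

  set.seed(42)
  for (i in 1:100) {
    for (d in c("silva", "greengenes")) {
      s <- random_lineage_string(d)
      expect_identical(format_lineage(parse_lineage(s, d), d), s)
    }
  }
})

test_that("extract_amplicon performs deterministic in-silico PCR", {
  pp <- toy_primers()
  core <- "CCCCGGGGCCCCGGGG"
  rec <- setNames(wrap_in_primers(core, pp), "x")
  expect_equal(unname(extract_amplicon(rec, pp)), core)
  expect_equal(names(extract_amplicon(rec, pp)), "x")

  # degenerate M matches A and C targets at that position
  pm <- primer_pair("ACGTACGTAM", "TTGGCCAATT", 4, 100)
  for (b in c("A", "C")) {
    rec2 <- setNames(paste0("ACGTACGTA", b, core, revcomp(pm$reverse)), "y")
    expect_equal(unname(extract_amplicon(rec2, pm)), core)
  }
  rec3 <- setNames(paste0("ACGTACGTAG", core, revcomp(pm$reverse)), "z")
  expect_null(extract_amplicon(rec3, pm))   # G not in M = {A, C}

  # forward site but no downstream reverse site -> none
  expect_null(extract_amplicon(setNames(paste0(pp$forward, core), "w"), pp))
  # amplicon out of bounds -> none
  expect_null(extract_amplicon(setNames(wrap_in_primers("CC", pp), "w"), pp))

  # reverse-complement strand: amplicon reported on the primer-bearing strand
  expect_equal(unname(extract_amplicon(setNames(revcomp(unname(rec)), "x"), pp)),
               core)
  # amplicon is a contiguous subsequence of the bearing strand, within bounds
  amp <- extract_amplicon(rec, pp)
  expect_true(grepl(amp, unname(rec), fixed = TRUE))
  expect_true(nchar(amp) >= pp$min_amplicon_len &&
              nchar(amp) <= pp$max_amplicon_len)
})

test_that("extend_reference adds organelles without touching the base", {
  db <- tiny_db()
  pp <- toy_primers()
  set.seed(5)
  cores <- replicate(3, random_dna_str(30))
  org <- data.frame(id = paste0("m", 1:3),
                    seq = vapply(cores, wrap_in_primers, "", primers = pp))

  ext <- suppressMessages(extend_reference(db, org, "mitochondria", pp))
  expect_equal(length(ext), length(db) + 3L)
  expect_equal(sum(ext$provenance == "added"), 3L)
  added <- names(ext$provenance)[ext$provenance == "added"]
  expect_true(all(vapply(ext$lineages[added], `[[`, logical(1),
                         "is_mitochondrion")))
  expect_match(format_lineage(ext$lineages[["m1"]]),
               "^d__Bacteria; p__Proteobacteria; c__Alphaproteobacteria; o__Rickettsiales; f__Mitochondria")
  s <- attr(ext, "summary")
  expect_equal(unname(s["n_added"]), unname(s["n_extracted"] - s["n_skipped"]))

  # base entries unchanged
  for (id in names(db$seqs)) {
    expect_identical(ext$seqs[[id]], db$seqs[[id]])
    expect_identical(format_lineage(ext$lineages[[id]]),
                     format_lineage(db$lineages[[id]]))
  }

  # idempotence: re-adding the same records skips them all
  ext2 <- suppressMessages(extend_reference(ext, org, "mitochondria", pp))
  expect_equal(length(ext2), length(ext))
  expect_equal(unname(attr(ext2, "summary")["n_skipped"]), 3L)

  # records that fail extraction are skipped and counted
  org_bad <- rbind(org, data.frame(id = "nosite", seq = random_dna_str(60)))
  ext3 <- suppressMessages(extend_reference(db, org_bad, "mitochondria", pp))
  expect_equal(unname(attr(ext3, "summary")["n_extracted"]), 3L)

  # id collision with a different sequence -> suffixed id + warning
  org_dup <- data.frame(id = "a1", seq = wrap_in_primers(random_dna_str(30), pp))
  expect_warning(
    ext4 <- suppressMessages(extend_reference(db, org_dup, "mitochondria", pp)),
    "a1\\.dup1")
  expect_true("a1.dup1" %in% names(ext4$seqs))

  # host labels appended below the organelle rank
  ext5 <- suppressMessages(extend_reference(
    db, org[1, ], "mitochondria", pp,
    host_labels = list(m1 = c("Acropora", "millepora"))))
  expect_match(format_lineage(ext5$lineages[["m1"]]),
               "g__Acropora; s__millepora$")

  # chloroplast kind gets the chloroplast lineage + flag
  ext6 <- suppressMessages(extend_reference(db, org[1, ], "chloroplast", pp))
  expect_true(ext6$lineages[["m1"]]$is_chloroplast)
})

test_that("write_reference / read_reference round-trips exactly", {
  db <- tiny_db()
  pp <- toy_primers()
  set.seed(6)
  org <- data.frame(id = "zz_m1",
                    seq = wrap_in_primers(random_dna_str(30), pp))
  db <- suppressMessages(extend_reference(db, org, "mitochondria", pp))

  prefix <- file.path(withr::local_tempdir(), "ref")
  write_reference(db, prefix)
  back <- read_reference(prefix)
  expect_equal(length(back), length(db))
  expect_identical(back$dialect, db$dialect)
  expect_identical(back$seqs[names(db$seqs)], db$seqs)
  expect_identical(vapply(back$lineages[names(db$seqs)], format_lineage, ""),
                   vapply(db$lineages, format_lineage, ""))
  expect_identical(back$provenance[names(db$seqs)], db$provenance)

  # deterministic lexicographic order on disk
  ids <- read_fasta(paste0(prefix, ".fasta"))$id
  expect_identical(ids, sort(ids, method = "radix"))

  # empty db -> empty fasta + dialect comment only
  empty <- reference_db(setNames(character(0), character(0)), list(), "silva")
  write_reference(empty, prefix)
  expect_equal(nrow(read_fasta(paste0(prefix, ".fasta"))), 0L)
  expect_identical(readLines(paste0(prefix, ".tax.tsv")), "#dialect=silva")
})
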