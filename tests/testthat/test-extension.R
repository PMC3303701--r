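# Homology extension: search backends, hit filtering, profile construction,
# keyword database filtering.

test_that("builtin backend finds the self-hit with identity/coverage 100", {
  q <- sequence_set(c(a = "MKTLIVFGAAGGWLPSTE"))
  h <- search_hits(q, builtin_database(q))
  expect_equal(nrow(h), 1)
  expect_equal(h$pident, 100)
  expect_equal(h$coverage, 100)
  expect_equal(h$qstart, 1)
  expect_equal(h$qend, 18)
})

test_that("builtin backend returns nothing for unrelated sequences / empty db", {
  q <- sequence_set(c(a = "MKTLIVFG"))
  other <- sequence_set(c(z = "DDDEEDDEDEDEDEDDEE"))
  expect_equal(nrow(search_hits(q, builtin_database(other), evalue_max = 1e-6)), 0)
  empty <- sequence_set(c(x = "A"))[0, , drop = FALSE]
  class(empty) <- c("tmc_sequences", "data.frame")
  expect_equal(nrow(search_hits(q, builtin_database(empty))), 0)
})

test_that("builtin identity matches a hand-counted toy alignment", {
  # identical 10-mers up to one substitution: ungapped local alignment,
  # identity = 9 identical / 10 columns
  q <- sequence_set(c(a = "MKTLIVFGWA"))
  s <- sequence_set(c(b = "MKTLCVFGWA"))
  h <- search_hits(q, builtin_database(s))
  expect_equal(h$pident, 90)
  expect_equal(h$length, 10)
  expect_equal(h$qseq, "MKTLIVFGWA")
  expect_equal(h$sseq, "MKTLCVFGWA")
})

test_that("builtin agrees with the Biostrings aligner on scores", {
  withr::local_seed(42)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  for (k in 1:10) {
    q <- paste0(sample(tmcoffee:::AA20, 40, replace = TRUE), collapse = "")
    s <- paste0(sample(tmcoffee:::AA20, 50, replace = TRUE), collapse = "")
    db <- builtin_database(sequence_set(c(sub = s)))
    h <- search_hits(sequence_set(c(qq = q)), db, evalue_max = Inf)
    ref <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 11, gapExtension = 1)
    got <- if (nrow(h) == 0) 0 else {
      # recompute the raw score from the reported alignment
      qa <- strsplit(h$qseq, "")[[1]]; sa <- strsplit(h$sseq, "")[[1]]
      sc <- 0; ing <- FALSE
      for (i in seq_along(qa)) {
        if (qa[[i]] == "-" || sa[[i]] == "-") {
          sc <- sc - 1 - (!ing) * 11; ing <- TRUE
        } else {
          sc <- sc + mat[qa[[i]], sa[[i]]]; ing <- FALSE
        }
      }
      sc
    }
    expect_equal(got, Biostrings::score(ref), tolerance = 1e-9)
  }
})

test_that("filter_hits applies inclusive identity and strict coverage bounds", {
  mk <- function(id, cov) {
    df <- data.frame(qid = "q", sid = "s", pident = id, length = 10L,
                     qstart = 1L, qend = 10L, sstart = 1L, send = 10L,
                     evalue = 1e-9, qseq = "AAAAAAAAAA", sseq = "AAAAAAAAAA")
    h <- hit_table(df)
    h$coverage <- cov
    h
  }
  expect_equal(nrow(filter_hits(mk(95, 80))), 0)     # above 90 cap
  expect_equal(nrow(filter_hits(mk(70, 70))), 0)     # coverage > 70 is strict
  expect_equal(nrow(filter_hits(mk(50, 80))), 1)     # bounds inclusive
  expect_equal(nrow(filter_hits(mk(90, 80))), 1)
  expect_error(filter_hits(mk(60, 80), id_min = 80, id_max = 50), "id_min")
  # evalue_max = NULL disables e-value filtering
  h <- mk(60, 80); h$evalue <- 5
  expect_equal(nrow(filter_hits(h, evalue_max = NULL)), 1)
  expect_equal(nrow(filter_hits(h, evalue_max = 1)), 0)
})

test_that("filtering is monotone in the e-value ceiling", {
  withr::local_seed(7)
  fam <- simulate_family(seed = 7, n = 4, target_identity = 0.5)
  db <- builtin_database(build_mini_database(list(fam), n_decoys = 3, seed = 8))
  q <- fam$members[1, , drop = FALSE]
  class(q) <- c("tmc_sequences", "data.frame")
  hits <- search_hits(q, db)
  prev <- character()
  for (e in c(1e-40, 1e-20, 1e-10, 1e-3, 10)) {
    kept <- filter_hits(hits, evalue_max = e)
    expect_true(all(prev %in% kept$sid))
    prev <- kept$sid
  }
})

test_that("build_profile reproduces the hand-worked ACDEF example", {
  q <- sequence_set(c(q1 = "ACDEF"))
  hit <- hit_table(data.frame(
    qid = "q1", sid = "h1", pident = 66.7, length = 3L,
    qstart = 2L, qend = 4L, sstart = 1L, send = 3L, evalue = 1e-5,
    qseq = "CDE", sseq = "CNE"), c(q1 = 5L))
  p <- build_profile(q, hit)
  expect_equal(ncol(p$freq), 5)
  expect_equal(unname(colSums(p$freq)), rep(1, 5), tolerance = 1e-12)
  # columns outside the span: query residue and the hit's gap, half each
  expect_equal(unname(p$freq["A", 1]), 0.5)
  expect_equal(unname(p$freq["-", 1]), 0.5)
  expect_equal(unname(p$freq["F", 5]), 0.5)
  expect_equal(unname(p$freq["-", 5]), 0.5)
  expect_equal(unname(p$freq["C", 2]), 1.0)
  expect_equal(unname(p$freq["D", 3]), 0.5)
  expect_equal(unname(p$freq["N", 3]), 0.5)
  expect_equal(unname(p$freq["E", 4]), 1.0)
  expect_equal(p$support, c(1L, 2L, 2L, 2L, 1L))
})

test_that("subject residues opposite query gaps are discarded", {
  q <- sequence_set(c(q1 = "AC"))
  hit <- hit_table(data.frame(
    qid = "q1", sid = "h1", pident = 66.7, length = 3L,
    qstart = 1L, qend = 2L, sstart = 1L, send = 3L, evalue = 1e-5,
    qseq = "A-C", sseq = "AGC"), c(q1 = 2L))
  p <- build_profile(q, hit)
  expect_equal(ncol(p$freq), 2)  # the 'G' column vanishes
  expect_equal(unname(p$freq["A", 1]), 1.0)
  expect_equal(unname(p$freq["C", 2]), 1.0)
})

test_that("zero hits give a point mass on the query residue", {
  p <- build_profile(sequence_set(c(q = "MKW")))
  expect_equal(unname(p$freq["M", 1]), 1)
  expect_equal(unname(p$freq["K", 2]), 1)
  expect_equal(unname(p$freq["W", 3]), 1)
  expect_equal(p$nhits, 0L)
})

test_that("corrupt hits (query segment mismatch) are rejected", {
  q <- sequence_set(c(q1 = "ACDEF"))
  hit <- hit_table(data.frame(
    qid = "q1", sid = "h1", pident = 100, length = 3L,
    qstart = 2L, qend = 4L, sstart = 1L, send = 3L, evalue = 1e-5,
    qseq = "CEE", sseq = "CEE"), c(q1 = 5L))
  expect_error(build_profile(q, hit), "does not match")
})

test_that("extend_all: one profile per sequence, degenerate on empty db", {
  seqs <- sequence_set(c(a = "MKTLIV", b = "MKTLWV", c = "MKTAIV"))
  profs <- extend_all(seqs, db = NULL)
  expect_equal(names(profs), c("a", "b", "c"))
  for (p in profs) {
    expect_equal(p$nhits, 0L)
    expect_equal(max(abs(colSums(p$freq) - 1)), 0, tolerance = 1e-12)
  }
  # determinism
  fam <- simulate_family(seed = 5, n = 3, target_identity = 0.6)
  db <- builtin_database(build_mini_database(list(fam), n_decoys = 2, seed = 6))
  p1 <- extend_all(fam$members, db)
  p2 <- extend_all(fam$members, db)
  expect_identical(p1, p2)
})

test_that("keyword filtering is token-based and case-insensitive", {
  seqs <- sequence_set(
    rep("MKTLIV", 5),
    id = paste0("r", 1:5),
    desc = c("Transmembrane protein", "keyword:transmembrane receptor",
             "transmembrane-like protein", "soluble enzyme",
             "putative, transmembrane; fragment"))
  out <- filter_database_by_keyword(seqs, "transmembrane")
  expect_equal(out$id, c("r1", "r2", "r5"))  # hyphenated token must not match
  expect_equal(nrow(filter_database_by_keyword(seqs, "kinase")), 0)
})

test_that("blast+ backend agrees with builtin on an easy family", {
  fam <- simulate_family(seed = 9, n = 3, target_identity = 0.7)
  dbseqs <- build_mini_database(list(fam), n_decoys = 2, seed = 10)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(dbseqs, f)
  db <- blast_database(f)
  q <- fam$members[1, , drop = FALSE]
  class(q) <- c("tmc_sequences", "data.frame")
  h <- search_hits(q, db, evalue_max = 1e-3)
  expect_gt(nrow(h), 0)
  expect_true(all(h$qid == q$id))
  expect_false(anyNA(h$coverage))
  # the self-hit is found at full identity
  self <- h[h$sid == q$id, ]
  expect_equal(nrow(self), 1)
  expect_equal(self$pident, 100)
})

test_that("hits backend reads precomputed tabular files per query", {
  dir <- withr::local_tempdir()
  writeLines(paste(c("q1", "s", "80", "10", "1", "10", "1", "10", "1e-8",
                     "AAAAAAAAAA", "AAAAAAAAAA"), collapse = "\t"),
             file.path(dir, "q1.tsv"))
  db <- hits_database(dir)
  q <- sequence_set(c(q1 = "AAAAAAAAAA"))
  h <- search_hits(q, db)
  expect_equal(h$sid, "s")
  expect_equal(h$coverage, 100)
  # missing file means no hits
  q2 <- sequence_set(c(q2 = "CCCCC"))
  expect_equal(nrow(search_hits(q2, db)), 0)
})
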