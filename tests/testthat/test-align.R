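# Guide tree, consistency DP, progressive alignment and refinement.

diag_library <- function(s1, s2, ids = c("a", "b"), w = 100) {
  stopifnot(nchar(s1) == nchar(s2))
  n <- nchar(s1)
  constraint_library(
    stats::setNames(c(n, n), ids),
    data.frame(idA = ids[[1]], posA = seq_len(n),
               idB = ids[[2]], posB = seq_len(n), weight = w))
}

test_that("guide tree: cherry for 2, dominated pair first for 3, lexicographic ties", {
  lib <- diag_library("MKWTL", "MKWTL")
  tree <- build_guide_tree(lib)
  expect_equal(sort(unname(unlist(tree$root))), c("a", "b"))
  # a,b strongly constrained; c weakly
  lib3 <- constraint_library(
    c(a = 5, b = 5, c = 5),
    data.frame(idA = c(rep("a", 5), "a"), posA = c(1:5, 1L),
               idB = c(rep("b", 5), "c"), posB = c(1:5, 1L),
               weight = 100))
  tree3 <- build_guide_tree(lib3)
  first <- sort(unname(unlist(tree3$root$left)))
  if (length(first) == 1) first <- sort(unname(unlist(tree3$root$right)))
  expect_equal(first, c("a", "b"))
  # all-tied distances: lexicographically smallest pair merges first, giving
  # the caterpillar (((a,b),c),d)
  lib_tie <- constraint_library(c(b = 3, d = 3, a = 3, c = 3))
  tree_tie <- build_guide_tree(lib_tie)
  expect_equal(sort(unname(unlist(tree_tie$root$left$left))), c("a", "b"))
  expect_equal(tree_tie$root$left$right, "c")
  expect_equal(tree_tie$root$right, "d")
  expect_error(build_guide_tree(constraint_library(c(a = 3))), "at least 2")
})

test_that("DP recovers the diagonal from a 5-constraint diagonal library", {
  lib <- diag_library("MKWTL", "MKWTL")
  out <- align_pair_of_subalignments(msa(c(a = "MKWTL")), msa(c(b = "MKWTL")), lib)
  expect_equal(out$rows[["a"]], "MKWTL")
  expect_equal(out$rows[["b"]], "MKWTL")
  expect_equal(out$ncol, 5)
})

test_that("empty library still yields a valid, deterministic MSA", {
  lib <- constraint_library(c(a = 2, b = 2))
  out <- align_pair_of_subalignments(msa(c(a = "MK")), msa(c(b = "WL")), lib)
  # high-road tie-break: match preferred, so the rows align residue-to-residue
  expect_equal(out$ncol, 2)
  expect_equal(out$rows[["a"]], "MK")
  expect_equal(out$rows[["b"]], "WL")
  out2 <- align_pair_of_subalignments(msa(c(a = "MK")), msa(c(b = "WL")), lib)
  expect_identical(out, out2)
  expect_error(align_pair_of_subalignments(msa(c(a = "MK")), msa(c(a = "WL")), lib),
               "disjoint")
})

test_that("DP attains the exhaustive optimum on random small instances", {
  withr::local_seed(66)
  for (k in 1:25) {
    la <- sample(1:4, 1); lb <- sample(1:4, 1)
    cons <- expand.grid(posA = seq_len(la), posB = seq_len(lb))
    cons <- cons[stats::runif(nrow(cons)) < 0.5, , drop = FALSE]
    lib <- constraint_library(
      c(a = la, b = lb),
      if (nrow(cons) > 0) data.frame(idA = "a", posA = cons$posA,
                                     idB = "b", posB = cons$posB,
                                     weight = sample.int(100, nrow(cons), replace = TRUE))
      else tmcoffee:::empty_constraints())
    sa <- paste0(sample(tmcoffee:::AA20, la, replace = TRUE), collapse = "")
    sb <- paste0(sample(tmcoffee:::AA20, lb, replace = TRUE), collapse = "")
    out <- align_pair_of_subalignments(msa(c(a = sa)), msa(c(b = sb)), lib,
                                       extended = FALSE)
    realized <- tmcoffee:::total_library_score(out, lib, extended = FALSE)
    S <- pair_weight_matrix(lib, "a", "b")
    expect_equal(realized, oracle_best_alignment_score(S))
  }
})

test_that("column count bounds hold on random merges", {
  withr::local_seed(77)
  for (k in 1:10) {
    lib <- random_library(n_seqs = 2, max_len = 5, density = 0.3)
    la <- lib$lengths[["a"]]; lb <- lib$lengths[["b"]]
    sa <- paste0(sample(tmcoffee:::AA20, la, replace = TRUE), collapse = "")
    sb <- paste0(sample(tmcoffee:::AA20, lb, replace = TRUE), collapse = "")
    out <- align_pair_of_subalignments(msa(c(a = sa)), msa(c(b = sb)), lib)
    expect_lte(out$ncol, la + lb)
    expect_gte(out$ncol, max(la, lb))
  }
})

test_that("progressive alignment of 2 equals the single merge; 4 identical stay ungapped", {
  lib <- diag_library("MKWTL", "MKWTL")
  seqs <- sequence_set(c(a = "MKWTL", b = "MKWTL"))
  tree <- build_guide_tree(lib)
  expect_equal(progressive_align(tree, lib, seqs),
               align_pair_of_subalignments(msa(c(a = "MKWTL")),
                                           msa(c(b = "MKWTL")), lib))
  seqs4 <- sequence_set(stats::setNames(rep("MKWTLIV", 4), c("a", "b", "c", "d")))
  aln4 <- tmcoffee_align(seqs4)
  expect_equal(aln4$ncol, 7)
  expect_true(all(!grepl("-", unlist(aln4$rows), fixed = TRUE)))
})

test_that("input order only permutes rows, not column content", {
  fam <- simulate_family(seed = 12, n = 4, target_identity = 0.55)
  seqs <- fam$members
  perm <- seqs[c(3, 1, 4, 2), , drop = FALSE]
  class(perm) <- c("tmc_sequences", "data.frame")
  a1 <- tmcoffee_align(seqs)
  a2 <- tmcoffee_align(perm)
  expect_equal(a1$rows[sort(a1$ids)], a2$rows[sort(a2$ids)])
  expect_equal(a2$ids, perm$id)  # rows follow input order
})

test_that("repeated runs are byte-identical", {
  fam <- simulate_family(seed = 13, n = 4, target_identity = 0.5)
  a1 <- tmcoffee_align(fam$members)
  a2 <- tmcoffee_align(fam$members)
  expect_identical(a1$rows, a2$rows)
})

test_that("refine: rounds=0 is identity, score never decreases, shifts heal", {
  seqs <- sequence_set(stats::setNames(rep("MKWTLIV", 3), c("a", "b", "c")))
  profs <- lapply(seq_len(3), function(i) {
    q <- seqs[i, , drop = FALSE]; class(q) <- c("tmc_sequences", "data.frame")
    profile_from_sequence(q)
  })
  names(profs) <- seqs$id
  lib <- build_primary_library(profs)
  good <- tmcoffee_align(seqs)
  expect_identical(refine(good, lib, rounds = 0), good)
  # corrupt one row by shifting it right
  bad <- msa(c(a = "MKWTLIV-", b = "MKWTLIV-", c = "-MKWTLIV"))
  s_bad <- tmcoffee:::total_library_score(bad, lib)
  healed <- refine(bad, lib, rounds = 1)
  s_healed <- tmcoffee:::total_library_score(healed, lib)
  expect_gte(s_healed, s_bad)
  stripped <- tmcoffee:::drop_allgap_columns(healed)
  expect_equal(stripped$rows[["c"]], stripped$rows[["a"]])
})

test_that("extension off equals extension against a query-only database", {
  # mutually unrelated queries: self-hits are rejected by the 90% identity
  # cap and cross-hits fall below the 50% floor (or the coverage bound), so
  # every profile degenerates and the two code paths coincide exactly
  withr::local_seed(14)
  seqs <- sequence_set(stats::setNames(vapply(1:3, function(i) {
    paste0(sample(tmcoffee:::AA20, 60, replace = TRUE), collapse = "")
  }, character(1)), c("u1", "u2", "u3")))
  db <- builtin_database(seqs)
  a_off <- tmcoffee_align(seqs, extension = FALSE)
  a_on <- tmcoffee_align(seqs, db = db, extension = TRUE)
  expect_equal(unname(attr(a_on, "stats")["hits_kept"]), 0)
  expect_identical(a_off$rows, a_on$rows)
})

test_that("two identical sequences align residue-to-residue end to end", {
  seqs <- sequence_set(c(x = "MKTWLIVGAS", y = "MKTWLIVGAS"))
  aln <- tmcoffee_align(seqs)
  expect_equal(aln$rows[["x"]], "MKTWLIVGAS")
  expect_equal(aln$rows[["y"]], "MKTWLIVGAS")
})
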