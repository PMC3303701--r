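# Guide-tree construction and progressive alignment maximizing
# extended-library consistency. The DP carries no gap penalty: all
# positional signal comes from the relay-extended constraint weights
# (classic T-Coffee behaviour; gap modelling lives in the pair-HMM stage).

#' Build a UPGMA guide tree from library scores
#'
#' Pairwise distance d(A,B) = 1 - min(1, sum of constraint weights on (A,B)
#' / (100 * min(lenA, lenB))). Ties are broken by merging the pair whose
#' (lexicographically smallest member) pair sorts first, so the tree is
#' deterministic.
#'
#' @param lib a `tmc_library` over >= 2 sequences
#' @return a `tmc_tree`: nested list of `list(left, right)` nodes with
#'   character leaves
#' @export
build_guide_tree <- function(lib) {
  ids <- names(lib$lengths)
  if (length(ids) < 2) tmc_error("need at least 2 sequences for a guide tree")
  n <- length(ids)
  D <- matrix(1, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  cons <- lib$constraints
  if (nrow(cons) > 0) {
    key <- paste(cons$idA, cons$idB)
    tot <- tapply(cons$weight, key, sum)
    for (k in names(tot)) {
      p <- strsplit(k, " ", fixed = TRUE)[[1]]
      sc <- tot[[k]] / (100 * min(lib$lengths[[p[1]]], lib$lengths[[p[2]]]))
      D[p[1], p[2]] <- D[p[2], p[1]] <- max(0, 1 - min(1, sc))
    }
  }
  # active clusters: node structure, member leaf ids (sorted), size, rep id
  clusters <- lapply(ids, function(id) list(node = id, rep = id, size = 1L))
  dist <- D
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (a in seq_len(m - 1)) {
      for (b in (a + 1):m) {
        d <- dist[a, b]
        key <- sort(c(clusters[[a]]$rep, clusters[[b]]$rep))
        if (d < best_d - 1e-12 ||
            (abs(d - best_d) <= 1e-12 &&
             (is.null(best_key) ||
              key[1] < best_key[1] ||
              (key[1] == best_key[1] && key[2] < best_key[2])))) {
          best <- c(a, b); best_d <- d; best_key <- key
        }
      }
    }
    a <- best[1]; b <- best[2]
    # left child is the cluster with the lexicographically smaller rep
    if (clusters[[a]]$rep <= clusters[[b]]$rep) { l <- a; r <- b } else { l <- b; r <- a }
    merged <- list(node = list(left = clusters[[l]]$node,
                               right = clusters[[r]]$node),
                   rep = min(clusters[[a]]$rep, clusters[[b]]$rep),
                   size = clusters[[a]]$size + clusters[[b]]$size)
    keep <- setdiff(seq_len(m), c(a, b))
    newd <- vapply(keep, function(k) {
      (clusters[[a]]$size * dist[a, k] + clusters[[b]]$size * dist[b, k]) /
        (clusters[[a]]$size + clusters[[b]]$size)
    }, numeric(1))
    dist <- rbind(cbind(dist[keep, keep, drop = FALSE], newd),
                  c(newd, 0))
    clusters <- c(clusters[keep], list(merged))
  }
  structure(list(root = clusters[[1]]$node, ids = ids), class = "tmc_tree")
}

#' @export
print.tmc_tree <- function(x, ...) {
  fmt <- function(nd) {
    if (is.character(nd)) nd else sprintf("(%s,%s)", fmt(nd$left), fmt(nd$right))
  }
  cat("tmc_tree:", fmt(x$root), "\n")
  invisible(x)
}

# residue index of each alignment cell (NA at gaps), rows x columns
residue_index_matrix <- function(aln) {
  m <- msa_matrix(aln)
  idx <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (r in seq_len(nrow(m))) {
    nz <- m[r, ] != "-"
    idx[r, nz] <- seq_len(sum(nz))
  }
  idx
}

# column-vs-column consistency score matrix between two sub-alignments
column_score_matrix <- function(subA, subB, lib, extended = TRUE) {
  idxA <- residue_index_matrix(subA)
  idxB <- residue_index_matrix(subB)
  nA <- ncol(idxA); nB <- ncol(idxB)
  S <- matrix(0, nA, nB)
  for (a in rownames(idxA)) {
    pa <- idxA[a, ]
    ua <- which(!is.na(pa))
    if (length(ua) == 0) next
    for (b in rownames(idxB)) {
      W <- pair_weight_matrix(lib, a, b, extended = extended)
      pb <- idxB[b, ]
      ub <- which(!is.na(pb))
      if (length(ub) == 0) next
      S[ua, ub] <- S[ua, ub] + W[pa[ua], pb[ub], drop = FALSE]
    }
  }
  occA <- colSums(!is.na(idxA)); occB <- colSums(!is.na(idxB))
  N <- outer(occA, occB)
  S / pmax(N, 1)
}

# DP over the column-pair score matrix; no gap penalty; tie-break prefers
# match, then consuming a column of A (gap in B), then a column of B
consistency_dp <- function(S) {
  nA <- nrow(S); nB <- ncol(S)
  dp <- matrix(0, nA + 1, nB + 1)
  move <- matrix(0L, nA + 1, nB + 1)  # 1 diag, 2 up(A), 3 left(B)
  if (nA > 0) move[seq_len(nA) + 1, 1] <- 2L
  if (nB > 0) move[1, seq_len(nB) + 1] <- 3L
  for (i in seq_len(nA)) {
    for (j in seq_len(nB)) {
      diag <- dp[i, j] + S[i, j]
      up <- dp[i, j + 1]
      left <- dp[i + 1, j]
      if (diag >= up && diag >= left) {
        dp[i + 1, j + 1] <- diag; move[i + 1, j + 1] <- 1L
      } else if (up >= left) {
        dp[i + 1, j + 1] <- up; move[i + 1, j + 1] <- 2L
      } else {
        dp[i + 1, j + 1] <- left; move[i + 1, j + 1] <- 3L
      }
    }
  }
  # traceback
  path <- integer(0)
  i <- nA + 1; j <- nB + 1
  while (i > 1 || j > 1) {
    mv <- move[i, j]
    path <- c(mv, path)
    if (mv == 1L) { i <- i - 1; j <- j - 1 }
    else if (mv == 2L) i <- i - 1
    else j <- j - 1
  }
  list(score = dp[nA + 1, nB + 1], path = path)
}

#' Align two sub-alignments by consistency dynamic programming
#'
#' Global column-level DP maximizing the sum over matched columns of the
#' average extended-library weight across contributing (non-gap) row pairs,
#' with no gap penalty. Output rows are the rows of `subA` followed by the
#' rows of `subB`.
#'
#' @param subA,subB `tmc_msa` objects over disjoint id sets
#' @param lib a `tmc_library`
#' @param extended use lazily extended weights (default) or primary weights
#' @return a `tmc_msa`
#' @export
align_pair_of_subalignments <- function(subA, subB, lib, extended = TRUE) {
  if (length(intersect(subA$ids, subB$ids)) > 0) {
    tmc_error("sub-alignments must cover disjoint sequence sets")
  }
  S <- column_score_matrix(subA, subB, lib, extended = extended)
  res <- consistency_dp(S)
  mA <- msa_matrix(subA); mB <- msa_matrix(subB)
  out <- matrix("-", nrow(mA) + nrow(mB), length(res$path),
                dimnames = list(c(rownames(mA), rownames(mB)), NULL))
  i <- 0L; j <- 0L
  for (k in seq_along(res$path)) {
    mv <- res$path[[k]]
    if (mv != 3L) { i <- i + 1L; out[seq_len(nrow(mA)), k] <- mA[, i] }
    if (mv != 2L) { j <- j + 1L; out[nrow(mA) + seq_len(nrow(mB)), k] <- mB[, j] }
  }
  matrix_msa(out)
}

#' Progressively align sequences along a guide tree
#'
#' Post-order traversal merging sub-alignments with
#' [align_pair_of_subalignments()]. Output rows follow the order of `seqs`.
#'
#' @param tree a `tmc_tree`
#' @param lib a `tmc_library`
#' @param seqs the input `tmc_sequences`
#' @param extended use extended weights in the merge DP
#' @return a `tmc_msa`
#' @export
progressive_align <- function(tree, lib, seqs, extended = TRUE) {
  recurse <- function(node) {
    if (is.character(node)) {
      return(msa(stats::setNames(get_residues(seqs, node), node)))
    }
    align_pair_of_subalignments(recurse(node$left), recurse(node$right),
                                lib, extended = extended)
  }
  aln <- recurse(tree$root)
  msa(aln$rows[seqs$id])  # restore input row order
}

# total library score of an MSA: sum over matched residue pairs of
# (extended) weights
total_library_score <- function(aln, lib, extended = TRUE) {
  idx <- residue_index_matrix(aln)
  ids <- rownames(idx)
  total <- 0
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (a >= b) next
      W <- pair_weight_matrix(lib, ids[[a]], ids[[b]], extended = extended)
      both <- !is.na(idx[a, ]) & !is.na(idx[b, ])
      if (!any(both)) next
      total <- total + sum(W[cbind(idx[a, both], idx[b, both])])
    }
  }
  total
}

drop_allgap_columns <- function(aln) {
  m <- msa_matrix(aln)
  keep <- colSums(m != "-") > 0
  matrix_msa(m[, keep, drop = FALSE])
}

#' Iterative leave-one-out refinement
#'
#' Each round removes every sequence in turn and realigns it against the
#' remainder; the move is kept only if the total library score does not
#' decrease. `rounds = 0` (the default) returns the input unchanged.
#'
#' @param aln a `tmc_msa`
#' @param lib a `tmc_library`
#' @param rounds number of refinement sweeps
#' @param extended use extended weights
#' @return a `tmc_msa` with total library score >= the input's
#' @export
refine <- function(aln, lib, rounds = 0, extended = TRUE) {
  if (rounds <= 0) return(aln)
  current <- aln
  score <- total_library_score(current, lib, extended = extended)
  for (r in seq_len(rounds)) {
    for (id in current$ids) {
      m <- msa_matrix(current)
      rest <- matrix_msa(m[setdiff(rownames(m), id), , drop = FALSE])
      rest <- drop_allgap_columns(rest)
      solo <- msa(stats::setNames(gsub("-", "", current$rows[[id]], fixed = TRUE), id))
      cand <- align_pair_of_subalignments(rest, solo, lib, extended = extended)
      cand <- msa(cand$rows[current$ids])
      cand_score <- total_library_score(cand, lib, extended = extended)
      # strict improvement only: equal-score moves would let the alignment
      # wander without ever paying for it
      if (cand_score > score) {
        current <- cand
        score <- cand_score
      }
    }
  }
  current
}

#' End-to-end consistency alignment with homology extension
#'
#' The full pipeline: homology-extend every sequence into a profile (or use
#' degenerate self-profiles when extension is off), build the primary
#' constraint library from pair-HMM posteriors, relay-extend it lazily
#' during progressive alignment along a UPGMA guide tree, and optionally
#' refine.
#'
#' @param seqs a `tmc_sequences` object (>= 2 sequences)
#' @param db a database handle (see [builtin_database()]) or NULL
#' @param extension run homology extension (needs `db`); FALSE gives the
#'   plain consistency aligner on self-profiles
#' @param params pair-HMM parameters
#' @param threshold posterior constraint threshold
#' @param refine_rounds leave-one-out refinement sweeps (default off)
#' @param id_min,id_max,cov_min,evalue_max hit-filter settings
#' @param threads worker processes for search and library stages
#' @param verbose log per-stage counts to stderr
#' @return a `tmc_msa`; attributes `library` (primary `tmc_library`),
#'   `tree`, and `stats` (named counts)
#' @export
tmcoffee_align <- function(seqs, db = NULL, extension = !is.null(db),
                           params = pairhmm_params(), threshold = 0.99,
                           refine_rounds = 0, id_min = 50, id_max = 90,
                           cov_min = 70, evalue_max = NULL, threads = 1,
                           verbose = FALSE) {
  if (!inherits(seqs, "tmc_sequences")) tmc_error("seqs must be a tmc_sequences object")
  if (nrow(seqs) < 2) tmc_error("need at least 2 sequences to align")
  say <- function(...) if (verbose) message(sprintf(...))
  profiles <- extend_all(seqs, db = if (extension) db else NULL,
                         id_min = id_min, id_max = id_max, cov_min = cov_min,
                         evalue_max = evalue_max, threads = threads)
  say("profiles: %d (total hits kept: %d)", length(profiles),
      sum(vapply(profiles, function(p) p$nhits, integer(1))))
  lib <- build_primary_library(profiles, params = params,
                               threshold = threshold)
  say("primary library: %d constraints", nrow(lib$constraints))
  tree <- build_guide_tree(lib)
  aln <- progressive_align(tree, lib, seqs, extended = TRUE)
  if (refine_rounds > 0) aln <- refine(aln, lib, rounds = refine_rounds)
  say("alignment: %d columns", aln$ncol)
  attr(aln, "library") <- lib
  attr(aln, "tree") <- tree
  attr(aln, "stats") <- c(
    sequences = nrow(seqs),
    hits_kept = sum(vapply(profiles, function(p) p$nhits, integer(1))),
    constraints = nrow(lib$constraints),
    columns = aln$ncol)
  aln
}
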