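# BAliBASE-style evaluation: sum-of-pairs (SP) and total-column (TC)
# scores restricted to annotated core blocks of a reference alignment, an
# aggregate report, and an exact paired signed-rank test for comparing two
# result sets family by family.

# shared machinery for SP and TC: walk the reference core columns, collect
# the test columns each core residue maps to
core_column_stats <- function(test, ref, core) {
  if (!setequal(test$ids, ref$ids)) {
    tmc_error("test and reference alignments cover different sequence ids")
  }
  for (id in ref$ids) {
    if (gsub("-", "", test$rows[[id]], fixed = TRUE) !=
        gsub("-", "", ref$rows[[id]], fixed = TRUE)) {
      tmc_error(sprintf("sequence '%s' differs between test and reference after degapping", id))
    }
  }
  if (core$ncol != ref$ncol) {
    tmc_error("core annotation does not match the reference column count")
  }
  idx_ref <- residue_index_matrix(ref)
  idx_test <- residue_index_matrix(test)
  # test column of the k-th residue of each sequence
  test_col <- lapply(ref$ids, function(id) {
    which(!is.na(idx_test[id, ]))  # k-th entry = test column of residue k
  })
  names(test_col) <- ref$ids
  pairs_total <- 0; pairs_ok <- 0
  cols_total <- 0; cols_ok <- 0
  mask <- core$mask[ref$ids, , drop = FALSE]
  for (cc in which(colSums(mask) > 0)) {
    members <- ref$ids[mask[, cc] & !is.na(idx_ref[ref$ids, cc])]
    if (length(members) < 2) next
    tcols <- vapply(members, function(id) {
      test_col[[id]][[idx_ref[id, cc]]]
    }, numeric(1))
    tab <- table(tcols)
    npairs <- length(members) * (length(members) - 1) / 2
    okpairs <- sum(tab * (tab - 1) / 2)
    pairs_total <- pairs_total + npairs
    pairs_ok <- pairs_ok + okpairs
    cols_total <- cols_total + 1
    if (length(tab) == 1) cols_ok <- cols_ok + 1
  }
  list(pairs_total = pairs_total, pairs_ok = pairs_ok,
       cols_total = cols_total, cols_ok = cols_ok)
}

#' Sum-of-pairs score over reference core regions
#'
#' Enumerates, in reference core columns only, every pair of residues
#' placed in the same reference column, and reports the fraction of those
#' pairs also co-columned in the test alignment. An empty core yields
#' `sp = NA` with `pairs = 0` (flagged, never divided by zero).
#'
#' @param test,ref `tmc_msa` objects over the same sequences (identical
#'   after degapping)
#' @param core a `tmc_core` over the reference columns
#' @return list with `sp` and `pairs` (the denominator)
#' @export
sp_score <- function(test, ref, core) {
  st <- core_column_stats(test, ref, core)
  sp <- if (st$pairs_total > 0) st$pairs_ok / st$pairs_total else NA_real_
  if (st$pairs_total == 0) warning("empty core: SP undefined for this family")
  list(sp = sp, pairs = st$pairs_total)
}

#' Total-column score over reference core regions
#'
#' A reference core column (with at least two masked residues) counts as
#' recovered iff all its masked residues appear together in a single test
#' column.
#'
#' @inheritParams sp_score
#' @return list with `tc` and `cols` (the denominator)
#' @export
tc_score <- function(test, ref, core) {
  st <- core_column_stats(test, ref, core)
  tc <- if (st$cols_total > 0) st$cols_ok / st$cols_total else NA_real_
  if (st$cols_total == 0) warning("empty core: TC undefined for this family")
  list(tc = tc, cols = st$cols_total)
}

#' Score a suite of families and aggregate
#'
#' @param results named list; each element a list with `test`, `ref`
#'   (`tmc_msa`) and `core` (`tmc_core`)
#' @return a `tmc_score_report`: `per_family` data.frame (family, sp, tc,
#'   pairs, cols) and `aggregate` (unweighted mean SP/TC over families with
#'   non-empty cores, total pairs and columns)
#' @export
score_suite <- function(results) {
  if (length(results) < 1) tmc_error("need at least one family")
  fam <- names(results)
  if (is.null(fam)) fam <- sprintf("family%d", seq_along(results))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    st <- core_column_stats(r$test, r$ref, r$core)
    data.frame(family = fam[[i]],
               sp = if (st$pairs_total > 0) st$pairs_ok / st$pairs_total else NA_real_,
               tc = if (st$cols_total > 0) st$cols_ok / st$cols_total else NA_real_,
               pairs = st$pairs_total, cols = st$cols_total)
  })
  per_family <- do.call(rbind, rows)
  usable <- !is.na(per_family$sp)
  if (any(!usable)) {
    warning(sprintf("excluding %d family(ies) with empty cores from aggregates",
                    sum(!usable)))
  }
  aggregate <- list(sp = mean(per_family$sp[usable]),
                    tc = mean(per_family$tc[usable]),
                    pairs = sum(per_family$pairs),
                    cols = sum(per_family$cols))
  structure(list(per_family = per_family, aggregate = aggregate),
            class = "tmc_score_report")
}

#' @export
print.tmc_score_report <- function(x, ...) {
  print(x$per_family, row.names = FALSE)
  cat(sprintf("avg SP %.3f  avg TC %.3f  pairs %d  cols %d\n",
              x$aggregate$sp, x$aggregate$tc, x$aggregate$pairs,
              x$aggregate$cols))
  invisible(x)
}

#' Write a score report as TSV
#' @param report a `tmc_score_report`
#' @param path output path
#' @export
write_score_report <- function(report, path) {
  utils::write.table(report$per_family, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a score report TSV back into a per-family data.frame
#' @param path input path
#' @export
read_score_report <- function(path) {
  if (!file.exists(path)) tmc_error(sprintf("no such file: %s", path))
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Exact paired two-sided Wilcoxon signed-rank test
#'
#' Computed over per-family paired differences; zero differences are
#' dropped (standard exact convention) and all-zero input returns p = 1.
#' The exact null distribution is enumerated by dynamic programming over
#' all 2^n sign assignments (handles tied magnitudes); above n = 20 a
#' normal approximation is used.
#'
#' @param scores_a,scores_b numeric vectors of per-family scores, same
#'   families in the same order, length >= 2
#' @return two-sided p-value
#' @export
paired_test <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    tmc_error("score vectors have different lengths")
  }
  if (length(scores_a) < 2) tmc_error("need at least 2 families")
  d <- scores_a - scores_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1.0)
  r2 <- as.integer(round(2 * rank(abs(d))))  # doubled ranks are integers
  W2 <- sum(r2[d > 0])
  mu <- sum(r2) / 2
  if (n <= 20) {
    # DP over the doubled-rank sum distribution under random signs
    counts <- rep(0, sum(r2) + 1)
    counts[1] <- 1
    for (r in r2) {
      shifted <- c(rep(0, r), counts[seq_len(length(counts) - r)])
      counts <- counts + shifted
    }
    sums <- seq_along(counts) - 1
    p <- sum(counts[abs(sums - mu) >= abs(W2 - mu) - 1e-9]) / 2^n
    min(1, p)
  } else {
    sigma <- sqrt(sum(r2^2)) / 2
    2 * stats::pnorm(-abs(W2 - mu) / sigma)
  }
}
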