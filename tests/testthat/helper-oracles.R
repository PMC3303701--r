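# Independent oracles used by the unit and acceptance tests. These
# deliberately re-derive every quantity from first principles (explicit
# enumeration, triple loops, double sums) and share no code with the
# package implementation paths they check.

# ---- pair-HMM: exhaustive state-labelled path enumeration ------------------

# emission likelihood-ratio matrix between two 21-letter profiles, by
# explicit double sum (with the occupancy multiplier when asked)
oracle_emissions <- function(freqA, freqB, params) {
  L1 <- ncol(freqA); L2 <- ncol(freqB)
  E <- matrix(0, L1, L2)
  for (i in seq_len(L1)) {
    for (j in seq_len(L2)) {
      fa <- freqA[1:20, i]; fb <- freqB[1:20, j]
      if (sum(fa) <= 0 || sum(fb) <= 0) { E[i, j] <- 1; next }
      fa <- fa / sum(fa); fb <- fb / sum(fb)
      s <- 0
      for (a in 1:20) {
        for (b in 1:20) {
          s <- s + fa[[a]] * fb[[b]] * params$emission[a, b] /
            (params$background[[a]] * params$background[[b]])
        }
      }
      if (isTRUE(params$occupancy)) {
        s <- s * (1 - freqA[21, i]) * (1 - freqB[21, j])
      }
      E[i, j] <- s
    }
  }
  E
}

# posterior match probabilities by enumerating every monotone alignment
# with explicit state labels under the 5-state bi-phasic model
oracle_posteriors <- function(freqA, freqB, params) {
  E <- oracle_emissions(freqA, freqB, params)
  L1 <- nrow(E); L2 <- ncol(E)
  d1 <- params$gap_open_short; d2 <- params$gap_open_long
  e1 <- params$gap_extend_short; e2 <- params$gap_extend_long
  states <- c("M", "X1", "X2", "Y1", "Y2")
  A <- matrix(0, 5, 5, dimnames = list(states, states))
  A["M", ] <- c(1 - 2 * d1 - 2 * d2, d1, d2, d1, d2)
  A["X1", c("M", "X1")] <- c(1 - e1, e1)
  A["X2", c("M", "X2")] <- c(1 - e2, e2)
  A["Y1", c("M", "Y1")] <- c(1 - e1, e1)
  A["Y2", c("M", "Y2")] <- c(1 - e2, e2)
  to_end <- c(M = 1 - 2 * d1 - 2 * d2, X1 = 1 - e1, X2 = 1 - e2,
              Y1 = 1 - e1, Y2 = 1 - e2)
  post <- matrix(0, L1, L2)
  total <- 0
  rec <- function(i, j, state, prob, cells) {
    if (i == L1 && j == L2) {
      p <- prob * to_end[[state]]
      total <<- total + p
      if (nrow(cells) > 0) {
        for (r in seq_len(nrow(cells))) {
          post[cells[r, 1], cells[r, 2]] <<- post[cells[r, 1], cells[r, 2]] + p
        }
      }
      return(invisible())
    }
    for (s in states) {
      a <- A[state, s]
      if (a == 0) next
      if (s == "M") {
        if (i < L1 && j < L2) {
          rec(i + 1, j + 1, s, prob * a * E[i + 1, j + 1],
              rbind(cells, c(i + 1, j + 1)))
        }
      } else if (s %in% c("X1", "X2")) {
        if (i < L1) rec(i + 1, j, s, prob * a, cells)
      } else {
        if (j < L2) rec(i, j + 1, s, prob * a, cells)
      }
    }
  }
  rec(0, 0, "M", 1, matrix(0, 0, 2))
  list(posterior = post / total, total = total)
}

# random tmc_profile over a reduced residue alphabet (first `k` letters),
# optionally with gap mass
random_profile <- function(len, k = 3, gap = FALSE) {
  freq <- matrix(0, 21, len, dimnames = list(tmcoffee:::PROFILE_ALPHABET, NULL))
  for (i in seq_len(len)) {
    w <- stats::runif(k)
    g <- if (gap) stats::runif(1, 0, 0.5) else 0
    freq[seq_len(k), i] <- (1 - g) * w / sum(w)
    freq[21, i] <- g
  }
  structure(list(query = NULL, freq = freq,
                 support = rep(1L, len), nhits = 0L),
            class = "tmc_profile")
}

# ---- library extension: brute-force triple loop ----------------------------

oracle_extend <- function(lib) {
  cons <- lib$constraints
  look <- new.env(parent = emptyenv())
  put <- function(a, i, b, j, w) {
    assign(paste(a, i, b, j, sep = "|"), w, envir = look)
  }
  get0w <- function(a, i, b, j) {
    v <- mget(paste(a, i, b, j, sep = "|"), envir = look,
              ifnotfound = list(0))[[1]]
    v
  }
  if (nrow(cons) > 0) {
    for (r in seq_len(nrow(cons))) {
      put(cons$idA[[r]], cons$posA[[r]], cons$idB[[r]], cons$posB[[r]], cons$weight[[r]])
      put(cons$idB[[r]], cons$posB[[r]], cons$idA[[r]], cons$posA[[r]], cons$weight[[r]])
    }
  }
  ids <- names(lib$lengths)
  out <- list()
  for (a in ids) {
    for (b in ids) {
      if (a >= b) next
      for (i in seq_len(lib$lengths[[a]])) {
        for (j in seq_len(lib$lengths[[b]])) {
          w <- get0w(a, i, b, j)
          relay <- 0
          for (cc in setdiff(ids, c(a, b))) {
            for (k in seq_len(lib$lengths[[cc]])) {
              relay <- relay + min(get0w(a, i, cc, k), get0w(cc, k, b, j))
            }
          }
          tot <- w + relay
          if (tot > 0) {
            out[[length(out) + 1L]] <- data.frame(
              idA = a, posA = i, idB = b, posB = j, weight = tot,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(out) == 0) return(tmcoffee:::empty_constraints())
  df <- do.call(rbind, out)
  df[order(df$idA, df$posA, df$idB, df$posB), , drop = FALSE]
}

random_library <- function(n_seqs = 3, max_len = 5, density = 0.3,
                           max_w = 100) {
  ids <- letters[seq_len(n_seqs)]
  lens <- stats::setNames(sample(2:max_len, n_seqs, replace = TRUE), ids)
  rows <- list()
  for (a in seq_len(n_seqs - 1)) {
    for (b in (a + 1):n_seqs) {
      for (i in seq_len(lens[[a]])) {
        for (j in seq_len(lens[[b]])) {
          if (stats::runif(1) < density) {
            rows[[length(rows) + 1L]] <- data.frame(
              idA = ids[[a]], posA = i, idB = ids[[b]], posB = j,
              weight = sample.int(max_w, 1), stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  cons <- if (length(rows)) do.call(rbind, rows) else tmcoffee:::empty_constraints()
  constraint_library(lens, cons)
}

# ---- alignment DP: exhaustive enumeration of monotone alignments -----------

oracle_best_alignment_score <- function(S) {
  nA <- nrow(S); nB <- ncol(S)
  best <- -Inf
  rec <- function(i, j, sc) {
    if (i == nA && j == nB) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i < nA && j < nB) rec(i + 1, j + 1, sc + S[i + 1, j + 1])
    if (i < nA) rec(i + 1, j, sc)
    if (j < nB) rec(i, j + 1, sc)
  }
  rec(0, 0, 0)
  best
}

# ---- SP/TC: direct-definition scorer ---------------------------------------

oracle_sp_tc <- function(test, ref, core) {
  rm_ <- function(aln) do.call(rbind, strsplit(unname(aln$rows[ref$ids]), ""))
  mr <- rm_(ref); mt <- rm_(test)
  rownames(mr) <- rownames(mt) <- ref$ids
  # test column of each residue of each sequence
  colof <- lapply(ref$ids, function(id) which(mt[id, ] != "-"))
  names(colof) <- ref$ids
  residx <- function(id, col) sum(mr[id, 1:col] != "-")
  pt <- 0; po <- 0; ct <- 0; co <- 0
  for (col in seq_len(ncol(mr))) {
    members <- ref$ids[core$mask[ref$ids, col] & mr[, col] != "-"]
    if (length(members) < 2) next
    tcols <- sapply(members, function(id) colof[[id]][residx(id, col)])
    ok_all <- length(unique(tcols)) == 1
    ct <- ct + 1; if (ok_all) co <- co + 1
    for (x in seq_along(members)) {
      for (y in seq_along(members)) {
        if (x >= y) next
        pt <- pt + 1
        if (tcols[[x]] == tcols[[y]]) po <- po + 1
      }
    }
  }
  list(sp = if (pt > 0) po / pt else NA_real_,
       tc = if (ct > 0) co / ct else NA_real_,
       pairs = pt, cols = ct)
}

# random ungapped reference + gap-perturbed test over the same sequences
random_scoring_instance <- function(n_seqs = 3, len = 8) {
  ids <- paste0("s", seq_len(n_seqs))
  res <- vapply(ids, function(i) {
    paste0(sample(tmcoffee:::AA20, len, replace = TRUE), collapse = "")
  }, character(1))
  ref <- msa(stats::setNames(res, ids))
  # perturb: insert 0..3 gaps at random positions in each row
  width <- len + 4
  rows <- vapply(res, function(r) {
    k <- sample(0:3, 1)
    cs <- strsplit(r, "")[[1]]
    pos <- sort(sample(seq_len(len + k), k))
    out <- rep("-", len + k)
    out[setdiff(seq_len(len + k), pos)] <- cs
    paste0(c(out, rep("-", width - len - k)), collapse = "")
  }, character(1))
  test <- msa(stats::setNames(rows, ids))
  core <- core_annotation(data.frame(id = ids, start = 1, end = len),
                          ncol = len, ids = ids)
  list(test = test, ref = ref, core = core)
}
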