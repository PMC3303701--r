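# Synthetic transmembrane-protein family generator: alternating loop / TM
# helix architecture, star-tree evolution with column-exact truth tracking,
# and a mini homolog database so homology extension can be exercised
# offline with known ground truth.

# residue sampling pools: TM helices are dominated by hydrophobics, loops by
# polar/charged residues, echoing the amphiphilic character of
# membrane-spanning helices
default_tm_pool <- function() {
  c(I = 0.17, L = 0.21, V = 0.15, F = 0.12, A = 0.11, M = 0.06, G = 0.06,
    W = 0.04, C = 0.03, T = 0.03, S = 0.02)
}

default_loop_pool <- function() {
  c(S = 0.09, T = 0.07, N = 0.07, Q = 0.06, D = 0.08, E = 0.09, K = 0.09,
    R = 0.08, G = 0.08, P = 0.07, H = 0.04, A = 0.05, L = 0.04, V = 0.03,
    I = 0.02, F = 0.02, Y = 0.02)
}

#' Transmembrane topology model for the family simulator
#'
#' @param n_tm number of membrane-spanning helices (>= 1)
#' @param tm_len integer range (min, max) of TM helix lengths; must lie
#'   within 5..30 residues (helices tilted in the bilayer can need up to 30)
#' @param loop_len integer range of inter-helix loop lengths
#' @param tm_pool,loop_pool named positive sampling weights over residue
#'   letters for helix and loop positions
#' @return a `tmc_topology` list
#' @export
topology_model <- function(n_tm = 3, tm_len = c(15, 30), loop_len = c(5, 20),
                           tm_pool = default_tm_pool(),
                           loop_pool = default_loop_pool()) {
  if (n_tm < 1) tmc_config_error("need at least one TM segment")
  if (tm_len[1] < 5 || tm_len[2] > 30 || tm_len[1] > tm_len[2]) {
    tmc_config_error("TM length range must lie within [5, 30]")
  }
  if (loop_len[1] < 0 || loop_len[1] > loop_len[2]) {
    tmc_config_error("invalid loop length range")
  }
  for (pool in list(tm_pool, loop_pool)) {
    if (any(pool <= 0) || !all(names(pool) %in% AA20)) {
      tmc_config_error("pool weights must be positive and over standard residues")
    }
  }
  structure(list(n_tm = as.integer(n_tm), tm_len = as.integer(tm_len),
                 loop_len = as.integer(loop_len),
                 tm_pool = tm_pool / sum(tm_pool),
                 loop_pool = loop_pool / sum(loop_pool)),
            class = "tmc_topology")
}

sample_pool <- function(pool, n) {
  if (n == 0) return(character())
  sample(names(pool), n, replace = TRUE, prob = pool)
}

# uniform integer in [lo, hi]; immune to sample()'s scalar-first-arg rule
sample_len <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1)

#' Sample an ancestral transmembrane protein
#'
#' Alternating loop / helix / loop ... architecture: loop lengths and helix
#' lengths are drawn uniformly from the topology's ranges, residues from the
#' respective pools. Deterministic per seed.
#'
#' @param topology a `tmc_topology`
#' @param seed integer seed
#' @param id sequence id for the ancestor
#' @return list with `residues` (string), `segments` (data.frame
#'   `start end type`, 1-based inclusive residue coordinates, type
#'   `"loop"`/`"tm"`), and `is_tm` (per-residue logical)
#' @export
sample_ancestor <- function(topology, seed = 1, id = "anc") {
  with_seed(seed, {
    pieces <- list()
    types <- character()
    n_loops <- topology$n_tm + 1L
    for (k in seq_len(topology$n_tm)) {
      llen <- sample_len(topology$loop_len[1], topology$loop_len[2])
      pieces[[length(pieces) + 1L]] <- sample_pool(topology$loop_pool, llen)
      types <- c(types, "loop")
      tlen <- sample_len(topology$tm_len[1], topology$tm_len[2])
      pieces[[length(pieces) + 1L]] <- sample_pool(topology$tm_pool, tlen)
      types <- c(types, "tm")
    }
    llen <- sample_len(topology$loop_len[1], topology$loop_len[2])
    pieces[[length(pieces) + 1L]] <- sample_pool(topology$loop_pool, llen)
    types <- c(types, "loop")
    lens <- lengths(pieces)
    keep <- lens > 0
    ends <- cumsum(lens)[keep]
    starts <- (cumsum(lens) - lens + 1L)[keep]
    segments <- data.frame(start = starts, end = ends, type = types[keep])
    residues <- collapse0(unlist(pieces))
    is_tm <- logical(nchar(residues))
    for (i in which(segments$type == "tm")) {
      is_tm[segments$start[[i]]:segments$end[[i]]] <- TRUE
    }
    list(id = id, residues = residues, segments = segments, is_tm = is_tm)
  })
}

# P(two star-tree leaves agree at a site) when each branch substitutes with
# probability p and replacements are uniform over all 20 residues
match_prob <- function(p) {
  s <- 1 - p + p / 20
  s^2 + 19 * (p / 20)^2
}

#' Per-branch substitution rate realizing a target pairwise identity
#'
#' Inverts the exact star-tree site-match probability, accounting for the
#' slower evolution of TM segments (rate multiplier), to find the loop
#' substitution rate at which two family members have the requested
#' expected pairwise identity.
#'
#' @param target target pairwise identity in (0, 1]
#' @param tm_fraction fraction of sites inside TM segments
#' @param tm_multiplier TM substitution-rate multiplier
#' @return per-site substitution probability for loop sites
#' @export
rate_for_identity <- function(target, tm_fraction = 0.5, tm_multiplier = 0.3) {
  if (target >= 1) return(0)
  f <- function(p) {
    tm_fraction * match_prob(p * tm_multiplier) +
      (1 - tm_fraction) * match_prob(p) - target
  }
  # TM conservation imposes an identity floor; saturate if the target is
  # below what the topology can reach
  if (f(0.999) > 0) return(0.999)
  stats::uniroot(f, c(0, 0.999), tol = 1e-9)$root
}

mutate_residues <- function(res_chars, rates) {
  hit <- stats::runif(length(res_chars)) < rates
  if (any(hit)) res_chars[hit] <- sample(AA20, sum(hit), replace = TRUE)
  res_chars
}

#' Evolve a synthetic family from an ancestor on a star tree
#'
#' Each descendant is an independent branch: per-site substitutions (TM
#' sites at `tm_multiplier` times the loop rate; replacement drawn uniformly
#' from all 20 residues), and geometric-length indels restricted to loop
#' sites (insertions and deletions equally likely). The true alignment is
#' tracked column-exactly through every edit and the TM segments become the
#' core blocks of the true core annotation.
#'
#' @param ancestor result of [sample_ancestor()]
#' @param n number of descendants (>= 2)
#' @param sub_rate per-branch per-site substitution probability (loop sites)
#' @param indel_rate per-branch per-loop-site indel event probability
#' @param seed integer seed
#' @param tm_multiplier TM substitution-rate multiplier (< 1: helices are
#'   conserved)
#' @param indel_mean_len mean geometric indel length
#' @param prefix id prefix for the descendants
#' @return a `tmc_family`: list with `ancestor`, `members`
#'   (`tmc_sequences`), `truth` (`tmc_msa`), `core` (`tmc_core`), and the
#'   generation parameters
#' @export
evolve_family <- function(ancestor, n = 5, sub_rate = 0.1, indel_rate = 0,
                          seed = 1, tm_multiplier = 0.3, indel_mean_len = 3,
                          prefix = "seq") {
  if (n < 2) tmc_config_error("need at least 2 descendants")
  if (sub_rate < 0 || sub_rate >= 1 || indel_rate < 0 || indel_rate >= 1) {
    tmc_config_error("rates must lie in [0, 1)")
  }
  anc <- chars(ancestor$residues)
  L <- length(anc)
  rates <- ifelse(ancestor$is_tm, sub_rate * tm_multiplier, sub_rate)
  ids <- sprintf("%s%d", prefix, seq_len(n))
  with_seed(seed, {
    kept <- matrix(NA_character_, nrow = n, ncol = L)   # residue or NA=deleted
    inserts <- vector("list", n)                        # per member: list by anchor 0..L
    for (d in seq_len(n)) {
      res <- mutate_residues(anc, rates)
      deleted <- logical(L)
      ins <- list()
      if (indel_rate > 0) {
        loop_sites <- which(!ancestor$is_tm)
        for (s in loop_sites) {
          r <- stats::runif(1)
          if (r < indel_rate / 2) {          # deletion starting here
            len <- stats::rgeom(1, 1 / indel_mean_len) + 1L
            run <- s:min(L, s + len - 1L)
            run <- run[!ancestor$is_tm[run]]  # indels never eat helix sites
            deleted[run] <- TRUE
          } else if (r < indel_rate) {       # insertion anchored after this site
            len <- stats::rgeom(1, 1 / indel_mean_len) + 1L
            ins[[as.character(s)]] <- collapse0(sample_pool(default_loop_pool(), len))
          }
        }
      }
      res[deleted] <- NA_character_
      kept[d, ] <- res
      inserts[[d]] <- ins
    }
    # assemble true alignment: ancestor-site columns in order, each followed
    # by any member-specific insertion columns anchored at that site
    cols <- list()
    anc_col <- integer(L)  # truth column index of each ancestor site
    emit_insertions <- function(anchor) {
      for (d in seq_len(n)) {
        s <- inserts[[d]][[as.character(anchor)]]
        if (is.null(s)) next
        for (ch in chars(s)) {
          col <- rep("-", n); col[[d]] <- ch
          cols[[length(cols) + 1L]] <<- col
        }
      }
    }
    emit_insertions(0L)
    for (s in seq_len(L)) {
      col <- ifelse(is.na(kept[, s]), "-", kept[, s])
      cols[[length(cols) + 1L]] <- col
      anc_col[[s]] <- length(cols)
      emit_insertions(s)
    }
    m <- do.call(cbind, cols)
    rownames(m) <- ids
    all_gap <- colSums(m != "-") == 0
    anc_col_kept <- cumsum(!all_gap)[anc_col]  # shift after dropping empties
    m <- m[, !all_gap, drop = FALSE]
    truth <- matrix_msa(m)
    # core blocks: TM-segment ancestor columns, per member where a residue
    # is present
    tm_segs <- ancestor$segments[ancestor$segments$type == "tm", ]
    blocks <- list()
    for (i in seq_len(nrow(tm_segs))) {
      crange <- anc_col_kept[tm_segs$start[[i]]:tm_segs$end[[i]]]
      for (d in seq_len(n)) {
        present <- m[d, crange] != "-"
        if (!any(present)) next
        r <- rle(present)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        for (k in which(r$values)) {
          blocks[[length(blocks) + 1L]] <- data.frame(
            id = ids[[d]], start = crange[[starts[[k]]]],
            end = crange[[ends[[k]]]])
        }
      }
    }
    blocks <- if (length(blocks)) do.call(rbind, blocks) else
      data.frame(id = character(), start = integer(), end = integer())
    core <- core_annotation(blocks, ncol = truth$ncol, ids = ids)
    members <- degap(truth)
    members$desc <- rep("synthetic transmembrane protein", n)
    structure(list(ancestor = ancestor, members = members, truth = truth,
                   core = core, sub_rate = sub_rate, indel_rate = indel_rate,
                   tm_multiplier = tm_multiplier, seed = seed),
              class = "tmc_family")
  })
}

#' Simulate a family at a requested pairwise identity
#'
#' Convenience wrapper: samples an ancestor, converts the identity target to
#' a substitution rate via [rate_for_identity()], and evolves the family.
#'
#' @param seed integer seed
#' @param n number of members
#' @param topology a `tmc_topology`
#' @param target_identity expected pairwise identity between members
#' @param indel_rate per-loop-site indel event probability
#' @param prefix id prefix
#' @inheritParams evolve_family
#' @return a `tmc_family`
#' @export
simulate_family <- function(seed = 1, n = 5, topology = topology_model(),
                            target_identity = 0.6, indel_rate = 0.02,
                            tm_multiplier = 0.3, prefix = "seq") {
  anc <- sample_ancestor(topology, seed = seed, id = paste0(prefix, "_anc"))
  rate <- rate_for_identity(target_identity, tm_fraction = mean(anc$is_tm),
                            tm_multiplier = tm_multiplier)
  evolve_family(anc, n = n, sub_rate = rate, indel_rate = indel_rate,
                seed = seed + 1L, tm_multiplier = tm_multiplier,
                prefix = prefix)
}

#' Mean pairwise identity of an alignment
#'
#' Identity is computed over columns where both rows carry residues,
#' averaged over all row pairs.
#' @param aln a `tmc_msa`
#' @return scalar in [0, 1]
#' @export
pairwise_identity <- function(aln) {
  m <- msa_matrix(aln)
  n <- nrow(m)
  vals <- c()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      both <- m[a, ] != "-" & m[b, ] != "-"
      if (!any(both)) next
      vals <- c(vals, mean(m[a, both] == m[b, both]))
    }
  }
  mean(vals)
}

# P(two leaves agree at a site) for branch substitution rates p1, p2
match_prob2 <- function(p1, p2) {
  s1 <- 1 - p1 + p1 / 20
  s2 <- 1 - p2 + p2 / 20
  s1 * s2 + 19 * (p1 / 20) * (p2 / 20)
}

# substitution rate for a relative evolved from the ancestor so that its
# expected identity to the family members (whose own branch rate is
# member_rate) hits `target`; clamps to 0 when the members are so diverged
# that even an exact ancestor copy sits below the target
relative_rate <- function(target, member_rate, tm_fraction,
                          tm_multiplier = 0.3) {
  f <- function(p) {
    tm_fraction * match_prob2(p * tm_multiplier, member_rate * tm_multiplier) +
      (1 - tm_fraction) * match_prob2(p, member_rate) - target
  }
  if (f(0) <= 0) return(0)
  if (f(0.999) >= 0) return(0.999)
  stats::uniroot(f, c(0, 0.999), tol = 1e-9)$root
}

#' Build a mini homolog database for a set of synthetic families
#'
#' The database emulates a keyword-filtered, homolog-rich protein set: it
#' contains every family member, shared ungapped homologs evolved from each
#' family's ancestor so that their identity to the members lands in the
#' 50-90% band hit filtering keeps, and random decoy sequences.
#' Family-derived records carry the keyword `transmembrane` in their
#' descriptions; decoys do not.
#'
#' @param families list of `tmc_family` objects
#' @param n_decoys number of decoy records
#' @param decoy_len decoy length range
#' @param seed integer seed
#' @param relatives_per_member shared homologs generated per family member
#'   (total per family = members x this)
#' @param relative_identity identity band (to the members) the homologs are
#'   drawn in
#' @return a `tmc_sequences` database with keyword-annotated descriptions
#' @export
build_mini_database <- function(families, n_decoys = 10,
                                decoy_len = c(60, 200), seed = 1,
                                relatives_per_member = 2,
                                relative_identity = c(0.60, 0.85)) {
  with_seed(seed, {
    id <- character(); desc <- character(); res <- character()
    for (fi in seq_along(families)) {
      fam <- families[[fi]]
      anc <- fam$ancestor
      tmfrac <- mean(anc$is_tm)
      anc_chars <- chars(anc$residues)
      for (i in seq_len(nrow(fam$members))) {
        id <- c(id, fam$members$id[[i]])
        desc <- c(desc, "synthetic transmembrane protein keyword:transmembrane")
        res <- c(res, fam$members$residues[[i]])
      }
      # shared homologs: independent branches off the ancestor, divergence
      # solved so expected identity to every member falls in-band; being
      # shared across members is what lets profiles carry common signal
      n_rel <- relatives_per_member * nrow(fam$members)
      for (r in seq_len(n_rel)) {
        target <- stats::runif(1, relative_identity[1], relative_identity[2])
        p <- relative_rate(target, fam$sub_rate, tmfrac, fam$tm_multiplier)
        rates <- ifelse(anc$is_tm, p * fam$tm_multiplier, p)
        id <- c(id, sprintf("%s_rel%d", anc$id, r))
        desc <- c(desc, "synthetic transmembrane homolog keyword:transmembrane")
        res <- c(res, collapse0(mutate_residues(anc_chars, rates)))
      }
    }
    for (k in seq_len(n_decoys)) {
      len <- sample_len(decoy_len[1], decoy_len[2])
      id <- c(id, sprintf("decoy%d", k))
      desc <- c(desc, "synthetic soluble decoy protein")
      res <- c(res, collapse0(sample_pool(default_loop_pool(), len)))
    }
    sequence_set(res, id = id, desc = desc)
  })
}
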