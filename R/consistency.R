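# Constraint library: weighted residue-pair constraints between input
# sequences, plus the T-Coffee triplet extension that relays support through
# third sequences (extended weight = primary + sum over intermediates of
# min(w(A,i,C,k), w(C,k,B,j))).

empty_constraints <- function() {
  data.frame(idA = character(), posA = integer(), idB = character(),
             posB = integer(), weight = numeric(), stringsAsFactors = FALSE)
}

#' Construct a constraint library
#'
#' Constraints are stored once per unordered sequence pair, canonicalized so
#' that `idA < idB` lexicographically; lookups are symmetric. Duplicate
#' (idA,posA,idB,posB) entries have their weights summed.
#'
#' @param lengths named integer vector: sequence id -> residue length
#' @param constraints data.frame with columns `idA, posA, idB, posB, weight`
#'   (1-based residue positions, non-negative numeric weights)
#' @return a `tmc_library`
#' @export
constraint_library <- function(lengths, constraints = empty_constraints()) {
  ids <- names(lengths)
  if (is.null(ids) || anyDuplicated(ids)) tmc_error("lengths must be uniquely named")
  cons <- as.data.frame(constraints)
  if (nrow(cons) > 0) {
    if (any(cons$idA == cons$idB)) tmc_error("self-pair constraints are forbidden")
    swap <- cons$idA > cons$idB
    if (any(swap)) {
      cons[swap, c("idA", "posA", "idB", "posB")] <-
        cons[swap, c("idB", "posB", "idA", "posA")]
    }
    unknown <- setdiff(unique(c(cons$idA, cons$idB)), ids)
    if (length(unknown) > 0) {
      tmc_error(sprintf("constraints reference unknown id(s): %s",
                        paste(unknown, collapse = ", ")))
    }
    bad <- cons$posA < 1 | cons$posA > lengths[cons$idA] |
      cons$posB < 1 | cons$posB > lengths[cons$idB]
    if (any(bad)) tmc_error("constraint position outside sequence length")
    if (any(cons$weight < 0)) tmc_error("constraint weights must be non-negative")
    dt <- data.table::as.data.table(cons)
    cons <- as.data.frame(dt[, list(weight = sum(weight)),
                             by = c("idA", "posA", "idB", "posB")])
    cons <- cons[order(cons$idA, cons$posA, cons$idB, cons$posB), ,
                 drop = FALSE]
    rownames(cons) <- NULL
  }
  structure(list(lengths = lengths, constraints = cons), class = "tmc_library")
}

#' @export
print.tmc_library <- function(x, ...) {
  cat(sprintf("tmc_library: %d sequence(s), %d constraint(s)\n",
              length(x$lengths), nrow(x$constraints)))
  invisible(x)
}

# constraints expanded to both orientations (plain data.frame: subsetting
# with local variables must not hit data.table's column-scoping rules)
symmetric_constraints <- function(lib) {
  cons <- lib$constraints
  if (nrow(cons) == 0) return(cons)
  rev <- data.frame(idA = cons$idB, posA = cons$posB,
                    idB = cons$idA, posB = cons$posA,
                    weight = cons$weight, stringsAsFactors = FALSE)
  rbind(cons, rev)
}

#' Look up the weight of a residue-pair constraint
#'
#' @param lib a `tmc_library`
#' @param idA,posA,idB,posB sequence ids and 1-based residue positions
#' @return the stored weight, or 0 if the pair is absent
#' @export
pair_score <- function(lib, idA, posA, idB, posB) {
  for (id in c(idA, idB)) {
    if (!id %in% names(lib$lengths)) tmc_error(sprintf("unknown id '%s'", id))
  }
  if (idA > idB) {
    tmp <- idA; idA <- idB; idB <- tmp
    tmp <- posA; posA <- posB; posB <- tmp
  }
  cons <- lib$constraints
  hit <- cons$idA == idA & cons$posA == posA & cons$idB == idB & cons$posB == posB
  if (any(hit)) sum(cons$weight[hit]) else 0
}

#' Dense weight matrix for one sequence pair
#'
#' @param lib a `tmc_library`
#' @param idA,idB sequence ids
#' @param extended if TRUE, return lazily extended weights for this pair
#'   (identical to the pair's slice of [extend_library()])
#' @return numeric matrix `length(A) x length(B)`
#' @export
pair_weight_matrix <- function(lib, idA, idB, extended = FALSE) {
  for (id in c(idA, idB)) {
    if (!id %in% names(lib$lengths)) tmc_error(sprintf("unknown id '%s'", id))
  }
  W <- matrix(0, nrow = lib$lengths[[idA]], ncol = lib$lengths[[idB]])
  sym <- symmetric_constraints(lib)
  if (nrow(sym) > 0) {
    direct <- sym[sym$idA == idA & sym$idB == idB, ]
    if (nrow(direct) > 0) {
      W[cbind(direct$posA, direct$posB)] <-
        W[cbind(direct$posA, direct$posB)] + direct$weight
    }
    if (extended) {
      rel <- relay_contributions(sym, idA, idB)
      if (nrow(rel) > 0) {
        W[cbind(rel$posA, rel$posB)] <- W[cbind(rel$posA, rel$posB)] + rel$weight
      }
    }
  }
  W
}

# relayed weight for pair (idA, idB): join A->C with C->B on (C, k),
# min the two weights, sum over intermediates
relay_contributions <- function(sym, idA, idB) {
  left <- sym[sym$idA == idA & sym$idB != idB, ]
  right <- sym[sym$idB == idB & sym$idA != idA, ]
  if (nrow(left) == 0 || nrow(right) == 0) {
    return(data.frame(posA = integer(), posB = integer(), weight = numeric()))
  }
  left <- data.table::as.data.table(left)
  right <- data.table::as.data.table(right)
  data.table::setnames(left, c("idA", "posA", "C", "k", "w1"))
  data.table::setnames(right, c("C", "k", "idB", "posB", "w2"))
  j <- merge(left, right, by = c("C", "k"), allow.cartesian = TRUE)
  if (nrow(j) == 0) {
    return(data.frame(posA = integer(), posB = integer(), weight = numeric()))
  }
  j[, "w" := pmin(j$w1, j$w2)]
  out <- j[, list(weight = sum(w)), by = c("posA", "posB")]
  as.data.frame(out)
}

#' Triplet-extend a constraint library
#'
#' For every constrained pair (A,i,B,j) the extended weight adds, for each
#' third sequence C and position k, min(w(A,i,C,k), w(C,k,B,j)) — relayed
#' support through intermediates. New pairs can appear (two constraints
#' sharing an intermediate residue induce a relayed constraint even if the
#' direct weight was 0). Extended weights are never smaller than primary
#' weights, and symmetry is preserved. Extension is not idempotent.
#'
#' @param lib a `tmc_library`
#' @return a new `tmc_library` with extended weights
#' @export
extend_library <- function(lib) {
  sym <- symmetric_constraints(lib)
  if (nrow(sym) == 0) return(lib)
  left <- data.table::as.data.table(sym)
  right <- data.table::as.data.table(sym)
  data.table::setnames(left, c("idA", "posA", "C", "k", "w1"))
  data.table::setnames(right, c("C", "k", "idB", "posB", "w2"))
  j <- merge(left, right, by = c("C", "k"), allow.cartesian = TRUE)
  j <- j[j$idA != j$idB, ]
  relayed <- if (nrow(j) > 0) {
    j[, "w" := pmin(j$w1, j$w2)]
    j[, list(weight = sum(w)), by = c("idA", "posA", "idB", "posB")]
  } else {
    data.table::as.data.table(empty_constraints())
  }
  all_cons <- data.table::rbindlist(list(
    data.table::as.data.table(lib$constraints), # canonical orientation only
    relayed[relayed$idA < relayed$idB, ]))      # keep one orientation
  merged <- all_cons[, list(weight = sum(weight)),
                     by = c("idA", "posA", "idB", "posB")]
  constraint_library(lib$lengths, as.data.frame(merged))
}

#' Extract thresholded posterior cells as library constraints
#'
#' Cells of the posterior matrix strictly greater than `threshold` become
#' constraints; weights are the posterior scaled to integer percent
#' (round half up).
#'
#' @param post posterior matrix (rows = positions of A, cols = positions of B)
#' @param idA,idB sequence ids
#' @param threshold posterior cutoff in (0, 1]; strictly-greater comparison
#' @return data.frame of constraints (`idA posA idB posB weight`)
#' @export
extract_constraints <- function(post, idA, idB, threshold = 0.99) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    tmc_config_error("posterior threshold must lie in (0, 1]")
  }
  keep <- which(post > threshold, arr.ind = TRUE)
  if (nrow(keep) == 0) return(empty_constraints())
  data.frame(idA = idA, posA = as.integer(keep[, 1]),
             idB = idB, posB = as.integer(keep[, 2]),
             weight = floor(post[keep] * 100 + 0.5),  # round half up
             stringsAsFactors = FALSE)
}

#' Build the primary constraint library from extended profiles
#'
#' Runs the profile pair-HMM on every unordered pair of profiles and pools
#' the thresholded posterior constraints.
#'
#' @param profiles named list of `tmc_profile` objects (>= 2)
#' @param params pair-HMM parameters, see [pairhmm_params()]
#' @param threshold posterior cutoff (strictly greater)
#' @return a `tmc_library`
#' @export
build_primary_library <- function(profiles, params = pairhmm_params(),
                                  threshold = 0.99) {
  ids <- names(profiles)
  if (length(ids) < 2) tmc_error("need at least 2 profiles")
  lengths <- stats::setNames(
    vapply(profiles, function(p) ncol(p$freq), integer(1)), ids)
  pieces <- list()
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (a >= b) next
      fb <- forward_backward(profiles[[a]], profiles[[b]], params)
      pieces[[length(pieces) + 1L]] <-
        extract_constraints(fb$posterior, ids[[a]], ids[[b]], threshold)
    }
  }
  cons <- if (length(pieces)) do.call(rbind, pieces) else empty_constraints()
  constraint_library(lengths, cons)
}
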