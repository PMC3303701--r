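# Profile-adapted ProbCons-style pair-HMM: bi-phasic affine gap model
# (two insert-state pairs with distinct open/extend probabilities), expected
# likelihood-ratio match emissions over profile columns, forward-backward
# posterior decoding, and the 0.99-posterior constraint threshold applied
# downstream by the consistency module.

# BLOSUM62 joint target frequencies, reconstructed from the half-bit score
# matrix: p(a,b) proportional to 2^(S(a,b)/2), normalised; background
# frequencies are the marginals of the joint, which makes the
# likelihood-ratio emission model exactly self-consistent.
blosum62_joint <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      S <- e$BLOSUM62[AA20, AA20]
      P <- 2^(S / 2)
      P <- (P + t(P)) / 2
      cache <<- P / sum(P)
    }
    cache
  }
})

#' Pair-HMM parameter set
#'
#' Defaults follow the published ProbCons bi-phasic gap parameterisation:
#' two insert-state pairs with distinct gap-open and gap-extend
#' probabilities (short gaps: open 0.0119511066, extend 0.3965826333; long
#' gaps: open 0.008008334786, extend 0.8988758326). The joint residue-pair
#' emission matrix is reconstructed from BLOSUM62 target frequencies and the
#' background is its marginal distribution (see the methods vignette for why
#' this substitution is made and what it implies).
#'
#' @param gap_open_short,gap_extend_short short-gap state probabilities
#' @param gap_open_long,gap_extend_long long-gap state probabilities
#' @param emission symmetric positive 20x20 joint residue-pair probability
#'   matrix (rows/cols in `AA20` order), summing to 1
#' @param background positive background frequencies over `AA20`, summing
#'   to 1; defaults to the emission marginals
#' @param occupancy if TRUE (default) the match emission between two profile
#'   columns is scaled by (1 - gapA)(1 - gapB), down-weighting sparsely
#'   populated profile positions
#' @return a `tmc_hmm_params` list
#' @export
pairhmm_params <- function(gap_open_short = 0.0119511066,
                           gap_extend_short = 0.3965826333,
                           gap_open_long = 0.008008334786,
                           gap_extend_long = 0.8988758326,
                           emission = blosum62_joint(),
                           background = NULL,
                           occupancy = TRUE) {
  if (2 * gap_open_short + 2 * gap_open_long >= 1) {
    tmc_config_error("gap-open probabilities too large: match state has no self-transition mass")
  }
  for (p in c(gap_open_short, gap_extend_short, gap_open_long, gap_extend_long)) {
    if (p <= 0 || p >= 1) tmc_config_error("transition probabilities must lie in (0,1)")
  }
  emission <- as.matrix(emission)
  if (!isTRUE(all.equal(emission, t(emission), tolerance = 1e-8)) ||
      any(emission <= 0) || abs(sum(emission) - 1) > 1e-6) {
    tmc_config_error("emission matrix must be symmetric, positive, and sum to 1")
  }
  if (is.null(background)) background <- rowSums(emission)
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-9) {
    tmc_config_error("background frequencies must be positive and sum to 1")
  }
  lr <- emission / outer(background, background)
  structure(list(gap_open_short = gap_open_short,
                 gap_extend_short = gap_extend_short,
                 gap_open_long = gap_open_long,
                 gap_extend_long = gap_extend_long,
                 emission = emission, background = background,
                 log_odds = log(lr), occupancy = occupancy),
            class = "tmc_hmm_params")
}

#' Read pair-HMM parameters from a key-value config file
#'
#' Recognised keys: `gap_open_short`, `gap_extend_short`, `gap_open_long`,
#' `gap_extend_long`, `occupancy` (0/1), `emission_matrix` (path to a TSV
#' with 20 rows/cols in `AA20` order, resolved relative to the config file).
#' Unknown keys are rejected.
#'
#' @param path config file path
#' @return a `tmc_hmm_params` list
#' @export
read_pairhmm_params <- function(path) {
  kv <- read_keyvalue(path)
  known <- c("gap_open_short", "gap_extend_short", "gap_open_long",
             "gap_extend_long", "occupancy", "emission_matrix")
  unknown <- setdiff(names(kv), known)
  if (length(unknown) > 0) {
    tmc_config_error(sprintf("unknown parameter key(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  args <- list()
  for (k in setdiff(known, c("occupancy", "emission_matrix"))) {
    if (k %in% names(kv)) args[[k]] <- as.numeric(kv[[k]])
  }
  if ("occupancy" %in% names(kv)) args$occupancy <- kv[["occupancy"]] %in% c("1", "true", "TRUE")
  if ("emission_matrix" %in% names(kv)) {
    mpath <- kv[["emission_matrix"]]
    if (!file.exists(mpath)) mpath <- file.path(dirname(path), kv[["emission_matrix"]])
    m <- as.matrix(utils::read.table(mpath, sep = "\t", header = TRUE,
                                     row.names = 1, check.names = FALSE))
    args$emission <- m[AA20, AA20]
  }
  do.call(pairhmm_params, args)
}

read_keyvalue <- function(path) {
  if (!file.exists(path)) tmc_error(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(stats::setNames(character(), character()))
  parts <- regmatches(lines, regexec("^([^=\\s]+)\\s*=\\s*(.*)$", lines,
                                     perl = TRUE))
  if (any(lengths(parts) != 3)) tmc_config_error(sprintf("cannot parse config '%s'", path))
  stats::setNames(vapply(parts, `[[`, character(1), 3),
                  vapply(parts, `[[`, character(1), 2))
}

# renormalize a 21-letter profile column matrix over the 20 residues;
# returns list(fhat = 20 x L, gap = length-L gap mass, dead = columns whose
# residue mass is zero)
renormalize_columns <- function(freq) {
  f20 <- freq[seq_len(20), , drop = FALSE]
  mass <- colSums(f20)
  dead <- mass <= 0
  mass[dead] <- 1
  fhat <- sweep(f20, 2, mass, "/")
  list(fhat = fhat, gap = freq[21, ], dead = dead)
}

#' Expected match-emission likelihood ratio between two profile columns
#'
#' Computes sum over residue pairs of fA(a) fB(b) p(a,b) / (q(a) q(b)),
#' where fA, fB are the column frequencies renormalized over the 20
#' residues (gap mass removed). A column with all mass on the gap symbol
#' falls back to the neutral score 1.
#'
#' @param colA,colB 21-letter profile frequency vectors (20 residues + gap)
#' @param params a `tmc_hmm_params`
#' @return positive scalar
#' @export
column_emission_score <- function(colA, colB, params = pairhmm_params()) {
  lr <- exp(params$log_odds)
  a20 <- colA[seq_len(20)]; b20 <- colB[seq_len(20)]
  sa <- sum(a20); sb <- sum(b20)
  if (sa <= 0 || sb <= 0) {
    message("all-gap profile column: neutral emission score 1 used")
    return(1)
  }
  as.numeric((a20 / sa) %*% lr %*% (b20 / sb))
}

# log-odds emission matrix between all column pairs of two profiles
profile_log_emissions <- function(profA, profB, params) {
  ra <- renormalize_columns(profA$freq)
  rb <- renormalize_columns(profB$freq)
  lr <- exp(params$log_odds)
  E <- t(ra$fhat) %*% lr %*% rb$fhat
  E[ra$dead, ] <- 1  # all-gap columns emit neutrally
  E[, rb$dead] <- 1
  if (isTRUE(params$occupancy)) {
    occ <- outer(1 - ra$gap, 1 - rb$gap)
    occ[ra$dead, ] <- 1
    occ[, rb$dead] <- 1
    E <- E * occ
  }
  log(E)
}

#' Forward-backward posterior match probabilities between two profiles
#'
#' Runs the 5-state bi-phasic pair-HMM over the two extended profiles in log
#' space and returns, for every pair of positions (i of A, j of B), the
#' posterior probability that they are aligned in the match state.
#'
#' @param profA,profB `tmc_profile` objects (see [build_profile()]); plain
#'   sequences can be lifted with [profile_from_sequence()]
#' @param params a `tmc_hmm_params`
#' @return list with `posterior` (length(A) x length(B) matrix),
#'   `loglik_forward` and `loglik_backward` (log-odds totals, equal within
#'   numerical tolerance)
#' @export
forward_backward <- function(profA, profB, params = pairhmm_params()) {
  if (ncol(profA$freq) == 0 || ncol(profB$freq) == 0) {
    tmc_error("profiles must be non-empty")
  }
  logE <- profile_log_emissions(profA, profB, params)
  .fb_pairhmm_cpp(logE, params$gap_open_short, params$gap_open_long,
                  params$gap_extend_short, params$gap_extend_long)
}
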