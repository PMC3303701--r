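# Shared constants and small helpers.

# let data.table's [ dispatch see this package as data.table-aware
.datatable.aware <- TRUE

#' Standard amino-acid alphabet
#'
#' The 20 standard residue letters in the fixed order used by profile
#' matrices and the pair-HMM emission model.
#' @keywords internal
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# 21-letter profile alphabet: 20 residues + gap
PROFILE_ALPHABET <- c(AA20, "-")

GAP <- "-"

# letters collapsed to 'X' on read (no emission model for them)
NONSTANDARD_AA <- c("B", "Z", "U", "O", "J")

tmc_error <- function(msg, class = "tmc_data_error", call. = FALSE) {
  stop(structure(class = c(class, "tmc_error", "error", "condition"),
                 list(message = msg, call = if (call.) sys.call(-1))))
}

tmc_usage_error <- function(msg) tmc_error(msg, class = "tmc_usage_error")

tmc_config_error <- function(msg) tmc_error(msg, class = "tmc_config_error")

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global `.Random.seed`, so generator functions are
#' pure functions of their arguments and do not disturb the caller's RNG
#' stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# split a residue string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# paste a character vector back into one string
collapse0 <- function(x) paste0(x, collapse = "")

# uppercase, strip '*', map nonstandard letters to X; error on anything else
canonicalize_residues <- function(x, id = "?") {
  x <- toupper(gsub("*", "", x, fixed = TRUE))
  cs <- chars(x)
  cs[cs %in% NONSTANDARD_AA] <- "X"
  bad <- setdiff(unique(cs), c(AA20, "X"))
  if (length(bad) > 0) {
    tmc_error(sprintf("sequence '%s' contains invalid residue letters: %s",
                      id, paste(bad, collapse = ", ")))
  }
  collapse0(cs)
}
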