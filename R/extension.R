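# Homology extension: run (or ingest) a database search per input sequence,
# filter the hits on identity/coverage/e-value, and stack the surviving hit
# segments into a per-query position-wise profile ("one-against-all MSA"
# trimmed to query coordinates).

# ---- search backends -------------------------------------------------------

#' Built-in local-alignment search backend
#'
#' Affine-gap Smith-Waterman (Gotoh) over an in-memory FASTA database,
#' scored with BLOSUM62 (gap open 11 / extend 1). The reported e-values
#' are Karlin-Altschul surrogates derived from the raw score
#' (lambda = 0.267, K = 0.041, the gapped BLOSUM62-11-1 constants); parity
#' with blast+ statistics is not claimed. Exists so the whole pipeline runs
#' with no external binary.
#'
#' @param db a `tmc_sequences` object or path to a FASTA file
#' @param score_matrix substitution matrix over the 20 residues + `X`
#'   (default BLOSUM62 from Biostrings)
#' @param gap_open,gap_extend affine gap costs (a length-k gap costs
#'   `gap_open + k * gap_extend`)
#' @return a database handle for [search_hits()]
#' @export
builtin_database <- function(db, score_matrix = NULL, gap_open = 11,
                             gap_extend = 1) {
  if (is.character(db)) db <- read_fasta(db)
  if (!inherits(db, "tmc_sequences")) tmc_error("db must be sequences or a FASTA path")
  if (is.null(score_matrix)) {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    score_matrix <- get("BLOSUM62", envir = environment())
  }
  alpha <- c(AA20, "X")
  score_matrix <- score_matrix[alpha, alpha]
  structure(list(seqs = db, mat = score_matrix,
                 codes = lapply(db$residues, function(r) {
                   match(chars(r), alpha) - 1L
                 }),
                 gap_open = gap_open, gap_extend = gap_extend),
            class = c("tmc_db_builtin", "tmc_db"))
}

#' External blast+ search backend
#'
#' Formats the database once with `makeblastdb` and runs `blastp` per query
#' with default parameters, requesting tabular output extended with the
#' aligned segment strings.
#'
#' @param fasta path to the database FASTA file
#' @param workdir directory for the formatted database (default: tempdir)
#' @return a database handle for [search_hits()]
#' @export
blast_database <- function(fasta, workdir = tempfile("blastdb")) {
  for (exe in c("makeblastdb", "blastp")) {
    if (Sys.which(exe) == "") {
      tmc_error(sprintf("search backend 'blast' unavailable: '%s' not on PATH", exe))
    }
  }
  if (!file.exists(fasta)) tmc_error(sprintf("no such file: %s", fasta))
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  prefix <- file.path(workdir, "db")
  status <- system2("makeblastdb",
                    c("-in", shQuote(fasta), "-dbtype", "prot",
                      "-out", shQuote(prefix)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) tmc_error("makeblastdb failed")
  structure(list(prefix = prefix), class = c("tmc_db_blast", "tmc_db"))
}

#' Precomputed-hits search backend
#'
#' A directory of extended tabular hit files named `<query id>.tsv`
#' (see [read_tabular_hits()]); a missing file means no hits for that query.
#'
#' @param dir directory path
#' @return a database handle for [search_hits()]
#' @export
hits_database <- function(dir) {
  if (!dir.exists(dir)) tmc_error(sprintf("no such directory: %s", dir))
  structure(list(dir = dir), class = c("tmc_db_hits", "tmc_db"))
}

# gapped BLOSUM62-11-1 Karlin-Altschul constants for the surrogate e-value
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Search a query sequence against a database
#'
#' @param query one-row `tmc_sequences` object (or an id-named residue
#'   string)
#' @param db a database handle from [builtin_database()],
#'   [blast_database()] or [hits_database()]
#' @param evalue_max report only hits with e-value at or below this ceiling
#' @return a `tmc_hits` data.frame (coverage filled from the query length);
#'   self-hits are permitted, an empty database yields an empty table
#' @export
search_hits <- function(query, db, evalue_max = 10) {
  if (!inherits(query, "tmc_sequences")) {
    query <- sequence_set(query)
  }
  if (nrow(query) != 1) tmc_error("search_hits expects a single query sequence")
  UseMethod("search_hits", db)
}

#' @export
search_hits.default <- function(query, db, evalue_max = 10) {
  tmc_error("unknown search backend (use builtin_database/blast_database/hits_database)")
}

empty_hit_frame <- function() {
  data.frame(qid = character(), sid = character(), pident = numeric(),
             length = integer(), qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(), evalue = numeric(),
             qseq = character(), sseq = character(),
             stringsAsFactors = FALSE)
}

#' @export
search_hits.tmc_db_builtin <- function(query, db, evalue_max = 10) {
  qres <- query$residues[[1]]
  qid <- query$id[[1]]
  qlen <- nchar(qres)
  if (nrow(db$seqs) == 0) return(hit_table(empty_hit_frame(),
                                           stats::setNames(qlen, qid)))
  alpha <- c(AA20, "X")
  qchars <- chars(qres)
  qcode <- match(qchars, alpha) - 1L
  rows <- vector("list", nrow(db$seqs))
  for (i in seq_len(nrow(db$seqs))) {
    al <- .sw_local_cpp(qcode, db$codes[[i]], db$mat, db$gap_open,
                        db$gap_extend)
    if (al$qend == 0) next
    evalue <- KA_K * qlen * nchar(db$seqs$residues[[i]]) *
      exp(-KA_LAMBDA * al$score)
    if (evalue > evalue_max) next
    schars <- chars(db$seqs$residues[[i]])
    qa <- ifelse(al$qpath > 0, qchars[pmax(al$qpath, 1)], "-")
    sa <- ifelse(al$spath > 0, schars[pmax(al$spath, 1)], "-")
    nid <- sum(qa == sa & qa != "-")
    rows[[i]] <- data.frame(
      qid = qid, sid = db$seqs$id[[i]],
      pident = 100 * nid / length(qa), length = length(qa),
      qstart = al$qstart, qend = al$qend,
      sstart = al$sstart, send = al$send,
      evalue = evalue, qseq = collapse0(qa), sseq = collapse0(sa),
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) do.call(rbind, rows) else empty_hit_frame()
  hit_table(df, stats::setNames(qlen, qid))
}

#' @export
search_hits.tmc_db_blast <- function(query, db, evalue_max = 10) {
  qfile <- tempfile(fileext = ".fasta")
  on.exit(unlink(qfile))
  write_fasta(query, qfile)
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out), add = TRUE)
  status <- system2("blastp",
                    c("-query", shQuote(qfile), "-db", shQuote(db$prefix),
                      "-evalue", format(evalue_max), "-outfmt",
                      shQuote("6 qseqid sseqid pident length qstart qend sstart send evalue qseq sseq"),
                      "-out", shQuote(out)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) tmc_error("blastp failed")
  read_tabular_hits(out, query_lengths = seq_lengths(query))
}

#' @export
search_hits.tmc_db_hits <- function(query, db, evalue_max = 10) {
  path <- file.path(db$dir, paste0(query$id[[1]], ".tsv"))
  if (!file.exists(path)) {
    return(search_hits.tmc_db_builtin(query,
                                      builtin_database(query[0, , drop = FALSE]),
                                      evalue_max))
  }
  hits <- read_tabular_hits(path, query_lengths = seq_lengths(query))
  hits <- hits[hits$qid == query$id[[1]] & hits$evalue <= evalue_max, ,
               drop = FALSE]
  structure(hits, class = c("tmc_hits", "data.frame"))
}

# ---- hit filtering ---------------------------------------------------------

#' Filter search hits on identity, coverage and e-value
#'
#' Keeps hits with identity between `id_min` and `id_max` (inclusive on both
#' ends) and coverage strictly greater than `cov_min`; if `evalue_max` is
#' non-NULL, additionally requires e-value at or below it (NULL reproduces
#' the unfiltered "NONE" setting). Input order is preserved.
#'
#' @param hits a `tmc_hits` data.frame with coverage filled in
#' @param id_min,id_max percent-identity bounds (inclusive)
#' @param cov_min percent-coverage bound (strict)
#' @param evalue_max e-value ceiling or NULL for no e-value filtering
#' @return the kept subset, same class
#' @export
filter_hits <- function(hits, id_min = 50, id_max = 90, cov_min = 70,
                        evalue_max = NULL) {
  if (id_min > id_max) tmc_config_error("id_min must not exceed id_max")
  if (nrow(hits) == 0) return(hits)
  if (anyNA(hits$coverage)) {
    tmc_error("hit coverage unknown: supply query lengths when reading hits")
  }
  keep <- hits$pident >= id_min & hits$pident <= id_max &
    hits$coverage > cov_min
  if (!is.null(evalue_max)) keep <- keep & hits$evalue <= evalue_max
  structure(hits[keep, , drop = FALSE], class = c("tmc_hits", "data.frame"))
}

# ---- profile construction --------------------------------------------------

# background used to spread mass of unknown residues ('X') across the 20
# letters, keeping emissions neutral for unknowns
x_background <- function() rowSums(blosum62_joint())

#' Build an extended profile from a query and its kept hits
#'
#' Each hit contributes one symbol at every query position: inside its query
#' span, the aligned subject residue (or a gap symbol where the subject has
#' a gap); outside its span, a gap. Subject residues opposite query gaps are
#' discarded, so the profile always has exactly one column per query
#' residue. The query itself is counted as one row. Frequencies are counts
#' over the 21-letter alphabet (20 residues + gap) divided by the rows
#' counted at that column; `X` residues contribute background-distributed
#' mass.
#'
#' @param query one-row `tmc_sequences` object
#' @param hits kept hits for this query (see [filter_hits()])
#' @return a `tmc_profile`: list with `query`, `freq` (21 x L matrix, rows
#'   named by residue letters + `-`), `support` (non-gap contributors per
#'   column) and `nhits`
#' @export
build_profile <- function(query, hits = NULL) {
  if (!inherits(query, "tmc_sequences")) query <- sequence_set(query)
  if (nrow(query) != 1) tmc_error("build_profile expects a single query")
  qres <- chars(query$residues[[1]])
  L <- length(qres)
  counts <- matrix(0, nrow = 21, ncol = L,
                   dimnames = list(PROFILE_ALPHABET, NULL))
  support <- rep(1L, L)  # the query occupies every column
  bg <- x_background()
  add_symbol <- function(sym, pos, w = 1) {
    if (sym == "X") counts[seq_len(20), pos] <<- counts[seq_len(20), pos] + w * bg
    else counts[sym, pos] <<- counts[sym, pos] + w
  }
  for (i in seq_len(L)) add_symbol(qres[[i]], i)
  nhits <- if (is.null(hits)) 0L else nrow(hits)
  if (nhits > 0) {
    for (h in seq_len(nhits)) {
      qa <- chars(hits$qseq[[h]]); sa <- chars(hits$sseq[[h]])
      span <- hits$qstart[[h]]:hits$qend[[h]]
      degapped <- qa[qa != "-"]
      if (length(degapped) != length(span) ||
          !all(degapped == qres[span] | degapped == "X" | qres[span] == "X")) {
        tmc_error(sprintf(
          "hit %s->%s: aligned query segment does not match query residues over span %d..%d",
          hits$qid[[h]], hits$sid[[h]], hits$qstart[[h]], hits$qend[[h]]))
      }
      qpos <- hits$qstart[[h]] - 1L
      for (k in seq_along(qa)) {
        if (qa[[k]] == "-") next  # subject residue opposite a query gap: drop
        qpos <- qpos + 1L
        if (sa[[k]] == "-") {
          counts["-", qpos] <- counts["-", qpos] + 1
        } else {
          add_symbol(sa[[k]], qpos)
          support[[qpos]] <- support[[qpos]] + 1L
        }
      }
      outside <- setdiff(seq_len(L), span)
      if (length(outside) > 0) counts["-", outside] <- counts["-", outside] + 1
    }
  }
  freq <- sweep(counts, 2, colSums(counts), "/")
  structure(list(query = query, freq = freq, support = support,
                 nhits = nhits), class = "tmc_profile")
}

#' @export
print.tmc_profile <- function(x, ...) {
  cat(sprintf("tmc_profile: query '%s', %d column(s), %d hit(s)\n",
              x$query$id[[1]], ncol(x$freq), x$nhits))
  invisible(x)
}

#' Degenerate self-profile of a sequence (extension off)
#' @param query one-row `tmc_sequences` or an id-named residue string
#' @return a `tmc_profile` with point-mass columns
#' @export
profile_from_sequence <- function(query) build_profile(query, NULL)

#' Homology-extend every input sequence into a profile
#'
#' Searches each sequence against the database, filters the hits, and
#' builds one extended profile per sequence; sequences with no surviving
#' hits get the degenerate self-profile. The stage is deterministic.
#'
#' @param seqs a `tmc_sequences` object with unique ids
#' @param db a database handle, or NULL to disable extension
#' @param id_min,id_max,cov_min,evalue_max hit-filter parameters (see
#'   [filter_hits()])
#' @param evalue_search e-value ceiling handed to the search backend
#' @param max_hits optional cap on kept hits per query (default unlimited)
#' @param threads number of worker processes for the per-sequence searches;
#'   results are independent of this value
#' @return named list of `tmc_profile`, one per input sequence
#' @export
extend_all <- function(seqs, db = NULL, id_min = 50, id_max = 90,
                       cov_min = 70, evalue_max = NULL, evalue_search = 10,
                       max_hits = Inf, threads = 1) {
  if (anyDuplicated(seqs$id)) tmc_error("sequence ids must be unique")
  one <- function(i) {
    q <- seqs[i, , drop = FALSE]
    class(q) <- c("tmc_sequences", "data.frame")
    if (is.null(db)) return(build_profile(q, NULL))
    hits <- search_hits(q, db, evalue_max = evalue_search)
    kept <- filter_hits(hits, id_min = id_min, id_max = id_max,
                        cov_min = cov_min, evalue_max = evalue_max)
    if (is.finite(max_hits) && nrow(kept) > max_hits) {
      kept <- kept[order(kept$evalue)[seq_len(max_hits)], , drop = FALSE]
    }
    build_profile(q, kept)
  }
  idx <- seq_len(nrow(seqs))
  profiles <- if (threads > 1) {
    parallel::mclapply(idx, one, mc.cores = threads)
  } else {
    lapply(idx, one)
  }
  stats::setNames(profiles, seqs$id)
}

# ---- keyword database filtering --------------------------------------------

#' Keep only records whose description carries a keyword
#'
#' Token-based, case-insensitive match: descriptions are split on
#' whitespace, commas and semicolons; a token matches either whole or after
#' stripping a `key:` prefix (so `keyword:transmembrane` matches
#' `transmembrane`). `transmembrane-like` does not match `transmembrane`.
#'
#' @param seqs a `tmc_sequences` object
#' @param keyword the keyword (e.g. `"transmembrane"`)
#' @return the matching subset, order preserved (possibly empty)
#' @export
filter_database_by_keyword <- function(seqs, keyword) {
  kw <- tolower(keyword)
  keep <- vapply(seqs$desc, function(d) {
    toks <- tolower(strsplit(d, "[\\s,;]+", perl = TRUE)[[1]])
    stripped <- sub("^[a-z0-9_]+:", "", toks)
    any(toks == kw | stripped == kw)
  }, logical(1), USE.NAMES = FALSE)
  out <- seqs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tmc_sequences", "data.frame")
  out
}
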