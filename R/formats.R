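# Readers and writers for every external representation the tool touches:
# FASTA sequence sets, aligned FASTA / Clustal blocks, core-annotation XML,
# tabular search hits, and the constraint-library text format.
#
# Coordinate convention: everything user-visible and everything internal is
# 1-based inclusive (the R convention); external formats already use 1-based
# inclusive coordinates so no conversion layer is needed.

# ---- sequence sets ---------------------------------------------------------

#' Construct a sequence set
#'
#' @param residues character vector of residue strings (uppercase; `*`
#'   stripped; nonstandard letters B/Z/U/O/J mapped to `X`)
#' @param id unique sequence identifiers
#' @param desc free-text descriptions (defaults to empty)
#' @return a `tmc_sequences` object: a data.frame with columns `id`, `desc`,
#'   `residues`
#' @export
sequence_set <- function(residues, id = names(residues), desc = NULL) {
  if (is.null(id)) tmc_error("sequence ids are required")
  id <- as.character(id)
  if (anyDuplicated(id)) {
    tmc_error(sprintf("duplicate sequence id(s): %s",
                      paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  if (is.null(desc)) desc <- rep("", length(id))
  residues <- vapply(seq_along(residues), function(i) {
    canonicalize_residues(residues[[i]], id[[i]])
  }, character(1))
  if (any(nchar(residues) == 0)) {
    tmc_error(sprintf("empty sequence(s): %s",
                      paste(id[nchar(residues) == 0], collapse = ", ")))
  }
  if (any(grepl("-", residues, fixed = TRUE))) {
    tmc_error("sequences must not contain gap characters")
  }
  structure(data.frame(id = id, desc = as.character(desc),
                       residues = residues, stringsAsFactors = FALSE),
            class = c("tmc_sequences", "data.frame"))
}

#' @export
print.tmc_sequences <- function(x, ...) {
  cat(sprintf("tmc_sequences: %d sequence(s), lengths %d..%d\n",
              nrow(x), min(nchar(x$residues)), max(nchar(x$residues))))
  invisible(x)
}

seq_lengths <- function(seqs) {
  stats::setNames(nchar(seqs$residues), seqs$id)
}

get_residues <- function(seqs, id) {
  i <- match(id, seqs$id)
  if (is.na(i)) tmc_error(sprintf("unknown sequence id '%s'", id))
  seqs$residues[[i]]
}

#' Read protein sequences from a FASTA file
#'
#' Residues are uppercased, `*` stop characters stripped, and nonstandard
#' letters (B, Z, U, O, J) mapped to `X`. Record order is preserved.
#'
#' @param path path to a FASTA file
#' @return a `tmc_sequences` object
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) tmc_error(sprintf("no such file: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) tmc_error(sprintf(
                    "failed to parse FASTA '%s': %s", path, conditionMessage(e))))
  if (length(set) == 0) tmc_error(sprintf("FASTA file '%s' is empty", path))
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  sequence_set(as.character(set), id = id, desc = desc)
}

#' Write sequences to a FASTA file
#'
#' @param seqs a `tmc_sequences` object
#' @param path output path
#' @param width line-wrap width
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    hdr <- if (nzchar(seqs$desc[[i]])) paste(seqs$id[[i]], seqs$desc[[i]]) else seqs$id[[i]]
    writeLines(paste0(">", hdr), con)
    s <- seqs$residues[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# ---- multiple alignments ---------------------------------------------------

#' Construct a multiple alignment
#'
#' @param rows named character vector of gapped strings (names are sequence
#'   ids); all rows must have equal length
#' @return a `tmc_msa` object: list with `ids`, `rows` (named gapped strings)
#'   and `ncol`
#' @export
msa <- function(rows) {
  ids <- names(rows)
  if (is.null(ids) || anyDuplicated(ids)) {
    tmc_error("alignment rows must carry unique sequence ids")
  }
  len <- nchar(rows)
  if (length(unique(len)) != 1) {
    off <- ids[len != len[[1]]][1]
    tmc_error(sprintf("alignment rows have unequal lengths (e.g. '%s')", off))
  }
  structure(list(ids = ids, rows = rows, ncol = unname(len[[1]])),
            class = "tmc_msa")
}

#' @export
print.tmc_msa <- function(x, ...) {
  cat(sprintf("tmc_msa: %d row(s) x %d column(s)\n", length(x$ids), x$ncol))
  invisible(x)
}

#' Remove gaps from an alignment, recovering the input sequences
#' @param aln a `tmc_msa`
#' @return a `tmc_sequences` object in row order
#' @export
degap <- function(aln) {
  sequence_set(gsub("-", "", aln$rows, fixed = TRUE), id = aln$ids)
}

# character matrix view (rows = sequences, cols = alignment columns)
msa_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln$rows), "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

matrix_msa <- function(m) {
  msa(stats::setNames(apply(m, 1, collapse0), rownames(m)))
}

#' Read a multiple alignment (aligned FASTA or Clustal block format)
#'
#' The format is sniffed from the first non-blank line: a `>` means aligned
#' FASTA, anything else is parsed as Clustal-style blocks.
#'
#' @param path input path
#' @return a `tmc_msa` object
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) tmc_error(sprintf("no such file: %s", path))
  lines <- readLines(path)
  nonblank <- lines[nzchar(trimws(lines))]
  if (length(nonblank) == 0) tmc_error(sprintf("alignment file '%s' is empty", path))
  if (startsWith(nonblank[[1]], ">")) {
    set <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(set))
    rows <- stats::setNames(toupper(as.character(set)), ids)
  } else {
    # Clustal: optional CLUSTAL header, then blocks of "id  chunk"
    body <- grep("^(CLUSTAL|MUSCLE)", lines, value = TRUE, invert = TRUE)
    body <- body[nzchar(trimws(body))]
    body <- grep("^\\s", body, value = TRUE, invert = TRUE)  # conservation line
    parts <- regmatches(body, regexec("^(\\S+)\\s+(\\S+)", body))
    parts <- parts[lengths(parts) == 3]
    if (length(parts) == 0) tmc_error(sprintf("cannot parse alignment '%s'", path))
    ids <- vapply(parts, `[[`, character(1), 2)
    chunk <- vapply(parts, `[[`, character(1), 3)
    chunk <- gsub("[0-9]+$", "", chunk)  # trailing cumulative counts
    uid <- unique(ids)
    rows <- stats::setNames(vapply(uid, function(u) {
      toupper(collapse0(chunk[ids == u]))
    }, character(1)), uid)
  }
  rows <- gsub("\\.", "-", rows)
  msa(rows)
}

#' Write a multiple alignment
#' @param aln a `tmc_msa`
#' @param path output path
#' @param format `"fasta"` or `"clustal"`
#' @export
write_alignment <- function(aln, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (id in aln$ids) {
      writeLines(paste0(">", id), con)
      s <- aln$rows[[id]]
      starts <- seq(1, nchar(s), by = 60)
      writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
    }
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(c("CLUSTAL W-style alignment", ""), con)
    wid <- max(nchar(aln$ids)) + 3
    for (start in seq(1, aln$ncol, by = 60)) {
      for (id in aln$ids) {
        writeLines(sprintf("%-*s%s", wid, id,
                           substring(aln$rows[[id]], start,
                                     min(start + 59, aln$ncol))), con)
      }
      writeLines("", con)
    }
  }
  invisible(path)
}

# ---- core-block annotation -------------------------------------------------

#' Build a core annotation from explicit blocks
#'
#' @param blocks data.frame with columns `id`, `start`, `end` (1-based
#'   inclusive alignment columns)
#' @param ncol number of columns in the reference alignment
#' @param ids sequence ids of the reference alignment (mask row order)
#' @return a `tmc_core` object: logical matrix `ids x ncol`, TRUE where a
#'   residue position lies inside a core block
#' @export
core_annotation <- function(blocks, ncol, ids) {
  mask <- matrix(FALSE, nrow = length(ids), ncol = ncol,
                 dimnames = list(ids, NULL))
  if (nrow(blocks) > 0) {
    for (i in seq_len(nrow(blocks))) {
      id <- blocks$id[[i]]; s <- blocks$start[[i]]; e <- blocks$end[[i]]
      if (!id %in% ids) tmc_error(sprintf("core block references unknown id '%s'", id))
      if (s < 1 || e > ncol || s > e) {
        tmc_error(sprintf("core block %d..%d for '%s' outside alignment columns 1..%d",
                          s, e, id, ncol))
      }
      if (any(mask[id, s:e])) {
        tmc_error(sprintf("overlapping core blocks on sequence '%s'", id))
      }
      mask[id, s:e] <- TRUE
    }
  }
  structure(list(mask = mask, ncol = ncol), class = "tmc_core")
}

#' Read a core-block annotation XML file
#'
#' Schema: `<family><sequence id="..."><block start="..." end="..."/>...`
#' with 1-based inclusive alignment-column coordinates.
#'
#' @param path XML path
#' @param ncol reference alignment column count (bounds check)
#' @param ids reference sequence ids
#' @return a `tmc_core` object
#' @export
read_core_annotation <- function(path, ncol, ids) {
  if (!file.exists(path)) tmc_error(sprintf("no such file: %s", path))
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) tmc_error(sprintf(
                    "malformed XML '%s': %s", path, conditionMessage(e))))
  seq_nodes <- xml2::xml_find_all(doc, ".//sequence")
  rows <- list()
  for (sn in seq_nodes) {
    id <- xml2::xml_attr(sn, "id")
    for (bn in xml2::xml_find_all(sn, ".//block")) {
      s <- as.integer(xml2::xml_attr(bn, "start"))
      e <- as.integer(xml2::xml_attr(bn, "end"))
      if (is.na(s) || is.na(e)) tmc_error("core block missing start/end attribute")
      rows[[length(rows) + 1L]] <- data.frame(id = id, start = s, end = e)
    }
  }
  blocks <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), start = integer(), end = integer())
  core_annotation(blocks, ncol = ncol, ids = ids)
}

#' Write a core-block annotation XML file
#' @param core a `tmc_core`
#' @param path output path
#' @export
write_core_annotation <- function(core, path) {
  doc <- xml2::xml_new_root("family")
  for (id in rownames(core$mask)) {
    m <- core$mask[id, ]
    if (!any(m)) next
    sn <- xml2::xml_add_child(doc, "sequence", id = id)
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      xml2::xml_add_child(sn, "block", start = as.character(starts[[k]]),
                          end = as.character(ends[[k]]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# ---- tabular search hits ---------------------------------------------------

HIT_COLUMNS <- c("qid", "sid", "pident", "length", "qstart", "qend",
                 "sstart", "send", "evalue", "qseq", "sseq")

#' Construct a search-hit table
#'
#' @param df data.frame with the columns of the extended tabular hit format
#'   (`qid sid pident length qstart qend sstart send evalue qseq sseq`)
#' @param query_lengths optional named integer vector of query lengths; when
#'   given, a `coverage` column (percent of query residues inside the hit's
#'   query span) is computed
#' @return a `tmc_hits` data.frame
#' @export
hit_table <- function(df, query_lengths = NULL) {
  missing_cols <- setdiff(HIT_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    tmc_error(sprintf("hit table missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  }
  df <- df[HIT_COLUMNS]
  if (nrow(df) > 0 && any(nchar(df$qseq) != nchar(df$sseq))) {
    tmc_error("aligned query and subject segments must have equal length")
  }
  df$coverage <- rep(NA_real_, nrow(df))
  if (!is.null(query_lengths) && nrow(df) > 0) {
    qlen <- query_lengths[df$qid]
    df$coverage <- 100 * (df$qend - df$qstart + 1) / as.numeric(qlen)
  }
  structure(df, class = c("tmc_hits", "data.frame"))
}

#' Read search hits from an extended tabular file
#'
#' Tab-separated, one hit per line, columns
#' `qid sid pident length qstart qend sstart send evalue qseq sseq`
#' (BLAST+ outfmt-6 style extended with the aligned segment strings; all
#' coordinates 1-based inclusive). An empty file yields an empty hit table.
#'
#' @inheritParams hit_table
#' @param path input path
#' @return a `tmc_hits` data.frame
#' @export
read_tabular_hits <- function(path, query_lengths = NULL) {
  if (!file.exists(path)) tmc_error(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(hit_table(data.frame(qid = character(), sid = character(),
                                pident = numeric(), length = integer(),
                                qstart = integer(), qend = integer(),
                                sstart = integer(), send = integer(),
                                evalue = numeric(), qseq = character(),
                                sseq = character()), query_lengths))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11)) {
    tmc_error("hit line with fewer than 11 columns (aligned segment strings are required)")
  }
  m <- do.call(rbind, fields)
  df <- data.frame(qid = m[, 1], sid = m[, 2],
                   pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
                   qstart = as.integer(m[, 5]), qend = as.integer(m[, 6]),
                   sstart = as.integer(m[, 7]), send = as.integer(m[, 8]),
                   evalue = as.numeric(m[, 9]),
                   qseq = toupper(m[, 10]), sseq = toupper(m[, 11]),
                   stringsAsFactors = FALSE)
  hit_table(df, query_lengths)
}

#' Write search hits in the extended tabular format
#' @param hits a `tmc_hits` data.frame
#' @param path output path
#' @export
write_tabular_hits <- function(hits, path) {
  df <- as.data.frame(hits)[HIT_COLUMNS]
  df$evalue <- formatC(df$evalue, format = "g", digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- constraint-library serialization --------------------------------------

#' Write a constraint library to the T-Coffee-style text format
#'
#' Header: number of sequences, then `id length` lines in index order.
#' Body: per sequence pair a `#i j` line (1-based indices into the header
#' list) followed by `posA posB weight` triplets (1-based positions),
#' sorted by (idA, posA, idB, posB).
#'
#' @param lib a `tmc_library`
#' @param path output path
#' @export
write_library <- function(lib, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  ids <- names(lib$lengths)
  writeLines("! TMC_LIB_01", con)
  writeLines(as.character(length(ids)), con)
  writeLines(sprintf("%s %d", ids, lib$lengths), con)
  cons <- lib$constraints
  if (nrow(cons) > 0) {
    cons <- cons[order(cons$idA, cons$posA, cons$idB, cons$posB), ]
    key <- paste(cons$idA, cons$idB)
    for (k in unique(key)) {
      sub <- cons[key == k, ]
      ia <- match(sub$idA[[1]], ids); ib <- match(sub$idB[[1]], ids)
      writeLines(sprintf("#%d %d", ia, ib), con)
      writeLines(sprintf("%d %d %d", sub$posA, sub$posB, sub$weight), con)
    }
  }
  writeLines("! SEQ_1_TO_N", con)
  invisible(path)
}

#' Read a constraint library from the text format written by [write_library()]
#' @param path input path
#' @return a `tmc_library`
#' @export
read_library <- function(path) {
  if (!file.exists(path)) tmc_error(sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2 || !startsWith(lines[[1]], "! TMC_LIB")) {
    tmc_error(sprintf("'%s' is not a constraint-library file", path))
  }
  n <- as.integer(lines[[2]])
  hdr <- strsplit(lines[3:(2 + n)], "\\s+")
  ids <- vapply(hdr, `[[`, character(1), 1)
  lens <- stats::setNames(as.integer(vapply(hdr, `[[`, character(1), 2)), ids)
  body <- lines[-(1:(2 + n))]
  body <- body[!startsWith(body, "!")]
  rows <- list()
  ia <- ib <- NA_integer_
  for (ln in body) {
    if (startsWith(ln, "#")) {
      p <- as.integer(strsplit(sub("^#", "", ln), "\\s+")[[1]])
      ia <- p[[1]]; ib <- p[[2]]
    } else {
      v <- as.integer(strsplit(trimws(ln), "\\s+")[[1]])
      rows[[length(rows) + 1L]] <- data.frame(
        idA = ids[[ia]], posA = v[[1]], idB = ids[[ib]], posB = v[[2]],
        weight = v[[3]], stringsAsFactors = FALSE)
    }
  }
  cons <- if (length(rows)) do.call(rbind, rows) else empty_constraints()
  constraint_library(lens, cons)
}
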