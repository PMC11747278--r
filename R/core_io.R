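#' Construct a transcript set
#'
#' A transcript set is the unit all pipeline stages operate on: an ordered
#' collection of uniquely identified full-length transcript sequences over
#' the alphabet A/C/G/T/N, with an optional free-text description per record
#' and a provenance label (input path or `"synthetic"`).
#'
#' Internally all coordinates used by the package are 0-based half-open;
#' every user-facing table reports 1-based inclusive positions, matching the
#' convention of tabular alignment output.
#'
#' @param ids character vector of unique, non-empty identifiers containing
#'   no whitespace.
#' @param seqs character vector of sequences (same length as `ids`),
#'   uppercase over A/C/G/T/N.
#' @param desc optional character vector of descriptions (`""` for none).
#' @param provenance single string recording where the set came from.
#' @return An object of class `transcript_set` with elements `id`, `seq`
#'   (named by id), `desc` (named by id) and `provenance`.
#' @export
transcript_set <- function(ids, seqs, desc = NULL, provenance = "memory") {
  ids <- as.character(ids)
  seqs <- as.character(seqs)
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (is.null(desc)) desc <- rep("", length(ids))
  if (length(ids)) {
    if (any(!nzchar(ids))) stop("empty transcript id")
    if (any(grepl("\\s", ids))) stop("transcript ids must not contain whitespace")
    dup <- ids[duplicated(ids)]
    if (length(dup)) stop("duplicate transcript id: ", dup[[1L]])
    if (any(!nzchar(seqs))) {
      stop("zero-length sequence for id: ", ids[!nzchar(seqs)][[1L]])
    }
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      i <- which(bad)[[1L]]
      p <- regexpr("[^ACGTN]", seqs[[i]])
      stop(sprintf("invalid character '%s' at position %d of sequence '%s'",
                   substr(seqs[[i]], p, p), p, ids[[i]]))
    }
  }
  names(seqs) <- ids
  names(desc) <- ids
  structure(list(id = ids, seq = seqs, desc = desc, provenance = provenance),
            class = "transcript_set")
}

#' @export
length.transcript_set <- function(x) length(x$id)

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d sequences (provenance: %s)\n",
              length(x$id), x$provenance))
  if (length(x$id)) {
    n <- nchar(x$seq)
    cat(sprintf("  length range %d-%d nt, total %.0f nt\n",
                min(n), max(n), sum(as.numeric(n))))
  }
  invisible(x)
}

#' Sequence lengths of a transcript set
#'
#' @param set a [transcript_set()].
#' @return Named integer vector of sequence lengths.
#' @export
transcript_lengths <- function(set) {
  stopifnot(inherits(set, "transcript_set"))
  stats::setNames(nchar(set$seq), set$id)
}

#' Read transcripts from a FASTA file
#'
#' Wrapped or single-line FASTA is accepted; CRLF line endings are
#' tolerated.  Sequences are uppercased and `U` is mapped to `T`, so
#' RNA-alphabet inputs parse cleanly.  IUPAC ambiguity codes other than `N`
#' (R, Y, S, W, K, M, B, D, H, V) are mapped to `N` with a warning; any other
#' character is an error reporting its position.  The record id is the first
#' whitespace-delimited token of the header; the remainder becomes the
#' description.
#'
#' @param path path to a FASTA file.
#' @return A [transcript_set()] with `provenance = path`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA (no sequences): ", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate transcript id: ", dup[[1L]])
  seqs <- toupper(as.character(x))
  seqs <- chartr("U", "T", seqs)
  amb <- grepl("[RYSWKMBDHV]", seqs)
  if (any(amb)) {
    warning(sprintf(
      "%d sequence(s) contain IUPAC ambiguity codes; mapped to N", sum(amb)))
    seqs <- chartr("RYSWKMBDHV", "NNNNNNNNNN", seqs)
  }
  transcript_set(ids, seqs, desc, provenance = path)
}

#' Write a transcript set to FASTA
#'
#' @param set a [transcript_set()].
#' @param path output path.
#' @param wrap positive line width for sequence wrapping (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(set, path, wrap = 60L) {
  stopifnot(inherits(set, "transcript_set"))
  wrap <- as.integer(wrap)
  if (is.na(wrap) || wrap < 1L) stop("wrap must be a positive integer")
  x <- Biostrings::DNAStringSet(unname(set$seq))
  names(x) <- ifelse(nzchar(set$desc),
                     paste(set$id, set$desc), set$id)
  ok <- tryCatch({
    Biostrings::writeXStringSet(x, filepath = path, width = wrap)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write FASTA to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a typed tab-separated table
#'
#' Lines starting with `#` and blank lines are skipped.  A header row is
#' optional: it is detected when a column the schema declares numeric holds
#' a non-numeric token in the first data row, or when the first row matches
#' the schema's column names.
#'
#' @param path path to a TSV file.
#' @param schema named character vector mapping column name to one of
#'   `"character"`, `"integer"`, `"numeric"`.
#' @return A `data.frame` with the schema's columns and types; zero rows if
#'   the file holds only comments.
#' @export
read_tsv_table <- function(path, schema) {
  if (!file.exists(path)) stop("no such file: ", path)
  stopifnot(is.character(schema), !is.null(names(schema)))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- stats::setNames(
    as.data.frame(lapply(unname(schema), function(t) vector(t, 0L))),
    names(schema))
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nc <- length(schema)
  bad <- which(vapply(fields, length, 1L) != nc)
  if (length(bad)) {
    stop(sprintf("line %d: expected %d tab-separated columns, found %d",
                 lineno[bad[[1L]]], nc, length(fields[[bad[[1L]]]])))
  }
  first <- fields[[1L]]
  numcols <- schema %in% c("integer", "numeric")
  is_header <- identical(tolower(first), tolower(names(schema))) ||
    (any(numcols) && anyNA(suppressWarnings(as.numeric(first[numcols]))))
  if (is_header) {
    fields <- fields[-1L]
    lineno <- lineno[-1L]
  }
  if (!length(fields)) return(empty)
  mat <- do.call(rbind, fields)
  out <- vector("list", nc)
  for (j in seq_len(nc)) {
    v <- mat[, j]
    if (numcols[[j]]) {
      conv <- suppressWarnings(as.numeric(v))
      if (anyNA(conv)) {
        stop(sprintf("line %d: column '%s' is not numeric ('%s')",
                     lineno[which(is.na(conv))[[1L]]], names(schema)[[j]],
                     v[which(is.na(conv))[[1L]]]))
      }
      out[[j]] <- if (schema[[j]] == "integer") as.integer(round(conv)) else conv
    } else {
      out[[j]] <- v
    }
  }
  names(out) <- names(schema)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Write a data frame as a commented TSV
#'
#' @param df data frame.
#' @param path output path.
#' @param comment optional character vector written as leading `#` lines.
#' @return Invisibly, `path`.
#' @export
write_tsv_table <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# reverse complement of a plain character vector of DNA strings
revcomp <- function(s) {
  out <- chartr("ACGTN", "TGCAN", s)
  vapply(strsplit(out, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}
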