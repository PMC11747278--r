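#' @name orf_cds
#' @title ORF discovery and completeness classification
#'
#' @description
#' Explicit open-reading-frame enumeration on both strands of each
#' transcript.  Within every maximal stop-to-stop interval of a reading
#' frame the candidate ORF starts at the first ATG; if the interval has no
#' ATG but abuts the transcript edge, the frame start is used instead.
#' Completeness classes follow the usual convention: `complete` (ATG to
#' in-frame stop), `3prime_partial` (ATG, no stop before the 3' edge),
#' `5prime_partial` (no ATG, interval starts at the 5' edge, terminated by a
#' stop) and `internal` (neither).  Codons containing N never match ATG or a
#' stop and translate to X.
NULL

.stop_codons <- c("TAA", "TAG", "TGA")

.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

# translate a character vector of codons; unknown/ambiguous -> X, stop -> *
translate_codons <- function(codons) {
  aa <- .codon_table()[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

.completeness_levels <- c("complete", "5prime_partial", "3prime_partial",
                          "internal")

# ORFs in the three forward frames of one sequence string
.find_orfs_fwd <- function(s, min_protein_len) {
  n <- nchar(s)
  out <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) next
    starts <- f + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% .stop_codons
    is_atg <- codons == "ATG"
    stop_idx <- which(is_stop)
    bounds <- c(0L, stop_idx, if (!length(stop_idx) || stop_idx[length(stop_idx)] < ncod) ncod + 1L)
    # intervals run (prev_stop, next_stop_or_end)
    for (b in seq_len(length(bounds) - 1L)) {
      i0 <- bounds[[b]] + 1L              # first codon of interval
      i1 <- bounds[[b + 1L]]              # stop codon index, or ncod+1 sentinel
      has_stop <- i1 <= ncod && is_stop[[i1]]
      last_content <- if (has_stop) i1 - 1L else ncod
      if (last_content < i0) next
      atg_here <- which(is_atg[i0:last_content])
      if (length(atg_here)) {
        a <- i0 + atg_here[[1L]] - 1L
        plen <- last_content - a + 1L
        cls <- if (has_stop) "complete" else "3prime_partial"
        end_cod <- if (has_stop) i1 else last_content
        if (plen >= min_protein_len) {
          out[[length(out) + 1L]] <- list(
            frame = f, start = starts[[a]], end = starts[[end_cod]] + 2L,
            completeness = cls, protein_length = plen,
            protein = paste(translate_codons(codons[a:last_content]),
                            collapse = ""))
        }
      } else if (i0 == 1L) {
        # no ATG; interval abuts the 5' edge of this frame
        plen <- last_content - i0 + 1L
        cls <- if (has_stop) "5prime_partial" else "internal"
        end_cod <- if (has_stop) i1 else last_content
        if (plen >= min_protein_len) {
          out[[length(out) + 1L]] <- list(
            frame = f, start = starts[[i0]], end = starts[[end_cod]] + 2L,
            completeness = cls, protein_length = plen,
            protein = paste(translate_codons(codons[i0:last_content]),
                            collapse = ""))
        }
      }
    }
  }
  out
}

#' Find open reading frames in one transcript
#'
#' @param t a [transcript_set()] of length one, or a single named character
#'   string (name = transcript id).
#' @param min_protein_len minimum protein length in amino acids (default
#'   100, the conventional coding-prediction cutoff).
#' @param strands `"both"` (default) or `"forward_only"`.
#' @return A `data.frame`: `transcript_id`, `strand` (+/-), `frame` (0..2 on
#'   the searched strand), `start`, `end` (1-based inclusive on the input
#'   transcript, `start < end` on both strands), `completeness`,
#'   `protein_length`, `protein`.  Stop codons are included in the ORF span
#'   of stop-terminated classes; `protein_length` excludes the stop.
#' @export
find_orfs <- function(t, min_protein_len = 100L,
                      strands = c("both", "forward_only")) {
  strands <- match.arg(strands)
  if (inherits(t, "transcript_set")) {
    stopifnot(length(t) == 1L)
    id <- t$id[[1L]]; s <- t$seq[[1L]]
  } else {
    stopifnot(is.character(t), length(t) == 1L)
    id <- if (!is.null(names(t))) names(t) else "transcript"
    s <- unname(t)
  }
  if (nchar(s) < 3L) stop("sequence shorter than one codon")
  rows <- list()
  fwd <- .find_orfs_fwd(s, min_protein_len)
  for (o in fwd) {
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = id, strand = "+", frame = o$frame,
      start = o$start, end = o$end, completeness = o$completeness,
      protein_length = o$protein_length, protein = o$protein,
      stringsAsFactors = FALSE)
  }
  if (strands == "both") {
    L <- nchar(s)
    rc <- revcomp(s)
    rev <- .find_orfs_fwd(rc, min_protein_len)
    for (o in rev) {
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = id, strand = "-", frame = o$frame,
        start = L - o$end + 1L, end = L - o$start + 1L,
        completeness = o$completeness,
        protein_length = o$protein_length, protein = o$protein,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(transcript_id = character(), strand = character(),
                      frame = integer(), start = integer(), end = integer(),
                      completeness = character(), protein_length = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

#' ORFs for every transcript of a set
#'
#' @inheritParams find_orfs
#' @param set a [transcript_set()].
#' @return Row-bound [find_orfs()] tables for all transcripts (transcripts
#'   shorter than one codon are skipped).
#' @export
find_orfs_set <- function(set, min_protein_len = 100L,
                          strands = c("both", "forward_only")) {
  strands <- match.arg(strands)
  out <- lapply(set$id, function(id) {
    if (nchar(set$seq[[id]]) < 3L) return(NULL)
    find_orfs(stats::setNames(set$seq[id], id), min_protein_len, strands)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(find_orfs(c(x = "ATGTAA"), 10^6L))  # empty shape
  do.call(rbind, out)
}

#' Pick one representative ORF per transcript
#'
#' Longest protein first; ties broken by completeness rank (complete >
#' 5prime_partial > 3prime_partial > internal), then leftmost start, then
#' the + strand.
#'
#' @param orfs a `data.frame` from [find_orfs()].
#' @return A one-row `data.frame`, or `NULL` for an empty input.
#' @export
select_best_orf <- function(orfs) {
  if (is.null(orfs) || !nrow(orfs)) return(NULL)
  rank <- match(orfs$completeness, .completeness_levels)
  ord <- order(-orfs$protein_length, rank, orfs$start,
               match(orfs$strand, c("+", "-")))
  orfs[ord[[1L]], , drop = FALSE]
}

#' Histogram of complete-ORF protein lengths
#'
#' @param records a `data.frame` from [find_orfs()].
#' @param bin_width_aa bin width in amino acids (default 100).
#' @return Named integer vector of counts over bins `[0,100)`, `[100,200)`,
#'   ... covering the observed range; empty for no complete ORFs.
#' @export
orf_length_histogram <- function(records, bin_width_aa = 100L) {
  comp <- records[records$completeness == "complete", , drop = FALSE]
  if (!nrow(comp)) return(stats::setNames(integer(0), character(0)))
  b <- comp$protein_length %/% bin_width_aa
  tab <- table(factor(b, levels = 0:max(b)))
  lo <- as.integer(names(tab)) * bin_width_aa
  stats::setNames(as.integer(tab),
                  sprintf("[%d,%d)", lo, lo + bin_width_aa))
}
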