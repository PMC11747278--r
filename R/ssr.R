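#' @name ssr_scan
#' @title Microsatellite (SSR) scanning
#'
#' @description
#' MISA-style detection of perfect tandem repeats of 1-6 nt units on
#' transcripts of at least a minimum length (default 500 bp), with
#' per-unit-size minimum repeat counts (defaults 1:10, 2:6, 3:5, 4:5, 5:5,
#' 6:5), merging of nearby loci into compound SSRs, and type classification
#' (p1..p6, compound).
NULL

.default_min_repeats <- c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L,
                          `5` = 5L, `6` = 5L)

# TRUE if motif is itself a repetition of a shorter unit (e.g. "ATAT")
.is_periodic_motif <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(FALSE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), u / d)) return(TRUE)
  }
  FALSE
}

# lexicographically smallest rotation of a motif, for grouping
.canonical_rotation <- function(motif) {
  vapply(motif, function(m) {
    u <- nchar(m)
    rots <- vapply(seq_len(u) - 1L, function(r) {
      paste0(substr(m, r + 1L, u), substr(m, 1L, r))
    }, "")
    min(rots)
  }, "", USE.NAMES = FALSE)
}

# Maximal perfect tandem runs of unit sizes 1..6 in one sequence.
# Returns candidates before cross-unit overlap resolution and compound
# merging: motif (as it appears at the locus start), unit_length,
# repeat_count, start, end (1-based inclusive).  Runs whose motif is a
# repetition of a shorter unit are dropped (they are reported at the
# smaller unit size).
ssr_candidates <- function(seq, min_repeats = .default_min_repeats) {
  n <- nchar(seq)
  x <- utf8ToInt(seq)
  out <- vector("list", 6L)
  for (u in 1:6) {
    minr <- as.integer(min_repeats[[as.character(u)]])
    if (n < u * minr) next
    eq <- x[seq_len(n - u)] == x[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= (minr - 1L) * u)
    if (!length(hit)) next
    rows <- lapply(hit, function(h) {
      i <- starts[[h]]                      # run start in eq == seq position
      L <- r$lengths[[h]]                   # eq run length; span = L + u
      count <- (L + u) %/% u
      if (count < minr) return(NULL)
      motif <- substr(seq, i, i + u - 1L)
      if (.is_periodic_motif(motif)) return(NULL)
      data.frame(motif = motif, unit_length = u, repeat_count = count,
                 start = i, end = i + u * count - 1L,
                 stringsAsFactors = FALSE)
    })
    out[[u]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(motif = character(), unit_length = integer(),
                      repeat_count = integer(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  }
  res[order(res$start, -(res$end - res$start), res$unit_length), ,
      drop = FALSE]
}

# Left-to-right, longest-first resolution so no two simple loci overlap.
.resolve_overlaps <- function(cand) {
  if (nrow(cand) < 2L) return(cand)
  ord <- order(cand$start, -(cand$end - cand$start), cand$unit_length)
  cand <- cand[ord, , drop = FALSE]
  keep <- logical(nrow(cand))
  last_end <- 0L
  ends_kept <- integer(0)
  starts_kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[[i]]; e <- cand$end[[i]]
    if (!any(s <= ends_kept & e >= starts_kept)) {
      keep[[i]] <- TRUE
      starts_kept <- c(starts_kept, s)
      ends_kept <- c(ends_kept, e)
    }
  }
  cand[keep, , drop = FALSE]
}

#' Scan a transcript set for SSR loci
#'
#' Transcripts shorter than `min_transcript_len` are skipped entirely.
#' Maximal perfect tandem runs of 1-6 nt units meeting the per-unit-size
#' minimum repeat count are reported; a run whose unit is itself a
#' repetition of a shorter qualifying unit is reported at the smaller unit.
#' Overlaps are resolved left-to-right, longest match first, so reported
#' simple loci never overlap.  Two or more simple loci separated by at most
#' `compound_max_interruption` bases are merged into one compound locus
#' (`type_class == "compound"`); the component records are retained in the
#' `components` attribute of the result.
#'
#' @param set a [transcript_set()].
#' @param min_repeats named integer vector of minimum repeat counts for unit
#'   sizes `"1"` to `"6"` (MISA defaults).
#' @param min_transcript_len minimum transcript length scanned (default 500).
#' @param compound_max_interruption maximum interruption between simple SSRs
#'   merged into a compound locus (default 100).
#' @return A `data.frame` of loci: `transcript_id`, `type_class` (p1..p6 or
#'   compound), `motif` (for compound loci, components joined with `"+"`),
#'   `motif_canonical` (lexicographically smallest rotation; `NA` for
#'   compound), `unit_length`, `repeat_count` (`NA` for compound), `start`,
#'   `end` (1-based inclusive), `n_components`.  Attribute `"components"`
#'   holds the simple member loci of every compound locus.
#' @export
scan_ssrs <- function(set,
                      min_repeats = .default_min_repeats,
                      min_transcript_len = 500L,
                      compound_max_interruption = 100L) {
  stopifnot(inherits(set, "transcript_set"))
  if (!all(as.character(1:6) %in% names(min_repeats))) {
    stop("min_repeats must cover unit sizes 1..6")
  }
  loci <- list()
  comp <- list()
  for (id in set$id) {
    s <- set$seq[[id]]
    if (nchar(s) < min_transcript_len) next
    cand <- .resolve_overlaps(ssr_candidates(s, min_repeats))
    if (!nrow(cand)) next
    cand <- cand[order(cand$start), , drop = FALSE]
    gap_prev <- c(Inf, cand$start[-1L] - cand$end[-nrow(cand)] - 1L)
    grp <- cumsum(gap_prev > compound_max_interruption)
    for (g in unique(grp)) {
      rows <- cand[grp == g, , drop = FALSE]
      if (nrow(rows) == 1L) {
        loci[[length(loci) + 1L]] <- data.frame(
          transcript_id = id,
          type_class = paste0("p", rows$unit_length),
          motif = rows$motif,
          motif_canonical = .canonical_rotation(rows$motif),
          unit_length = rows$unit_length,
          repeat_count = rows$repeat_count,
          start = rows$start, end = rows$end, n_components = 1L,
          stringsAsFactors = FALSE)
      } else {
        loci[[length(loci) + 1L]] <- data.frame(
          transcript_id = id,
          type_class = "compound",
          motif = paste(sprintf("(%s)%d", rows$motif, rows$repeat_count),
                        collapse = "+"),
          motif_canonical = NA_character_,
          unit_length = NA_integer_, repeat_count = NA_integer_,
          start = min(rows$start), end = max(rows$end),
          n_components = nrow(rows),
          stringsAsFactors = FALSE)
        comp[[length(comp) + 1L]] <-
          cbind(transcript_id = id, rows,
                compound_start = min(rows$start), row.names = NULL)
      }
    }
  }
  res <- if (length(loci)) do.call(rbind, loci) else data.frame(
    transcript_id = character(), type_class = character(),
    motif = character(), motif_canonical = character(),
    unit_length = integer(), repeat_count = integer(),
    start = integer(), end = integer(), n_components = integer(),
    stringsAsFactors = FALSE)
  attr(res, "components") <-
    if (length(comp)) do.call(rbind, comp) else NULL
  res
}

#' Tabulate SSR loci by type class
#'
#' @param loci a loci `data.frame` from [scan_ssrs()].
#' @return A list: `counts` (named vector over p1..p6 and compound),
#'   `total`, `transcripts_with_ssr`, and `transcripts_multi` (transcripts
#'   carrying more than one locus).
#' @export
classify_ssr_types <- function(loci) {
  classes <- c(paste0("p", 1:6), "compound")
  counts <- stats::setNames(integer(length(classes)), classes)
  if (nrow(loci)) {
    tab <- table(factor(loci$type_class, levels = classes))
    counts[] <- as.integer(tab)
  }
  per_tx <- if (nrow(loci)) table(loci$transcript_id) else integer(0)
  list(counts = counts,
       total = sum(counts),
       transcripts_with_ssr = length(per_tx),
       transcripts_multi = sum(per_tx > 1L))
}
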