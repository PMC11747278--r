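#' @name as_detect
#' @title Reference-free alternative-splicing detection from HSP-pair geometry
#'
#' @description
#' Without a genome, an alternative-splicing difference between two
#' full-length transcripts shows up in their pairwise local alignment as two
#' high-scoring segment pairs (HSPs) with the same orientation: on one
#' transcript (the "continuous" one) the two segments are adjacent or
#' overlap by only a few bases, while on the other (the "distinct" one) they
#' are separated by an internal unaligned region -- the AS gap.  An event is
#' called when the gap is larger than `gap_min`, lies at least `end_margin`
#' from both ends of the distinct transcript, the junction overlap is
#' smaller than `overlap_max`, and the two segments jointly cover at least
#' `coverage_min` of the continuous transcript.  The event type (exon skip
#' versus intron retention) is not classified: that distinction needs a
#' reference genome.
NULL

.hsp_empty <- function() {
  data.frame(query_id = character(), subject_id = character(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             identity = numeric(), orientation = character(),
             score = numeric(), stringsAsFactors = FALSE)
}

# gapless high-scoring segments between two sequences: shared-word seeds
# grouped by diagonal, bridged across mismatches, then extended outward
# base by base.  Coordinates 1-based inclusive on both inputs.
.pair_hsps <- function(sa, sb, k = 12L, merge_gap = 40L,
                       min_identity = 0.9, min_hsp_len = 50L) {
  ca <- kmer_codes_cpp(sa, k)
  cb <- kmer_codes_cpp(sb, k)
  pa <- which(!is.na(ca)); pb <- which(!is.na(cb))
  if (!length(pa) || !length(pb)) return(NULL)
  dta <- data.table::data.table(code = ca[pa], pos1 = pa)
  dtb <- data.table::data.table(code = cb[pb], pos2 = pb)
  hits <- merge(dta, dtb, by = "code", allow.cartesian = TRUE)
  if (!nrow(hits)) return(NULL)
  hits[, diag := pos1 - pos2]
  data.table::setorder(hits, diag, pos1)
  grp <- cumsum(c(TRUE, diff(hits$pos1) > merge_gap | diff(hits$diag) != 0))
  xa <- utf8ToInt(sa); xb <- utf8ToInt(sb)
  la <- length(xa); lb <- length(xb)
  segs <- hits[, .(q0 = min(pos1), q1 = max(pos1) + k - 1L,
                   d = diag[[1L]]), by = .(g = grp)]
  out <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    q0 <- segs$q0[[i]]; q1 <- segs$q1[[i]]; d <- segs$d[[i]]
    # ungapped extension while bases match
    while (q0 > 1L && q0 - d > 1L && xa[[q0 - 1L]] == xb[[q0 - 1L - d]]) {
      q0 <- q0 - 1L
    }
    while (q1 < la && q1 - d < lb && xa[[q1 + 1L]] == xb[[q1 + 1L - d]]) {
      q1 <- q1 + 1L
    }
    len <- q1 - q0 + 1L
    if (len < min_hsp_len) next
    matches <- sum(xa[q0:q1] == xb[(q0 - d):(q1 - d)])
    idn <- matches / len
    if (idn < min_identity) next
    out[[i]] <- c(q0, q1, q0 - d, q1 - d, matches, len)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(NULL)
  m <- do.call(rbind, out)
  # merge duplicates created when extension fuses neighbouring seed groups
  m <- unique(m)
  keep <- rep(TRUE, nrow(m))
  if (nrow(m) > 1L) {
    dg <- m[, 1L] - m[, 3L]
    o <- order(dg, m[, 1L])
    m <- m[o, , drop = FALSE]; dg <- dg[o]
    keep <- rep(TRUE, nrow(m))
    for (i in 2:nrow(m)) {
      if (dg[[i]] == dg[[i - 1L]] && m[i, 1L] <= m[i - 1L, 2L]) {
        keep[[i]] <- FALSE   # contained/overlapping on the same diagonal
      }
    }
  }
  m <- m[keep, , drop = FALSE]
  data.frame(q_start = m[, 1L], q_end = m[, 2L],
             s_start = m[, 3L], s_end = m[, 4L],
             identity = m[, 5L] / m[, 6L],
             score = m[, 5L], stringsAsFactors = FALSE)
}

#' All-versus-all local alignment of a transcript set
#'
#' Computes gapless local-alignment segments (HSPs) for every unordered
#' transcript pair sharing at least `min_seed_hits` exact words, in both
#' orientations.  Self-comparisons are excluded.  Each HSP is reported in
#' both directions (a as query / b as query); reverse-orientation HSPs carry
#' normalized coordinates (`s_start <= s_end`) and `orientation ==
#' "reverse"`.
#'
#' @param set a [transcript_set()] of at least 2 transcripts (a smaller set
#'   returns an empty table).
#' @param min_identity minimum HSP identity (default 0.90).
#' @param min_hsp_len minimum HSP length in bases (default 50).
#' @param word_size seed word length (default 12).
#' @param min_seed_hits shared seed words required to consider a pair.
#' @return A `data.frame` of HSPs: `query_id`, `subject_id`, `q_start`,
#'   `q_end`, `s_start`, `s_end` (1-based inclusive), `identity` (0..1),
#'   `orientation` (forward/reverse), `score` (matching bases), ordered by
#'   (`query_id`, `subject_id`, `q_start`).
#' @export
align_all_vs_all <- function(set, min_identity = 0.90, min_hsp_len = 50L,
                             word_size = 12L, min_seed_hits = 2L) {
  stopifnot(inherits(set, "transcript_set"))
  n <- length(set)
  if (n < 2L) return(.hsp_empty())
  ids <- set$id
  seqs <- set$seq
  rc <- stats::setNames(revcomp(unname(seqs)), ids)
  lens <- transcript_lengths(set)

  # candidate pairs per orientation via a global word index
  index_codes <- function(strings) {
    dt <- data.table::rbindlist(lapply(seq_along(strings), function(i) {
      cc <- kmer_codes_cpp(strings[[i]], word_size)
      p <- which(!is.na(cc))
      if (!length(p)) return(NULL)
      data.table::data.table(code = cc[p], tid = i)
    }))
    if (!nrow(dt)) return(dt)
    unique(dt)
  }
  fwd_idx <- index_codes(unname(seqs))
  pair_counts <- function(idx_a, idx_b, same) {
    if (!nrow(idx_a) || !nrow(idx_b)) {
      return(data.table::data.table(tid1 = integer(), tid2 = integer()))
    }
    j <- merge(idx_a, idx_b, by = "code", allow.cartesian = TRUE,
               suffixes = c("1", "2"))
    if (!nrow(j)) return(data.table::data.table(tid1 = integer(),
                                                tid2 = integer()))
    if (same) j <- j[j$tid1 < j$tid2, ]
    else j <- j[j$tid1 != j$tid2, ]
    if (!nrow(j)) return(data.table::data.table(tid1 = integer(),
                                                tid2 = integer()))
    cnt <- j[, .N, by = .(tid1, tid2)]
    cnt[cnt$N >= min_seed_hits, c("tid1", "tid2")]
  }
  cand_f <- pair_counts(fwd_idx, fwd_idx, same = TRUE)
  rev_idx <- index_codes(unname(rc))
  cand_r <- pair_counts(fwd_idx, rev_idx, same = FALSE)
  if (nrow(cand_r)) {
    # one row per unordered pair
    a <- pmin(cand_r$tid1, cand_r$tid2)
    b <- pmax(cand_r$tid1, cand_r$tid2)
    cand_r <- unique(data.table::data.table(tid1 = a, tid2 = b))
  }

  rows <- list()
  emit <- function(i, j, h, orientation) {
    if (is.null(h) || !nrow(h)) return(invisible(NULL))
    rows[[length(rows) + 1L]] <<- data.frame(
      query_id = ids[[i]], subject_id = ids[[j]],
      q_start = h$q_start, q_end = h$q_end,
      s_start = h$s_start, s_end = h$s_end,
      identity = h$identity, orientation = orientation,
      score = h$score, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <<- data.frame(
      query_id = ids[[j]], subject_id = ids[[i]],
      q_start = h$s_start, q_end = h$s_end,
      s_start = h$q_start, s_end = h$q_end,
      identity = h$identity, orientation = orientation,
      score = h$score, stringsAsFactors = FALSE)
  }
  if (nrow(cand_f)) {
    for (r in seq_len(nrow(cand_f))) {
      i <- cand_f$tid1[[r]]; j <- cand_f$tid2[[r]]
      h <- .pair_hsps(seqs[[i]], seqs[[j]],
                      min_identity = min_identity,
                      min_hsp_len = min_hsp_len, k = word_size)
      emit(i, j, h, "forward")
    }
  }
  if (nrow(cand_r)) {
    for (r in seq_len(nrow(cand_r))) {
      i <- cand_r$tid1[[r]]; j <- cand_r$tid2[[r]]
      h <- .pair_hsps(seqs[[i]], rc[[j]],
                      min_identity = min_identity,
                      min_hsp_len = min_hsp_len, k = word_size)
      if (!is.null(h) && nrow(h)) {
        lj <- lens[[j]]
        s0 <- lj - h$s_end + 1L
        s1 <- lj - h$s_start + 1L
        h$s_start <- s0; h$s_end <- s1
        emit(i, j, h, "reverse")
      }
    }
  }
  if (!length(rows)) return(.hsp_empty())
  res <- do.call(rbind, rows)
  res[order(res$query_id, res$subject_id, res$q_start), , drop = FALSE]
}

#' Read pairwise alignments in standard 12-column tabular format
#'
#' The columns are query, subject, percent identity, alignment length,
#' mismatches, gap opens, q_start, q_end, s_start, s_end, e-value and bit
#' score.  Reverse orientation is inferred from `s_start > s_end` and the
#' subject coordinates are normalized.
#'
#' @param path path to the tabular file (optionally with `#` comments).
#' @return An HSP `data.frame` as from [align_all_vs_all()] (`score` holds
#'   the bit score).
#' @export
read_alignment_tabular <- function(path) {
  schema <- c(query_id = "character", subject_id = "character",
              pident = "numeric", length = "integer",
              mismatches = "integer", gapopen = "integer",
              q_start = "integer", q_end = "integer",
              s_start = "integer", s_end = "integer",
              evalue = "numeric", bitscore = "numeric")
  tab <- read_tsv_table(path, schema)
  if (!nrow(tab)) return(.hsp_empty())
  rev <- tab$s_start > tab$s_end
  s0 <- ifelse(rev, tab$s_end, tab$s_start)
  s1 <- ifelse(rev, tab$s_start, tab$s_end)
  data.frame(query_id = tab$query_id, subject_id = tab$subject_id,
             q_start = tab$q_start, q_end = tab$q_end,
             s_start = s0, s_end = s1,
             identity = tab$pident / 100,
             orientation = ifelse(rev, "reverse", "forward"),
             score = tab$bitscore, stringsAsFactors = FALSE)
}

#' Write HSPs in standard 12-column tabular format
#'
#' @param hsps an HSP `data.frame`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_alignment_tabular <- function(hsps, path) {
  len <- hsps$q_end - hsps$q_start + 1L
  rev <- hsps$orientation == "reverse"
  out <- data.frame(
    query_id = hsps$query_id, subject_id = hsps$subject_id,
    pident = round(hsps$identity * 100, 2),
    length = len,
    mismatches = as.integer(round((1 - hsps$identity) * len)),
    gapopen = 0L,
    q_start = hsps$q_start, q_end = hsps$q_end,
    s_start = ifelse(rev, hsps$s_end, hsps$s_start),
    s_end = ifelse(rev, hsps$s_start, hsps$s_end),
    evalue = 0, bitscore = hsps$score, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.as_event_empty <- function() {
  data.frame(continuous_id = character(), distinct_id = character(),
             gap_start = integer(), gap_end = integer(),
             gap_length = integer(), junction_pos = integer(),
             junction_overlap = integer(), coverage = numeric(),
             orientation = character(), stringsAsFactors = FALSE)
}

#' Detect alternative-splicing events from HSPs
#'
#' Every same-orientation HSP pair within a transcript pair is examined
#' under both role assignments; a qualifying configuration yields one event,
#' deduplicated by (`continuous_id`, `distinct_id`, `gap_start`, `gap_end`)
#' so each pair is counted once regardless of query/subject ordering.
#' Thresholds follow a strict reading: gap strictly greater than `gap_min`,
#' junction overlap strictly smaller than `overlap_max` in absolute value,
#' end margin at least `end_margin`.
#'
#' @param hsps an HSP `data.frame` ([align_all_vs_all()] or
#'   [read_alignment_tabular()]).
#' @param lengths named vector of transcript lengths covering every id in
#'   `hsps`.
#' @param overlap_max junction overlap bound in bases (default 5).
#' @param gap_min AS gap lower bound in bases (default 100).
#' @param end_margin minimum gap distance from either end of the distinct
#'   transcript (default 100).
#' @param coverage_min minimum joint HSP coverage of the continuous
#'   transcript (default 0.95).
#' @return A `data.frame` of events: `continuous_id`, `distinct_id`,
#'   `gap_start`, `gap_end` (1-based inclusive on the distinct transcript),
#'   `gap_length`, `junction_pos` (last aligned base before the junction on
#'   the continuous transcript), `junction_overlap` (signed; negative =
#'   overlap), `coverage`, `orientation`.
#' @export
detect_as_events <- function(hsps, lengths, overlap_max = 5L,
                             gap_min = 100L, end_margin = 100L,
                             coverage_min = 0.95) {
  if (is.null(hsps) || !nrow(hsps)) return(.as_event_empty())
  need <- unique(c(hsps$query_id, hsps$subject_id))
  miss <- setdiff(need, names(lengths))
  if (length(miss)) stop("no length for transcript id: ", miss[[1L]])

  # canonical direction: query id lexicographically smallest
  swap <- hsps$query_id > hsps$subject_id
  h <- hsps
  h[swap, c("query_id", "subject_id")] <- hsps[swap, c("subject_id", "query_id")]
  h[swap, c("q_start", "q_end")] <- hsps[swap, c("s_start", "s_end")]
  h[swap, c("s_start", "s_end")] <- hsps[swap, c("q_start", "q_end")]
  h <- unique(h[, c("query_id", "subject_id", "q_start", "q_end",
                    "s_start", "s_end", "orientation")])

  key <- paste(h$query_id, h$subject_id, h$orientation, sep = "\r")
  out <- list()
  for (kk in unique(key)) {
    hh <- h[key == kk, , drop = FALSE]
    if (nrow(hh) < 2L) next
    a <- hh$query_id[[1L]]; b <- hh$subject_id[[1L]]
    ori <- hh$orientation[[1L]]
    la <- lengths[[a]]; lb <- lengths[[b]]
    idx <- utils::combn(nrow(hh), 2L)
    for (cc in seq_len(ncol(idx))) {
      h1 <- hh[idx[1L, cc], ]; h2 <- hh[idx[2L, cc], ]
      for (cont_is_a in c(TRUE, FALSE)) {
        if (cont_is_a) {
          c1 <- c(h1$q_start, h1$q_end); c2 <- c(h2$q_start, h2$q_end)
          d1 <- c(h1$s_start, h1$s_end); d2 <- c(h2$s_start, h2$s_end)
          cont <- a; dist <- b; lc <- la; ld <- lb
        } else {
          c1 <- c(h1$s_start, h1$s_end); c2 <- c(h2$s_start, h2$s_end)
          d1 <- c(h1$q_start, h1$q_end); d2 <- c(h2$q_start, h2$q_end)
          cont <- b; dist <- a; lc <- lb; ld <- la
        }
        if (c1[[1L]] > c2[[1L]]) {
          tmp <- c1; c1 <- c2; c2 <- tmp
          tmp <- d1; d1 <- d2; d2 <- tmp
        }
        jo <- c2[[1L]] - c1[[2L]] - 1L          # signed; negative = overlap
        if (abs(jo) >= overlap_max) next
        if (ori == "forward") {
          gl <- d2[[1L]] - d1[[2L]] - 1L
          gs <- d1[[2L]] + 1L; ge <- d2[[1L]] - 1L
        } else {
          gl <- d1[[1L]] - d2[[2L]] - 1L
          gs <- d2[[2L]] + 1L; ge <- d1[[1L]] - 1L
        }
        if (gl <= gap_min) next
        if (min(gs - 1L, ld - ge) < end_margin) next
        union_len <- (c1[[2L]] - c1[[1L]] + 1L) +
          (c2[[2L]] - c2[[1L]] + 1L) - max(0L, -jo)
        if (union_len / lc < coverage_min) next
        out[[length(out) + 1L]] <- data.frame(
          continuous_id = cont, distinct_id = dist,
          gap_start = gs, gap_end = ge, gap_length = gl,
          junction_pos = c1[[2L]], junction_overlap = jo,
          coverage = union_len / lc, orientation = ori,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(.as_event_empty())
  ev <- do.call(rbind, out)
  dup <- duplicated(ev[, c("continuous_id", "distinct_id",
                           "gap_start", "gap_end")])
  ev <- ev[!dup, , drop = FALSE]
  ev[order(ev$distinct_id, ev$continuous_id, ev$gap_start), , drop = FALSE]
}

#' Per-unigene summary of AS events
#'
#' Events are grouped per unigene: the cluster representative of the
#' distinct transcript when a cluster table is supplied, otherwise the
#' distinct transcript itself.
#'
#' @param events an event `data.frame` from [detect_as_events()].
#' @param clusters optional cluster `data.frame` from [collapse()].
#' @return A list: `histogram` (named count vector, events-per-unigene ->
#'   number of unigenes), `n_unigenes`, `total_events`.
#' @export
summarize_as <- function(events, clusters = NULL) {
  if (is.null(events) || !nrow(events)) {
    return(list(histogram = stats::setNames(integer(0), character(0)),
                n_unigenes = 0L, total_events = 0L))
  }
  unigene <- events$distinct_id
  if (!is.null(clusters) && nrow(clusters)) {
    map <- stats::setNames(clusters$representative_id, clusters$member_id)
    hit <- unigene %in% names(map)
    unigene[hit] <- map[unigene[hit]]
  }
  per <- table(unigene)
  hist <- table(factor(per))
  list(histogram = stats::setNames(as.integer(hist), names(hist)),
       n_unigenes = length(per),
       total_events = as.integer(sum(per)))
}
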