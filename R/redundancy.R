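#' @name redundancy
#' @title Redundancy collapse of near-identical transcripts
#'
#' @description
#' Greedy incremental clustering in the style of CD-HIT-EST: sequences are
#' sorted by length (longest first) and each joins the first existing
#' cluster whose representative exceeds the identity threshold, otherwise it
#' founds a new cluster.  Identity is the number of matching bases in the
#' best ends-free global alignment divided by the length of the shorter
#' sequence (the named tool's convention).  A shared-word prefilter skips
#' alignments between sequences that cannot plausibly exceed the threshold;
#' it is conservative for the high thresholds this step is meant for.
NULL

#' Pairwise identity of two sequences
#'
#' Identity is the number of matching bases in the best global alignment
#' with free end gaps, divided by the shorter sequence length (the
#' CD-HIT-EST convention).  The alignment is an affine-gap dynamic program
#' (match +10, mismatch -20, gap open -100, gap extension -1; ties resolved
#' toward more matches), so one long internal deletion -- an isoform
#' difference -- costs little and two isoforms of one gene score as
#' near-identical over the shorter sequence, while chance matches between
#' unrelated sequences are not stitched together.
#'
#' @param a,b sequence strings (or length-1 [transcript_set()]s).
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (inherits(a, "transcript_set")) a <- a$seq[[1L]]
  if (inherits(b, "transcript_set")) b <- b$seq[[1L]]
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty")
  r <- align_ends_free_cpp(a, b)
  r$matches / min(nchar(a), nchar(b))
}

#' Collapse a transcript set at an identity threshold
#'
#' @param set a [transcript_set()].
#' @param threshold identity threshold in `(0, 1]`; membership requires
#'   identity strictly greater than this (default 0.99).
#' @param word_size word length of the shared-word prefilter (default 10).
#' @param min_shared_words shared-word count required before a full
#'   alignment is attempted (default 30).
#' @param use_prefilter set `FALSE` to align against every representative
#'   (oracle mode for small sets).
#' @return A list: `nonredundant` (a [transcript_set()] of representatives,
#'   longest first) and `clusters` (a `data.frame` with columns
#'   `representative_id`, `member_id`, `identity`; representatives appear as
#'   members of their own cluster with identity 1).
#' @export
collapse <- function(set, threshold = 0.99, word_size = 10L,
                     min_shared_words = 30L, use_prefilter = TRUE) {
  stopifnot(inherits(set, "transcript_set"),
            threshold > 0, threshold <= 1)
  n <- length(set)
  if (n == 0L) {
    return(list(
      nonredundant = transcript_set(character(0), character(0),
                                    provenance = set$provenance),
      clusters = data.frame(representative_id = character(),
                            member_id = character(), identity = numeric(),
                            stringsAsFactors = FALSE)))
  }
  lens <- transcript_lengths(set)
  ord <- order(-lens, set$id)
  ids <- set$id[ord]
  seqs <- unname(set$seq[ord])

  rep_ids <- character(0)
  rep_seqs <- character(0)
  rep_words <- list()
  members <- vector("list", 0L)
  identities <- vector("list", 0L)

  words_of <- function(s) unique(kmer_codes_cpp(s, word_size))

  for (i in seq_len(n)) {
    w <- if (use_prefilter) words_of(seqs[[i]]) else NULL
    assigned <- FALSE
    for (k in seq_along(rep_ids)) {
      if (use_prefilter) {
        shared <- sum(w %in% rep_words[[k]])
        if (shared < min_shared_words) next
      }
      idn <- pairwise_identity(seqs[[i]], rep_seqs[[k]])
      if (idn > threshold) {
        members[[k]] <- c(members[[k]], ids[[i]])
        identities[[k]] <- c(identities[[k]], idn)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_ids <- c(rep_ids, ids[[i]])
      rep_seqs <- c(rep_seqs, seqs[[i]])
      if (use_prefilter) rep_words[[length(rep_ids)]] <- w
      members[[length(rep_ids)]] <- ids[[i]]
      identities[[length(rep_ids)]] <- 1.0
    }
  }

  clusters <- do.call(rbind, lapply(seq_along(rep_ids), function(k) {
    data.frame(representative_id = rep_ids[[k]],
               member_id = members[[k]],
               identity = identities[[k]],
               stringsAsFactors = FALSE)
  }))
  nonred <- transcript_set(rep_ids, rep_seqs,
                           desc = unname(set$desc[rep_ids]),
                           provenance = set$provenance)
  list(nonredundant = nonred, clusters = clusters)
}
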