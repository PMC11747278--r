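#' @name synthetic_data
#' @title Synthetic transcriptome generation with a ground-truth manifest
#'
#' @description
#' Generates transcript sets whose planted features (redundant
#' near-identical copies, alternative-splicing isoform pairs, SSR loci,
#' complete ORFs, stop-rich noncoding transcripts) are recorded in a
#' manifest, so every downstream detector can be validated without the
#' study's deposited reads.  All planted geometry satisfies the detectors'
#' thresholds by construction: AS gaps exceed `gap_min` and keep
#' `end_margin` distance from both transcript ends, the bases flanking each
#' AS junction are made unequal so the gap coordinates are unambiguous, SSR
#' runs are guarded so they cannot extend into their flanks, and accidental
#' (unplanted) SSR runs arising from the random background are disrupted.
NULL

.bases <- c("A", "C", "G", "T")

# position-specific nucleotide frequencies used for planted ORF codons;
# the pronounced codon-position bias mimics real coding sequence so that
# composition-based coding-potential scorers see a realistic signal
.codon_pos_freq <- list(
  c(A = 0.20, C = 0.14, G = 0.32, T = 0.34),
  c(A = 0.38, C = 0.20, G = 0.12, T = 0.30),
  c(A = 0.12, C = 0.42, G = 0.36, T = 0.10)
)

# 22-mer carrying stop codons in all three forward and all three reverse
# frames; inserted periodically into noncoding transcripts
.stop_cassette <- "TAAGTAAGTAATTAGTTAGTTA"

.default_sim_params <- function() {
  list(
    end_margin = 100L,          # min distance of an AS gap from either end
    gap_min = 100L,             # AS gap strictly larger than this
    gap_len_range = c(121L, 400L),
    orf_aa_range = c(120L, 450L),
    utr5_range = c(80L, 250L),
    utr3_range = c(100L, 350L),
    noncoding_len_range = c(800L, 3000L),
    copy_sub_rate = 0.002,      # per-base substitutions in redundant copies
    cassette_spacing = 100L,
    ssr_extra_max = 4L,         # planted repeat count = minimum + 0..this
    min_repeats = as.list(.default_min_repeats)
  )
}

.rand_chars <- function(n) sample(.bases, n, replace = TRUE)

# sample m sense codons with position-specific base frequencies
.sample_codons <- function(m) {
  if (m == 0L) return(character(0))
  draw <- function(k) {
    vapply(1:3, function(p) sample(.bases, k, TRUE,
                                   prob = .codon_pos_freq[[p]]),
           character(k))
  }
  mat <- matrix(draw(m), nrow = m)
  cod <- paste0(mat[, 1L], mat[, 2L], mat[, 3L])
  while (any(bad <- cod %in% .stop_codons)) {
    k <- sum(bad)
    m2 <- matrix(draw(k), nrow = k)
    cod[bad] <- paste0(m2[, 1L], m2[, 2L], m2[, 3L])
  }
  cod
}

# non-periodic repeat unit of length u
.sample_motif <- function(u) {
  repeat {
    m <- paste(.rand_chars(u), collapse = "")
    if (!.is_periodic_motif(m)) return(m)
  }
}

# substitute positions `pos` of a char vector with random different bases
.substitute <- function(chars, pos) {
  for (p in pos) {
    chars[[p]] <- sample(setdiff(.bases, chars[[p]]), 1L)
  }
  chars
}

# disrupt unplanted SSR runs; protected positions are never touched and
# inside an ORF no in-frame stop is created
.scrub_ssrs <- function(chars, planted, protected, orf_range, min_repeats,
                        max_iter = 25L) {
  mr <- unlist(min_repeats)
  pk <- if (!is.null(planted) && nrow(planted)) {
    paste(planted$start, planted$unit_length, planted$repeat_count)
  } else character(0)
  for (iter in seq_len(max_iter)) {
    cand <- ssr_candidates(paste(chars, collapse = ""), mr)
    if (!nrow(cand)) break
    ck <- paste(cand$start, cand$unit_length, cand$repeat_count)
    acc <- cand[!(ck %in% pk), , drop = FALSE]
    if (!nrow(acc)) break
    changed <- FALSE
    for (i in seq_len(nrow(acc))) {
      span <- acc$start[[i]]:acc$end[[i]]
      allowed <- span[!protected[span]]
      if (!length(allowed)) next
      pos <- allowed[[which.min(abs(allowed - mean(range(span))))]]
      cur <- chars[[pos]]
      opts <- setdiff(.bases, cur)
      # avoid equalling immediate neighbours (would seed mono runs)
      nb <- c(if (pos > 1L) chars[[pos - 1L]],
              if (pos < length(chars)) chars[[pos + 1L]])
      opts <- opts[order(opts %in% nb)]
      if (!is.null(orf_range) && pos >= orf_range[[1L]] &&
          pos <= orf_range[[2L]]) {
        ci <- (pos - orf_range[[1L]]) %/% 3L
        c0 <- orf_range[[1L]] + 3L * ci
        ok <- vapply(opts, function(b) {
          cod <- chars[c0:(c0 + 2L)]
          cod[[pos - c0 + 1L]] <- b
          !(paste(cod, collapse = "") %in% .stop_codons)
        }, TRUE)
        opts <- opts[ok]
      }
      if (!length(opts)) next
      chars[[pos]] <- opts[[1L]]
      changed <- TRUE
    }
    if (!changed) break
  }
  chars
}

#' Simulate a full-length transcriptome with planted features
#'
#' Each gene yields either one transcript plus `cluster_redundancy - 1`
#' near-identical copies (per-base substitution rate `copy_sub_rate`), or --
#' for alternative-splicing genes -- a long "distinct" isoform and a short
#' "continuous" isoform equal to the long one with a single internal segment
#' deleted.  Coding genes carry one planted complete ORF (biased codon
#' composition, in-frame stop immediately upstream of the ATG so the ORF
#' start is unambiguous); noncoding genes are built over a stop-cassette
#' background that places stop codons in all six frames of every 150-base
#' window.  Selected genes carry one guarded SSR run.  Point mutations are
#' applied at `noise_rate` outside all planted features.
#'
#' @param n_genes number of genes (>= 0).
#' @param as_fraction fraction of genes emitting an isoform pair with a
#'   planted AS gap.
#' @param ssr_fraction fraction of genes carrying a planted SSR (drawn from
#'   the non-AS genes).
#' @param noncoding_fraction fraction of genes generated as stop-rich
#'   noncoding transcripts (drawn from the non-AS genes).
#' @param cluster_redundancy total near-identical copies per non-AS gene
#'   (1 = no redundancy).
#' @param noise_rate per-base substitution probability outside planted
#'   features.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param params named list overriding entries of the generator
#'   configuration (see the package vignette); unknown names are an error.
#' @return A list with elements `set` (a [transcript_set()], provenance
#'   `"synthetic"`) and `manifest` (see [write_manifest()]).
#' @export
simulate_transcriptome <- function(n_genes,
                                   as_fraction = 0.1,
                                   ssr_fraction = 0.1,
                                   noncoding_fraction = 0.15,
                                   cluster_redundancy = 2L,
                                   noise_rate = 0.002,
                                   seed = 1L,
                                   params = list()) {
  stopifnot(n_genes >= 0,
            as_fraction >= 0, as_fraction <= 1,
            ssr_fraction >= 0, ssr_fraction <= 1,
            noncoding_fraction >= 0, noncoding_fraction <= 1,
            cluster_redundancy >= 1L, noise_rate >= 0, noise_rate <= 1)
  p <- .default_sim_params()
  unknown <- setdiff(names(params), names(p))
  if (length(unknown)) stop("unknown generator parameter: ", unknown[[1L]])
  p[names(params)] <- params

  min_coding_len <- p$utr5_range[[1L]] + 3L * (p$orf_aa_range[[1L]] + 1L) +
    p$utr3_range[[1L]]
  if (n_genes > 0 && as_fraction > 0 &&
      min_coding_len < 2L * p$end_margin + p$gap_len_range[[1L]]) {
    stop(sprintf(paste0(
      "transcripts too short for the requested AS geometry: ",
      "need at least %d nt (2*end_margin + minimum gap); ",
      "increase utr/orf length ranges"),
      2L * p$end_margin + p$gap_len_range[[1L]]))
  }

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))

  empty_manifest <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    generator = list(as_fraction = as_fraction, ssr_fraction = ssr_fraction,
                     noncoding_fraction = noncoding_fraction,
                     cluster_redundancy = as.integer(cluster_redundancy),
                     noise_rate = noise_rate),
    planted_as_events = data.frame(
      distinct_id = character(), continuous_id = character(),
      gap_start = integer(), gap_end = integer(), gap_length = integer(),
      stringsAsFactors = FALSE),
    planted_ssrs = data.frame(
      transcript_id = character(), motif = character(),
      unit_length = integer(), repeat_count = integer(),
      start = integer(), end = integer(), stringsAsFactors = FALSE),
    planted_orfs = data.frame(
      transcript_id = character(), start = integer(), end = integer(),
      strand = character(), completeness = character(),
      protein_length = integer(), stringsAsFactors = FALSE),
    planted_clusters = list(),
    noncoding_ids = character())

  if (n_genes == 0) {
    return(list(set = transcript_set(character(0), character(0),
                                     provenance = "synthetic"),
                manifest = empty_manifest))
  }

  n_as <- round(n_genes * as_fraction)
  as_genes <- sort(sample.int(n_genes, n_as))
  non_as <- setdiff(seq_len(n_genes), as_genes)
  n_nc <- round(n_genes * noncoding_fraction)
  if (n_nc > length(non_as)) {
    stop("as_fraction + noncoding_fraction leave too few genes")
  }
  nc_genes <- sort(sample(non_as, n_nc))
  n_ssr <- round(n_genes * ssr_fraction)
  if (n_ssr > length(non_as)) {
    stop("as_fraction + ssr_fraction leave too few genes")
  }
  ssr_genes <- sort(sample(non_as, n_ssr))

  ids <- character(0); seqs <- character(0)
  man <- empty_manifest
  as_rows <- list(); ssr_rows <- list(); orf_rows <- list()
  clusters <- list(); nc_ids <- character(0)

  mr <- p$min_repeats

  for (g in seq_len(n_genes)) {
    gid <- sprintf("g%04d", g)
    is_nc <- g %in% nc_genes
    is_as <- g %in% as_genes
    has_ssr <- g %in% ssr_genes

    if (is_nc) {
      L <- sample(p$noncoding_len_range[[1L]]:p$noncoding_len_range[[2L]], 1L)
      chars <- .rand_chars(L)
      cw <- nchar(.stop_cassette)
      cas_starts <- seq(1L, L - cw + 1L, by = p$cassette_spacing)
      cas_chars <- strsplit(.stop_cassette, "")[[1L]]
      protected <- logical(L)
      for (cs in cas_starts) {
        chars[cs:(cs + cw - 1L)] <- cas_chars
        protected[cs:(cs + cw - 1L)] <- TRUE
      }
      orf_range <- NULL
    } else {
      paa <- sample(p$orf_aa_range[[1L]]:p$orf_aa_range[[2L]], 1L)
      utr5 <- sample(p$utr5_range[[1L]]:p$utr5_range[[2L]], 1L)
      utr3 <- sample(p$utr3_range[[1L]]:p$utr3_range[[2L]], 1L)
      orf_nt <- 3L * (paa + 1L)
      L <- utr5 + orf_nt + utr3
      orf_start <- utr5 + 1L
      orf_end <- utr5 + orf_nt
      body <- unlist(strsplit(.sample_codons(paa - 1L), ""))
      stopc <- sample(.stop_codons, 1L)
      chars <- c(.rand_chars(utr5 - 3L), c("T", "A", "A"),
                 c("A", "T", "G"), body, strsplit(stopc, "")[[1L]],
                 .rand_chars(utr3))
      stopifnot(length(chars) == L)
      protected <- logical(L)
      protected[(utr5 - 2L):orf_end] <- TRUE   # leading stop + whole ORF
      orf_range <- c(orf_start, orf_end)
      orf_rows[[length(orf_rows) + 1L]] <- data.frame(
        transcript_id = paste0(gid, "_i1"), start = orf_start,
        end = orf_end, strand = "+", completeness = "complete",
        protein_length = paa, stringsAsFactors = FALSE)
    }

    ssr_here <- NULL
    if (has_ssr) {
      u <- sample(1:6, 1L)
      reps <- as.integer(mr[[as.character(u)]]) + sample(0:p$ssr_extra_max, 1L)
      motif <- .sample_motif(u)
      span <- u * reps
      # free windows: outside protected regions, away from transcript ends
      free <- !protected
      free[c(seq_len(6L), (L - span - 6L):L)] <- FALSE
      r <- rle(free)
      rend <- cumsum(r$lengths); rstart <- rend - r$lengths + 1L
      wins <- which(r$values & r$lengths >= span + 2L)
      if (length(wins)) {
        w <- if (length(wins) > 1L) sample(wins, 1L) else wins
        off_max <- r$lengths[[w]] - span - 1L
        pos <- rstart[[w]] + 1L + sample.int(off_max, 1L) - 1L
        chars[pos:(pos + span - 1L)] <-
          rep(strsplit(motif, "")[[1L]], reps)
        mu <- substr(motif, u, u)
        chars[[pos - 1L]] <- setdiff(.bases, mu)[[1L]]
        m1 <- substr(motif, 1L, 1L)
        chars[[pos + span]] <- setdiff(.bases, m1)[[1L]]
        g0 <- max(1L, pos - 1L - 6L):min(L, pos + span + 6L)
        protected[g0] <- TRUE
        ssr_here <- data.frame(motif = motif, unit_length = u,
                               repeat_count = reps, start = pos,
                               end = pos + span - 1L,
                               stringsAsFactors = FALSE)
      }
    }

    chars <- .scrub_ssrs(chars, ssr_here, protected, orf_range, mr)
    # background noise, then re-scrub anything the noise created
    if (noise_rate > 0) {
      hits <- which(stats::runif(L) < noise_rate & !protected)
      if (length(hits)) {
        chars <- .substitute(chars, hits)
        chars <- .scrub_ssrs(chars, ssr_here, protected, orf_range, mr)
      }
    }

    if (is_as) {
      id1 <- paste0(gid, "_i1"); id2 <- paste0(gid, "_i2")
      dmax <- min(p$gap_len_range[[2L]], L - 2L * p$end_margin)
      dmin <- max(p$gap_len_range[[1L]], p$gap_min + 1L)
      if (dmax < dmin) {
        stop(sprintf(paste0(
          "transcript of %d nt too short for requested gap+margins; ",
          "needs at least %d nt"), L, 2L * p$end_margin + dmin))
      }
      for (try in 1:50) {
        del_len <- sample(dmin:dmax, 1L)
        ds <- sample((p$end_margin + 1L):(L - p$end_margin - del_len + 1L), 1L)
        de <- ds + del_len - 1L
        guard <- c(ds, de)
        in_edge_codon <- !is.null(orf_range) && any(
          guard >= orf_range[[1L]] & guard <= orf_range[[1L]] + 2L |
            guard >= orf_range[[2L]] - 2L & guard <= orf_range[[2L]])
        if (!in_edge_codon) break
      }
      fix_base <- function(pos, forbid) {
        if (chars[[pos]] != forbid) return(invisible(NULL))
        opts <- setdiff(.bases, c(forbid, chars[[pos]]))
        if (!is.null(orf_range) && pos >= orf_range[[1L]] &&
            pos <= orf_range[[2L]]) {
          ci <- (pos - orf_range[[1L]]) %/% 3L
          c0 <- orf_range[[1L]] + 3L * ci
          ok <- vapply(opts, function(b) {
            cod <- chars[c0:(c0 + 2L)]
            cod[[pos - c0 + 1L]] <- b
            !(paste(cod, collapse = "") %in% .stop_codons)
          }, TRUE)
          opts <- opts[ok]
        }
        stopifnot(length(opts) > 0L)
        chars[[pos]] <<- opts[[1L]]
        invisible(NULL)
      }
      # make the junction unambiguous: the first deleted base must differ
      # from the first retained base after the gap, and symmetrically
      fix_base(ds, chars[[de + 1L]])
      fix_base(de, chars[[ds - 1L]])
      distinct <- chars
      continuous <- chars[-(ds:de)]
      ids <- c(ids, id1, id2)
      seqs <- c(seqs, paste(distinct, collapse = ""),
                paste(continuous, collapse = ""))
      as_rows[[length(as_rows) + 1L]] <- data.frame(
        distinct_id = id1, continuous_id = id2,
        gap_start = ds, gap_end = de, gap_length = del_len,
        stringsAsFactors = FALSE)
      clusters[[gid]] <- c(id1, id2)
    } else {
      member_ids <- paste0(gid, c("_i1",
        if (cluster_redundancy > 1L) paste0("_c", 2:cluster_redundancy)))
      ids <- c(ids, member_ids[[1L]])
      seqs <- c(seqs, paste(chars, collapse = ""))
      if (!is.null(ssr_here)) {
        ssr_rows[[length(ssr_rows) + 1L]] <-
          cbind(transcript_id = member_ids[[1L]], ssr_here)
      }
      if (cluster_redundancy > 1L) {
        for (j in 2:cluster_redundancy) {
          cp <- chars
          hits <- which(stats::runif(L) < p$copy_sub_rate & !protected)
          if (length(hits)) cp <- .substitute(cp, hits)
          cp <- .scrub_ssrs(cp, ssr_here, protected, orf_range, mr)
          ids <- c(ids, member_ids[[j]])
          seqs <- c(seqs, paste(cp, collapse = ""))
          if (!is.null(ssr_here)) {
            ssr_rows[[length(ssr_rows) + 1L]] <-
              cbind(transcript_id = member_ids[[j]], ssr_here)
          }
        }
      }
      clusters[[gid]] <- member_ids
      if (is_nc) nc_ids <- c(nc_ids, member_ids)
    }
  }

  man$planted_as_events <- if (length(as_rows)) {
    do.call(rbind, as_rows)
  } else man$planted_as_events
  man$planted_ssrs <- if (length(ssr_rows)) {
    do.call(rbind, ssr_rows)
  } else man$planted_ssrs
  man$planted_orfs <- if (length(orf_rows)) {
    do.call(rbind, orf_rows)
  } else man$planted_orfs
  man$planted_clusters <- clusters
  man$noncoding_ids <- nc_ids

  list(set = transcript_set(ids, seqs, provenance = "synthetic"),
       manifest = man)
}

.manifest_fields <- c("seed", "n_genes", "generator", "planted_as_events",
                      "planted_ssrs", "planted_orfs", "planted_clusters",
                      "noncoding_ids")

#' Write / read a synthetic-data manifest as JSON
#'
#' @param manifest a manifest from [simulate_transcriptome()].
#' @param path JSON path.
#' @return `write_manifest()`: invisibly, `path`; `read_manifest()`: the
#'   manifest list (data frames restored).
#' @export
write_manifest <- function(manifest, path) {
  missing <- setdiff(.manifest_fields, names(manifest))
  if (length(missing)) stop("manifest is missing field: ", missing[[1L]])
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(.manifest_fields, names(m))
  if (length(missing)) stop("manifest is missing field: ", missing[[1L]])
  fix_df <- function(x, template) {
    if (is.data.frame(x) && nrow(x)) return(x[, names(template), drop = FALSE])
    template
  }
  tpl <- simulate_transcriptome(0)$manifest
  m$planted_as_events <- fix_df(as.data.frame(m$planted_as_events),
                                tpl$planted_as_events)
  m$planted_ssrs <- fix_df(as.data.frame(m$planted_ssrs), tpl$planted_ssrs)
  m$planted_orfs <- fix_df(as.data.frame(m$planted_orfs), tpl$planted_orfs)
  m$planted_clusters <- lapply(m$planted_clusters, unlist)
  m$noncoding_ids <- as.character(unlist(m$noncoding_ids))
  m
}

#' Check a manifest against the transcript set it describes
#'
#' Verifies that every referenced id exists and that planted AS geometry
#' satisfies the detector's discoverability constraints.
#'
#' @param manifest a manifest list.
#' @param set the matching [transcript_set()].
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_manifest <- function(manifest, set) {
  refs <- c(manifest$planted_as_events$distinct_id,
            manifest$planted_as_events$continuous_id,
            manifest$planted_ssrs$transcript_id,
            manifest$planted_orfs$transcript_id,
            unlist(manifest$planted_clusters),
            manifest$noncoding_ids)
  bad <- setdiff(unique(refs), set$id)
  if (length(bad)) stop("manifest references unknown id: ", bad[[1L]])
  ev <- manifest$planted_as_events
  if (nrow(ev)) {
    len <- transcript_lengths(set)[ev$distinct_id]
    gm <- manifest$generator
    glen <- ev$gap_end - ev$gap_start + 1L
    if (any(glen != ev$gap_length)) stop("inconsistent gap_length")
    if (any(glen <= 100L)) stop("planted gap not larger than 100 bp")
    margin <- pmin(ev$gap_start - 1L, len - ev$gap_end)
    if (any(margin < 100L)) stop("planted gap closer than 100 bp to an end")
  }
  invisible(TRUE)
}
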