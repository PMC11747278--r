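# Independent reference implementations used as oracles, plus small
# fixture builders.  These deliberately share no code with the package.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

# Plain-R ends-free affine-gap alignment (Gotoh), same scoring convention
# as the package aligner (match +10, mismatch -20, open -100, ext -1),
# maximizing score then matches.  Returns matches in the best alignment.
oracle_ends_free_matches <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  better <- function(s1, c1, s2, c2) s1 > s2 || (s1 == s2 && c1 > c2)
  SM <- matrix(NEG, n + 1, m + 1); CM <- matrix(0L, n + 1, m + 1)
  SX <- matrix(NEG, n + 1, m + 1); CX <- matrix(0L, n + 1, m + 1)
  SY <- matrix(NEG, n + 1, m + 1); CY <- matrix(0L, n + 1, m + 1)
  SM[1, ] <- 0; SM[, 1] <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- SM[i - 1, j - 1]; cc <- CM[i - 1, j - 1]
      if (better(SX[i - 1, j - 1], CX[i - 1, j - 1], s, cc)) {
        s <- SX[i - 1, j - 1]; cc <- CX[i - 1, j - 1]
      }
      if (better(SY[i - 1, j - 1], CY[i - 1, j - 1], s, cc)) {
        s <- SY[i - 1, j - 1]; cc <- CY[i - 1, j - 1]
      }
      mt <- A[i - 1] == B[j - 1]
      SM[i, j] <- s + if (mt) 10 else -20
      CM[i, j] <- cc + if (mt) 1L else 0L
      s <- SM[i - 1, j] - 101; cc <- CM[i - 1, j]
      if (better(SX[i - 1, j] - 1, CX[i - 1, j], s, cc)) {
        s <- SX[i - 1, j] - 1; cc <- CX[i - 1, j]
      }
      SX[i, j] <- s; CX[i, j] <- cc
      s <- SM[i, j - 1] - 101; cc <- CM[i, j - 1]
      if (better(SY[i, j - 1] - 1, CY[i, j - 1], s, cc)) {
        s <- SY[i, j - 1] - 1; cc <- CY[i, j - 1]
      }
      SY[i, j] <- s; CY[i, j] <- cc
    }
  }
  bs <- 0; bc <- 0L
  for (i in 1:(n + 1)) {
    for (st in list(c(SM[i, m + 1], CM[i, m + 1]),
                    c(SX[i, m + 1], CX[i, m + 1]),
                    c(SY[i, m + 1], CY[i, m + 1]))) {
      if (better(st[1], st[2], bs, bc)) { bs <- st[1]; bc <- st[2] }
    }
  }
  for (j in 1:(m + 1)) {
    for (st in list(c(SM[n + 1, j], CM[n + 1, j]),
                    c(SX[n + 1, j], CX[n + 1, j]),
                    c(SY[n + 1, j], CY[n + 1, j]))) {
      if (better(st[1], st[2], bs, bc)) { bs <- st[1]; bc <- st[2] }
    }
  }
  bc
}

oracle_identity <- function(a, b) {
  oracle_ends_free_matches(a, b) / min(nchar(a), nchar(b))
}

# Regex-backreference SSR oracle: maximal perfect tandem runs per unit
# size, trimmed to whole units, collapsed to non-periodic motifs.  No
# overlap resolution, no compound merging.
oracle_ssr_runs <- function(seq, min_repeats = c(`1` = 10, `2` = 6, `3` = 5,
                                                 `4` = 5, `5` = 5, `6` = 5)) {
  res <- list()
  for (u in 1:6) {
    minr <- min_repeats[[as.character(u)]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, minr - 1)
    mm <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (mm[1] == -1) next
    for (k in seq_along(mm)) {
      start <- mm[k]
      len <- attr(mm, "match.length")[k]
      motif <- substr(seq, start, start + u - 1)
      # periodic motifs belong to a smaller unit size
      periodic <- FALSE
      if (u > 1) for (d in 1:(u - 1)) {
        if (u %% d == 0 &&
            motif == strrep(substr(motif, 1, d), u / d)) periodic <- TRUE
      }
      if (periodic) next
      count <- len %/% u
      res[[length(res) + 1]] <- data.frame(
        motif = motif, unit_length = u, repeat_count = count,
        start = start, end = start + u * count - 1,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(motif = character(), unit_length = integer(),
                      repeat_count = integer(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$unit_length), , drop = FALSE]
}

# Brute-force complete-ORF oracle: every ATG scanned codon by codon to the
# first in-frame stop; earliest ATG kept per stop (both strands).
oracle_complete_orfs <- function(seq, min_protein_len = 100) {
  revcomp_chr <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }
  scan_one <- function(s) {
    n <- nchar(s)
    hits <- list()
    atg <- gregexpr("ATG", s, fixed = TRUE)[[1]]
    if (atg[1] == -1) return(hits)
    for (p in as.integer(atg)) {
      q <- p
      repeat {
        if (q + 2 > n) break
        cod <- substr(s, q, q + 2)
        if (q > p && cod %in% c("TAA", "TAG", "TGA")) {
          plen <- (q - p) / 3
          if (plen >= min_protein_len) {
            hits[[length(hits) + 1]] <- c(start = p, end = q + 2,
                                          plen = plen)
          }
          break
        }
        q <- q + 3
      }
    }
    if (!length(hits)) return(list())
    df <- as.data.frame(do.call(rbind, hits))
    # earliest ATG per stop-terminated interval
    df <- df[order(df$end, df$start), , drop = FALSE]
    df[!duplicated(df$end), , drop = FALSE]
  }
  fwd <- scan_one(seq)
  rc <- scan_one(revcomp_chr(seq))
  n <- nchar(seq)
  out <- list()
  if (length(fwd)) {
    out[[1]] <- cbind(as.data.frame(fwd), strand = "+")
  }
  if (length(rc)) {
    df <- as.data.frame(rc)
    out[[2]] <- data.frame(start = n - df$end + 1, end = n - df$start + 1,
                           plen = df$plen, strand = "-")
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      plen = integer(), strand = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

# Hand-rolled equal-variance two-sample t statistic
oracle_t_statistic <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
}

# Construct an isoform pair: continuous = distinct minus [del_start,
# del_end] (1-based inclusive), junction made unambiguous
make_as_pair <- function(len, del_start, del_end, seed = 1) {
  set.seed(seed)
  ch <- sample(BASES, len, replace = TRUE)
  if (ch[del_start] == ch[del_end + 1]) {
    ch[del_start] <- setdiff(BASES, ch[del_end + 1])[1]
  }
  if (ch[del_end] == ch[del_start - 1]) {
    ch[del_end] <- setdiff(BASES, ch[del_start - 1])[1]
  }
  distinct <- paste(ch, collapse = "")
  continuous <- paste(ch[-(del_start:del_end)], collapse = "")
  transcript_set(c("dst", "cnt"), c(distinct, continuous))
}
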