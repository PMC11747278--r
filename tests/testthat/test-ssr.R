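embed_run <- function(total_len, motif, reps, at, seed = 1) {
  set.seed(seed)
  ch <- sample(BASES, total_len, replace = TRUE)
  u <- nchar(motif)
  run <- rep(strsplit(motif, "")[[1]], reps)
  ch[at:(at + length(run) - 1L)] <- run
  # guard the flanks so the planted run is exactly maximal
  ch[at - 1L] <- setdiff(BASES, substr(motif, u, u))[1]
  ch[at + length(run)] <- setdiff(BASES, substr(motif, 1, 1))[1]
  paste(ch, collapse = "")
}

test_that("simple SSR detection honours motif, counts and the length filter", {
  s <- embed_run(600, "AG", 6, at = 200, seed = 60)
  loci <- scan_ssrs(transcript_set("t1", s))
  hit <- loci[loci$start == 200, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$type_class, "p2")
  expect_equal(hit$motif, "AG")
  expect_equal(hit$repeat_count, 6L)
  expect_equal(hit$end, 211L)

  # nine As stay below the mononucleotide minimum of ten
  s2 <- embed_run(600, "A", 9, at = 300, seed = 61)
  loci2 <- scan_ssrs(transcript_set("t1", s2))
  expect_false(any(loci2$start == 300))

  # transcripts under 500 bp are skipped entirely
  s3 <- embed_run(400, "ATC", 8, at = 150, seed = 62)
  expect_equal(nrow(scan_ssrs(transcript_set("t1", s3))), 0L)
  expect_equal(nrow(scan_ssrs(transcript_set(
    "t1", s3), min_transcript_len = 300L)), 1L)
})

test_that("periodic units are reported at the smallest unit size", {
  s <- embed_run(600, "AT", 8, at = 250, seed = 63)   # looks like (ATAT)x4 too
  loci <- scan_ssrs(transcript_set("t1", s))
  hit <- loci[loci$start == 250, ]
  expect_equal(hit$unit_length, 2L)
  expect_equal(hit$motif, "AT")
  expect_equal(hit$motif_canonical, "AT")
  # invariant: span length equals unit times count for simple loci
  simple <- loci[loci$type_class != "compound", ]
  expect_true(all(simple$end - simple$start + 1L ==
                    simple$unit_length * simple$repeat_count))
})

test_that("nearby loci merge into a compound locus with retained components", {
  set.seed(64)
  ch <- sample(BASES, 700, replace = TRUE)
  ch[200:211] <- rep(c("A", "G"), 6)
  ch[199] <- "C"; ch[212] <- "C"
  ch[232:246] <- rep(c("T", "T", "G"), 5)
  ch[231] <- "C"; ch[247] <- "C"
  s <- paste(ch, collapse = "")
  loci <- scan_ssrs(transcript_set("t1", s))
  comp <- loci[loci$type_class == "compound", ]
  expect_equal(nrow(comp), 1L)
  expect_equal(comp$start, 200L)
  expect_equal(comp$end, 246L)
  expect_equal(comp$n_components, 2L)
  parts <- attr(loci, "components")
  expect_equal(nrow(parts), 2L)
  expect_setequal(parts$motif, c("AG", "TTG"))
  # far apart (> 100 bases): two simple loci instead
  ch2 <- ch
  ch2[232:246] <- sample(BASES, 15, replace = TRUE)
  ch2[400:414] <- rep(c("T", "T", "G"), 5)
  ch2[399] <- "C"; ch2[415] <- "C"
  loci2 <- scan_ssrs(transcript_set("t1", paste(ch2, collapse = "")))
  expect_true(all(loci2$type_class != "compound"))
})

test_that("scanning agrees with the regex oracle on random sequences", {
  set.seed(65)
  for (i in 1:200) {
    s <- random_dna(1000)
    got <- fltrx:::ssr_candidates(s)
    want <- oracle_ssr_runs(s)
    rownames(got) <- rownames(want) <- NULL
    got <- got[order(got$start, got$unit_length), ]
    want <- want[order(want$start, want$unit_length), ]
    expect_equal(got, want, ignore_attr = TRUE,
                 info = sprintf("sequence %d", i))
  }
})

test_that("reported simple loci never overlap and mirror under revcomp", {
  set.seed(66)
  # SSR-dense sequences provoke overlaps
  ch <- character(0)
  for (k in 1:30) {
    u <- sample(1:3, 1)
    ch <- c(ch, sample(BASES, 20, replace = TRUE),
            rep(strsplit(paste(sample(BASES, u), collapse = ""), "")[[1]],
                sample(6:12, 1)))
  }
  s <- paste(ch, collapse = "")
  loci <- scan_ssrs(transcript_set("t1", s), compound_max_interruption = 0L)
  if (nrow(loci) > 1L) {
    o <- order(loci$start)
    expect_true(all(loci$start[o][-1] > loci$end[o][-nrow(loci)]))
  }
  # guarded runs have exact spans, so coordinates mirror exactly
  set.seed(68)
  ch2 <- sample(BASES, 1200, replace = TRUE)
  spots <- c(100L, 300L, 500L, 700L, 900L)
  units <- c("A", "AG", "TTG", "GATC", "CGTAA")
  for (k in seq_along(spots)) {
    u <- nchar(units[k]); reps <- 12L %/% u + 5L
    run <- rep(strsplit(units[k], "")[[1]], reps)
    at <- spots[k]
    ch2[at:(at + length(run) - 1L)] <- run
    ch2[at - 1L] <- setdiff(BASES, substr(units[k], u, u))[1]
    ch2[at + length(run)] <- setdiff(BASES, substr(units[k], 1, 1))[1]
  }
  s <- paste(ch2, collapse = "")
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
              collapse = "")
  fw <- fltrx:::ssr_candidates(s)
  bw <- fltrx:::ssr_candidates(rc)
  n <- nchar(s)
  # unit sizes and repeat counts are direction-invariant
  expect_equal(sort(paste(fw$unit_length, fw$repeat_count)),
               sort(paste(bw$unit_length, bw$repeat_count)))
  # the guarded runs mirror with exact coordinates and revcomp motifs
  revcomp_m <- function(m) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", m), "")[[1]]), collapse = "")
  }
  for (k in seq_along(spots)) {
    u <- nchar(units[k]); reps <- 12L %/% u + 5L
    span <- u * reps
    hit <- bw[bw$start == n - (spots[k] + span - 1L) + 1L, ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$end, n - spots[k] + 1L)
    expect_equal(hit$repeat_count, reps)
    canon <- function(m) {
      u2 <- nchar(m)
      min(vapply(seq_len(u2) - 1L, function(r) {
        paste0(substr(m, r + 1L, u2), substr(m, 1L, r))
      }, ""))
    }
    expect_equal(canon(hit$motif), canon(revcomp_m(units[k])))
  }
})

test_that("type classification reproduces the study's SSR accounting", {
  # a transcript below the length filter yields no loci at all
  stats <- classify_ssr_types(scan_ssrs(transcript_set("t", strrep("ACGT", 100))))
  expect_equal(stats$total, 0L)
  expect_equal(unname(stats$counts), rep(0L, 7))

  # the published per-type counts, fed through the classifier
  counts <- c(p1 = 2089L, p2 = 817L, p3 = 1971L, p4 = 57L, p5 = 23L,
              p6 = 90L, compound = 359L)
  loci <- data.frame(
    transcript_id = sprintf("t%04d", seq_len(sum(counts))),
    type_class = rep(names(counts), counts),
    stringsAsFactors = FALSE)
  st <- classify_ssr_types(loci)
  expect_equal(st$total, 5406L)
  expect_equal(st$counts[["p1"]], 2089L)
  expect_equal(st$counts[["p3"]], 1971L)
  expect_equal(st$counts[["compound"]], 359L)
  expect_equal(pct(st$counts[["p1"]], st$total), 38.64)
  expect_equal(pct(st$counts[["p3"]], st$total), 36.46)
  expect_equal(pct(st$counts[["p5"]], st$total), 0.43)
})

test_that("scanning recovers exactly the planted SSR manifest", {
  sim <- simulate_transcriptome(40, as_fraction = 0, ssr_fraction = 0.5,
                                noncoding_fraction = 0.2,
                                cluster_redundancy = 2L, noise_rate = 0.002,
                                seed = 67)
  loci <- scan_ssrs(sim$set)
  planted <- sim$manifest$planted_ssrs
  # transcripts shorter than the filter could hide planted loci; the
  # generator's defaults keep everything above 500 nt
  expect_true(all(transcript_lengths(sim$set) >= 500L))
  key <- function(d) sort(paste(d$transcript_id, d$motif, d$start,
                                d$repeat_count))
  expect_equal(key(loci[loci$type_class != "compound", ]), key(planted))
  st <- classify_ssr_types(loci)
  expect_equal(st$total, nrow(planted))
  expect_equal(st$transcripts_with_ssr, length(unique(planted$transcript_id)))
})
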