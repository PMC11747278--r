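test_that("the ORF-length scorer applies its cutoff inclusively", {
  expect_equal(score_orf_fraction("x", NULL), "noncoding")
  rec <- function(plen) data.frame(protein_length = plen)
  expect_equal(score_orf_fraction("x", rec(200L)), "coding")
  expect_equal(score_orf_fraction("x", rec(99L)), "noncoding")
  expect_equal(score_orf_fraction("x", rec(100L)), "coding")  # >= rule
})

test_that("the Fickett statistic reproduces published-table arithmetic", {
  # A homopolymer: position parameter 200/201 for A (lowest bucket), zero
  # for C, G, T; content 1 for A (highest bucket), zero for the rest.
  # Working through the lookup tables by hand gives 0.3458.
  expect_equal(fickett_score(strrep("A", 600)), 0.3458, tolerance = 1e-12)
  expect_equal(score_fickett(strrep("A", 600)), "noncoding")
  expect_error(fickett_score(strrep("A", 199)), "200")
  # strong third-position bias scores as coding
  codons <- paste(rep(c("GAC", "AAG", "GTC", "CAC"), 75), collapse = "")
  expect_equal(score_fickett(codons), "coding")
})

test_that("built-in scorers separate planted coding from noncoding", {
  sim <- simulate_transcriptome(60, as_fraction = 0, ssr_fraction = 0,
                                noncoding_fraction = 0.4,
                                cluster_redundancy = 1L, seed = 91)
  res <- consensus_lncrna(sim$set)
  calls <- res$calls
  nc <- sim$manifest$noncoding_ids
  coding <- sim$manifest$planted_orfs$transcript_id
  frac <- function(ids, scorer, verdict) {
    mean(calls[[scorer]][match(ids, calls$transcript_id)] == verdict)
  }
  expect_gte(frac(nc, "fickett", "noncoding"), 0.9)
  expect_gte(frac(coding, "fickett", "coding"), 0.9)
  expect_gte(frac(nc, "orf", "noncoding"), 0.9)
  expect_gte(frac(coding, "orf", "coding"), 0.9)
  # consensus lncRNAs and confidently coding transcripts are disjoint
  lnc_ids <- calls$transcript_id[calls$consensus_lncrna]
  coding_calls <- calls$transcript_id[calls$orf == "coding" &
                                        !is.na(calls$orf)]
  expect_length(intersect(lnc_ids, coding_calls), 0L)
})

test_that("candidacy and consensus follow the strict length and set logic", {
  short <- transcript_set("s", random_dna(150))
  res <- consensus_lncrna(short, scorers = "orf")
  expect_false(res$calls$candidate)
  expect_false(res$calls$consensus_lncrna)
  expect_equal(res$venn$n_candidates, 0L)
  # exactly 200 nt is still excluded (strictly longer than 200)
  at200 <- transcript_set("s", random_dna(200))
  expect_equal(consensus_lncrna(at200, scorers = "orf")$venn$n_candidates, 0L)
  expect_equal(consensus_lncrna(
    transcript_set("s", random_dna(201)), scorers = "orf")$venn$n_candidates,
    1L)

  # verdict-matrix intersection: A noncoding for {x,y}, B for {y,z} -> {y}
  set.seed(92)
  ts <- transcript_set(c("x", "y", "z"),
                       vapply(rep(300L, 3), random_dna, ""))
  va <- c(x = "noncoding", y = "noncoding", z = "coding")
  vb <- c(x = "coding", y = "noncoding", z = "noncoding")
  res <- consensus_lncrna(ts, scorers = character(0),
                          verdicts = list(A = va, B = vb))
  expect_equal(res$calls$transcript_id[res$calls$consensus_lncrna], "y")
  expect_equal(res$venn$A, 2L)
  expect_equal(res$venn$B, 2L)
  expect_equal(res$venn$intersection, 1L)

  # a verdict table missing a candidate id names the id
  expect_error(consensus_lncrna(ts, scorers = character(0),
                                verdicts = list(A = va[-2])),
               "y")
  expect_error(consensus_lncrna(ts, scorers = character(0)), "scorer")
})

test_that("adding a scorer never grows the consensus set", {
  sim <- simulate_transcriptome(30, as_fraction = 0, ssr_fraction = 0,
                                noncoding_fraction = 0.5,
                                cluster_redundancy = 1L, seed = 93)
  one <- consensus_lncrna(sim$set, scorers = "orf")
  both <- consensus_lncrna(sim$set, scorers = c("orf", "fickett"))
  expect_lte(both$venn$intersection, one$venn$intersection)
  expect_lte(both$venn$intersection,
             min(unlist(both$venn[c("orf", "fickett")])))
  # venn marginals are reproduced exactly from the call matrix
  expect_equal(both$venn$orf,
               sum(both$calls$orf == "noncoding", na.rm = TRUE))
  expect_equal(both$venn$fickett,
               sum(both$calls$fickett == "noncoding", na.rm = TRUE))
  expect_equal(both$venn$intersection, sum(both$calls$consensus_lncrna))
})
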