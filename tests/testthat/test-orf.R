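test_that("ORF calling translates and classifies hand-built cases", {
  # complete ORF with hand translation
  t1 <- c(x = "ATGAAATAA")
  orfs <- find_orfs(t1, min_protein_len = 1L, strands = "forward_only")
  orfs <- orfs[orfs$completeness == "complete", ]
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$completeness, "complete")
  expect_equal(orfs$protein, "MK")
  expect_equal(orfs$protein_length, 2L)
  expect_equal(c(orfs$start, orfs$end), c(1L, 9L))
  expect_equal((orfs$end - orfs$start + 1L) %% 3L, 0L)

  # no ATG, no stop anywhere in frame 0: an internal ORF
  t2 <- c(y = strrep("CAC", 30))
  orfs2 <- find_orfs(t2, min_protein_len = 10L, strands = "forward_only")
  f0 <- orfs2[orfs2$frame == 0L, ]
  expect_equal(f0$completeness, "internal")
  expect_equal(f0$start, 1L)
  expect_equal(f0$protein_length, 30L)

  # no ATG but stop-terminated from the 5' edge: 5prime_partial
  t3 <- c(z = paste0(strrep("CAC", 20), "TAA", strrep("CAC", 5)))
  orfs3 <- find_orfs(t3, min_protein_len = 10L, strands = "forward_only")
  f0 <- orfs3[orfs3$frame == 0L, ]
  expect_equal(f0$completeness[1], "5prime_partial")
  expect_equal(f0$protein_length[1], 20L)

  # ATG without a downstream stop: 3prime_partial
  t4 <- c(w = paste0("TAA", "ATG", strrep("GCA", 20)))
  orfs4 <- find_orfs(t4, min_protein_len = 10L, strands = "forward_only")
  f0 <- orfs4[orfs4$frame == 0L, ]
  expect_equal(f0$completeness, "3prime_partial")
  expect_equal(f0$start, 4L)

  # codons containing N neither start, stop, nor translate
  t5 <- c(v = paste0("ATG", "AAN", "AAA", "TAA"))
  orfs5 <- find_orfs(t5, min_protein_len = 1L, strands = "forward_only")
  expect_equal(orfs5$protein[orfs5$completeness == "complete"], "MXK")
})

test_that("complete ORFs agree with the brute-force enumeration oracle", {
  set.seed(81)
  for (i in 1:100) {
    s <- random_dna(1000)
    minaa <- sample(c(20L, 50L), 1)
    got <- find_orfs(c(t = s), min_protein_len = minaa)
    got <- got[got$completeness == "complete", ]
    want <- oracle_complete_orfs(s, min_protein_len = minaa)
    expect_equal(nrow(got), nrow(want), info = sprintf("seq %d", i))
    key <- function(d) sort(paste(d$start, d$end, d$strand))
    expect_equal(key(got), key(want), info = sprintf("seq %d", i))
    expect_equal(sort(got$protein_length), sort(want$plen),
                 info = sprintf("seq %d", i))
  }
})

test_that("minus-strand ORFs mirror plus-strand ORFs of the revcomp", {
  set.seed(82)
  s <- random_dna(1200)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
              collapse = "")
  a <- find_orfs(c(t = s), min_protein_len = 30L)
  b <- find_orfs(c(t = rc), min_protein_len = 30L)
  n <- nchar(s)
  am <- a[a$strand == "-", ]
  bp <- b[b$strand == "+", ]
  expect_equal(sort(paste(n - am$end + 1L, n - am$start + 1L)),
               sort(paste(bp$start, bp$end)))
  expect_equal(sort(am$protein), sort(bp$protein))
  # total ORF count is invariant to transcript order in a set
  ts <- transcript_set(c("a", "b"), c(s, rc))
  ts_rev <- transcript_set(c("b", "a"), c(rc, s))
  expect_equal(nrow(find_orfs_set(ts, 30L)), nrow(find_orfs_set(ts_rev, 30L)))
})

test_that("representative ORF selection ranks length, completeness, position", {
  expect_null(select_best_orf(NULL))
  expect_null(select_best_orf(find_orfs(c(t = "CCCCCCCCC"), 100L)))
  orfs <- data.frame(
    transcript_id = "t", strand = c("+", "+"), frame = 0L,
    start = c(1L, 400L), end = c(363L, 642L),
    completeness = "complete", protein_length = c(120L, 80L),
    protein = "", stringsAsFactors = FALSE)
  expect_equal(select_best_orf(orfs)$protein_length, 120L)
  # tie on length: completeness rank wins
  tie <- orfs
  tie$protein_length <- 100L
  tie$completeness <- c("3prime_partial", "complete")
  expect_equal(select_best_orf(tie)$completeness, "complete")
  # full tie: leftmost start, then + strand
  tie2 <- tie
  tie2$completeness <- "complete"
  expect_equal(select_best_orf(tie2)$start, 1L)
  tie3 <- tie2
  tie3$start <- 1L; tie3$end <- 363L; tie3$strand <- c("-", "+")
  expect_equal(select_best_orf(tie3)$strand, "+")
})

test_that("protein-length histograms bin complete ORFs only", {
  expect_length(orf_length_histogram(find_orfs(c(t = "CCCCCC"), 100L)), 0L)
  rec <- data.frame(
    transcript_id = "t", strand = "+", frame = 0L, start = 1L, end = 3L,
    completeness = c("complete", "complete", "internal"),
    protein_length = c(150L, 199L, 170L), protein = "",
    stringsAsFactors = FALSE)
  h <- orf_length_histogram(rec)
  expect_equal(h[["[100,200)"]], 2L)
  expect_equal(sum(h), 2L)
})

test_that("planted complete ORFs are recovered with exact coordinates", {
  sim <- simulate_transcriptome(25, as_fraction = 0.2, ssr_fraction = 0.2,
                                noncoding_fraction = 0.2, noise_rate = 0,
                                seed = 83)
  orfs <- find_orfs_set(sim$set)
  complete <- orfs[orfs$completeness == "complete", ]
  planted <- sim$manifest$planted_orfs
  key <- paste(complete$transcript_id, complete$start, complete$end,
               complete$strand)
  want <- paste(planted$transcript_id, planted$start, planted$end,
                planted$strand)
  expect_true(all(want %in% key))
  # and the protein lengths match the manifest
  m <- merge(complete, planted,
             by = c("transcript_id", "start", "end"))
  expect_equal(m$protein_length.x, m$protein_length.y)
  # histogram over the planted transcripts matches the manifest
  planted_best <- complete[paste(complete$transcript_id, complete$start,
                                 complete$end, complete$strand) %in% want, ]
  expect_equal(unname(orf_length_histogram(planted_best)),
               unname(orf_length_histogram(data.frame(
                 completeness = planted$completeness,
                 protein_length = planted$protein_length))))
})
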