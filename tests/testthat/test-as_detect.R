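test_that("all-vs-all alignment finds the expected segment structure", {
  expect_equal(nrow(align_all_vs_all(transcript_set("a", random_dna(500)))),
               0L)
  set.seed(41)
  s <- random_dna(800)
  pair <- transcript_set(c("a", "b"), c(s, s))
  h <- align_all_vs_all(pair)
  # exactly one full-length HSP per direction
  expect_equal(nrow(h), 2L)
  expect_equal(sort(h$query_id), c("a", "b"))
  expect_true(all(h$q_start == 1L & h$q_end == 800L &
                    h$s_start == 1L & h$s_end == 800L))
  expect_true(all(h$identity == 1))
  expect_true(all(h$orientation == "forward"))

  iso <- make_as_pair(1000, 401, 550, seed = 42)
  h <- align_all_vs_all(iso)
  hq <- h[h$query_id == "cnt", ]
  expect_equal(nrow(hq), 2L)   # two HSPs flanking the deletion
  expect_equal(sort(hq$s_start), c(1L, 551L))
  expect_equal(sort(hq$q_end), c(400L, 850L))
})

test_that("reverse-orientation pairs are aligned with normalized coordinates", {
  set.seed(43)
  s <- random_dna(700)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
              collapse = "")
  pair <- transcript_set(c("f", "r"), c(s, rc))
  h <- align_all_vs_all(pair)
  expect_true(all(h$orientation == "reverse"))
  expect_true(all(h$s_start <= h$s_end))
  expect_equal(h$q_start[h$query_id == "f"], 1L)
  expect_equal(h$q_end[h$query_id == "f"], 700L)
})

test_that("a planted deletion yields one event with exact coordinates", {
  iso <- make_as_pair(1000, 401, 550, seed = 44)
  h <- align_all_vs_all(iso)
  ev <- detect_as_events(h, transcript_lengths(iso))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$continuous_id, "cnt")
  expect_equal(ev$distinct_id, "dst")
  expect_equal(ev$gap_start, 401L)
  expect_equal(ev$gap_end, 550L)
  expect_equal(ev$gap_length, 150L)
  expect_equal(ev$junction_overlap, 0L)
  expect_equal(ev$junction_pos, 400L)
  # brute-force check against the known construction
  d <- iso$seq[["dst"]]
  expect_equal(iso$seq[["cnt"]],
               paste0(substr(d, 1, 400), substr(d, 551, 1000)))

  # below the gap threshold: no event
  small <- make_as_pair(1000, 401, 480, seed = 45)
  ev2 <- detect_as_events(align_all_vs_all(small),
                          transcript_lengths(small))
  expect_equal(nrow(ev2), 0L)

  # too close to the 5' end: no event
  edge <- make_as_pair(1000, 51, 250, seed = 46)
  ev3 <- detect_as_events(align_all_vs_all(edge),
                          transcript_lengths(edge))
  expect_equal(nrow(ev3), 0L)
})

# geometric HSP fixtures allow exact boundary probing without an aligner:
# continuous length lc = 900, distinct length ld = lc + gap
hsp_fixture <- function(gap, margin_left = 400L, overlap = 0L,
                        lc = 900L) {
  gs <- margin_left + 1L
  ld <- lc + gap
  data.frame(
    query_id = "cnt", subject_id = "dst",
    q_start = c(1L, margin_left + 1L - overlap),
    q_end = c(margin_left, lc),
    s_start = c(1L, margin_left + gap + 1L - overlap),
    s_end = c(margin_left, ld),
    identity = 1, orientation = "forward", score = 1,
    stringsAsFactors = FALSE)
}

test_that("thresholds follow the strict/inclusive reading exactly", {
  lens <- function(gap) c(cnt = 900L, dst = 900L + gap)
  # gap of exactly 100 rejected, 101 accepted
  expect_equal(nrow(detect_as_events(hsp_fixture(100L), lens(100L))), 0L)
  expect_equal(nrow(detect_as_events(hsp_fixture(101L), lens(101L))), 1L)
  # end margin of 99 rejected, 100 accepted
  expect_equal(nrow(detect_as_events(hsp_fixture(150L, margin_left = 99L),
                                     lens(150L))), 0L)
  ev <- detect_as_events(hsp_fixture(150L, margin_left = 100L), lens(150L))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gap_start, 101L)
  # junction overlap of exactly 5 rejected, 4 accepted
  expect_equal(nrow(detect_as_events(hsp_fixture(150L, overlap = 5L),
                                     lens(150L))), 0L)
  ev <- detect_as_events(hsp_fixture(150L, overlap = 4L), lens(150L))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$junction_overlap, -4L)
  # joint coverage below 95% of the continuous sequence is rejected
  h <- hsp_fixture(150L)
  h$q_end[2] <- 840L; h$s_end[2] <- 990L
  expect_equal(nrow(detect_as_events(h, lens(150L))), 0L)
  # missing length entry is a hard error
  expect_error(detect_as_events(hsp_fixture(150L), c(cnt = 900L)), "dst")
})

test_that("detection is symmetric under query/subject relabelling", {
  h <- hsp_fixture(150L)
  swapped <- h
  swapped$query_id <- h$subject_id; swapped$subject_id <- h$query_id
  swapped$q_start <- h$s_start; swapped$q_end <- h$s_end
  swapped$s_start <- h$q_start; swapped$s_end <- h$q_end
  lens <- c(cnt = 900L, dst = 1050L)
  e1 <- detect_as_events(h, lens)
  e2 <- detect_as_events(swapped, lens)
  e3 <- detect_as_events(rbind(h, swapped), lens)
  expect_equal(e1, e2)
  expect_equal(e1, e3)
  expect_equal(nrow(e1), 1L)
})

test_that("raising gap_min can only shrink the event list", {
  sim <- simulate_transcriptome(20, as_fraction = 0.5, seed = 55,
                                params = list(gap_len_range = c(101L, 400L)))
  h <- align_all_vs_all(sim$set)
  lens <- transcript_lengths(sim$set)
  n_prev <- Inf
  for (gm in c(100L, 150L, 250L, 400L)) {
    n <- nrow(detect_as_events(h, lens, gap_min = gm))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("tabular alignment I/O round-trips and flags reverse orientation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("a", "b", "99.0", "500", "5", "0", "1", "500",
                     "101", "600", "0.0", "900"), collapse = "\t"), f)
  h <- read_alignment_tabular(f)
  expect_equal(h$orientation, "forward")
  expect_equal(h$identity, 0.99)
  writeLines(paste(c("a", "b", "98.0", "200", "4", "0", "1", "200",
                     "900", "701", "0.0", "350"), collapse = "\t"), f)
  h <- read_alignment_tabular(f)
  expect_equal(h$orientation, "reverse")
  expect_equal(h$s_start, 701L)
  expect_equal(h$s_end, 900L)

  writeLines("a\tb\tmalformed", f)
  expect_error(read_alignment_tabular(f), "line 1")

  iso <- make_as_pair(800, 301, 450, seed = 47)
  hs <- align_all_vs_all(iso)
  write_alignment_tabular(hs, f)
  back <- read_alignment_tabular(f)
  cols <- c("query_id", "subject_id", "q_start", "q_end",
            "s_start", "s_end", "orientation")
  expect_equal(back[cols], hs[cols], ignore_attr = TRUE)
  # events from re-read alignments match events from internal ones
  expect_equal(detect_as_events(back, transcript_lengths(iso)),
               detect_as_events(hs, transcript_lengths(iso)))
})

test_that("per-unigene summaries reproduce the study's event accounting", {
  expect_equal(summarize_as(NULL)$total_events, 0L)
  expect_equal(length(summarize_as(NULL)$histogram), 0L)

  # the published per-unigene distribution: 444 + 36 + 10 unigenes with
  # 1..3 events and three transcripts with 8, 6 and 4 events
  dist <- c(rep(1L, 444), rep(2L, 36), rep(3L, 10), 8L, 6L, 4L)
  ev <- do.call(rbind, lapply(seq_along(dist), function(i) {
    data.frame(continuous_id = sprintf("c%03d", i),
               distinct_id = sprintf("u%03d", i),
               gap_start = 200L + seq_len(dist[i]) * 120L,
               gap_end = 310L + seq_len(dist[i]) * 120L,
               stringsAsFactors = FALSE)
  }))
  sm <- summarize_as(ev)
  expect_equal(sm$total_events, 564L)
  expect_equal(sm$n_unigenes, 493L)
  expect_equal(sm$histogram[["1"]], 444L)
  expect_equal(sm$histogram[["2"]], 36L)
  expect_equal(sm$histogram[["3"]], 10L)
  expect_equal(sm$histogram[["8"]], 1L)
})

test_that("summaries group by cluster representative when clusters are given", {
  ev <- data.frame(continuous_id = c("b", "d"), distinct_id = c("a", "c"),
                   gap_start = c(200L, 220L), gap_end = c(320L, 340L),
                   stringsAsFactors = FALSE)
  clusters <- data.frame(representative_id = c("a", "a", "a", "a"),
                         member_id = c("a", "b", "c", "d"),
                         identity = 1, stringsAsFactors = FALSE)
  sm <- summarize_as(ev, clusters)
  expect_equal(sm$n_unigenes, 1L)
  expect_equal(sm$histogram[["2"]], 1L)
  expect_equal(sm$total_events, 2L)
})
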