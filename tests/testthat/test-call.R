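# Category classification and cleavage calling.

test_that("category definitions classify boundary cases correctly", {
  st <- list(max_count = 5, n_max_positions = 1, median_count = 2)
  expect_equal(classify_site(st, 5), 0L)   # unique maximum, > 1 read
  expect_equal(classify_site(st, 3), 2L)   # above median, below max
  expect_equal(classify_site(st, 2), 3L)   # tie at the median
  expect_equal(classify_site(st, 1), 4L)   # single raw read

  st2 <- list(max_count = 4, n_max_positions = 2, median_count = 3.0)
  expect_equal(classify_site(st2, 4), 1L)  # tied maximum
  expect_equal(classify_site(st2, 2), 3L)

  # a lone read that is also the transcript maximum stays category 4
  st3 <- list(max_count = 1, n_max_positions = 3, median_count = 1)
  expect_equal(classify_site(st3, 1), 4L)

  expect_error(classify_site(st, 0), "count")
})

test_that("classification matches a literal reading of the definitions", {
  set.seed(23)
  for (rep in 1:1000) {
    counts <- random_profile_counts()
    st <- profile_stats(counts)
    cnt <- sample(counts, 1)
    expect_identical(classify_site(st, cnt),
                     naive_category(st$max_count, st$n_max_positions,
                                    st$median_count, cnt))
  }
})

test_that("calls appear for every occupied position in the register window", {
  aln <- data.frame(mirna_id = "m1", transcript_id = "t1",
                    site_start = 91L, site_end = 111L, score = 1.5,
                    canonical_cleavage = 102L, pairing = "",
                    stringsAsFactors = FALSE)
  prof <- build_profiles(data.frame(
    tag = "x", transcript_id = "t1",
    position = c(102L, 104L, 300L), count = c(6, 2, 3),
    stringsAsFactors = FALSE))
  calls <- call_cleavages(aln, prof, window = 1)
  expect_equal(nrow(calls), 1)            # only 102 lies within +/- 1
  expect_equal(calls$offset, 0L)
  expect_equal(calls$raw_tags, 6)
  expect_equal(calls$category, 0L)        # unique maximum on t1

  # no signature within the window: no call at all
  aln2 <- aln; aln2$canonical_cleavage <- 200L
  expect_equal(nrow(call_cleavages(aln2, prof, window = 1)), 0)

  # widened register picks up the +2 neighbour as an independent call
  calls3 <- call_cleavages(aln, prof, window = 3)
  expect_equal(nrow(calls3), 2)
  expect_equal(sort(calls3$offset), c(0L, 2L))
})

test_that("a multi-register site reproduces the seven-position category split", {
  # seven occupied positions at offsets -2..+4 around the canonical
  # coordinate with counts 1,1,3,2,2,3,1, plus a distant higher peak fixing
  # the transcript maximum; median over the eight occupied counts is 2
  canon <- 100L
  positions <- c(canon + (-2:4), 500L)
  counts <- c(1, 1, 3, 2, 2, 3, 1, 10)
  prof <- build_profiles(data.frame(
    tag = "x", transcript_id = "t1", position = positions, count = counts,
    stringsAsFactors = FALSE))
  aln <- data.frame(mirna_id = "m1", transcript_id = "t1",
                    site_start = canon - 11L, site_end = canon + 9L,
                    score = 2, canonical_cleavage = canon, pairing = "",
                    stringsAsFactors = FALSE)
  calls <- call_cleavages(aln, prof, window = 4)
  expect_equal(nrow(calls), 7)
  split <- table(calls$category)
  expect_equal(as.integer(split[c("2", "3", "4")]), c(2L, 2L, 3L))
  # category re-derivation from the profile agrees call by call
  st <- profile_stats(profile_for(prof, "t1"))
  for (i in seq_len(nrow(calls))) {
    expect_equal(calls$category[i],
                 naive_category(st$max_count, st$n_max_positions,
                                st$median_count, calls$raw_tags[i]))
  }
})

test_that("one position cleaved by several miRNAs yields independent calls", {
  prof <- build_profiles(data.frame(
    tag = "x", transcript_id = "t1", position = c(46L, 80L),
    count = c(5, 2), stringsAsFactors = FALSE))
  aln <- data.frame(mirna_id = c("miR472a", "miR482b-3p"),
                    transcript_id = "t1",
                    site_start = c(35L, 33L), site_end = c(55L, 53L),
                    score = c(2, 3),
                    canonical_cleavage = c(46L, 44L), pairing = "",
                    stringsAsFactors = FALSE)
  calls <- call_cleavages(aln, prof, window = 2)
  expect_equal(nrow(calls), 2)
  expect_setequal(calls$mirna_id, c("miR472a", "miR482b-3p"))
  expect_true(all(calls$cleavage_position == 46))
  expect_equal(calls$offset[calls$mirna_id == "miR482b-3p"], 2L)
})

test_that("t-plot tables flag exactly the called positions", {
  prof <- data.frame(position = c(10L, 20L, 30L), count = c(2, 5, 1))
  calls <- data.frame(transcript_id = "t1", cleavage_position = 20L)
  tab <- tplot(prof, calls, transcript_id = "t1")
  expect_equal(nrow(tab), 3)
  expect_equal(sum(tab$is_call_site), 1)
  expect_true(tab$is_call_site[tab$position == 20])
  none <- tplot(prof, calls[0, , drop = FALSE], transcript_id = "t1")
  expect_false(any(none$is_call_site))
  expect_error(tplot(prof[0, ], calls), "empty")
  # plotting to file works
  f <- withr::local_tempfile(fileext = ".png")
  tplot(prof, calls, transcript_id = "t1", file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("t-plot flags biject with the call list on simulated data", {
  sim <- small_sim()
  pre <- preprocess_reads(sim$reads, sim$config$adapter,
                          ncrna_set = sim$ncrna)
  prof <- build_profiles(map_tags(pre$tags, sim$transcripts)$hits)
  al <- scan_catalog(setNames(sim$mature$sequence, sim$mature$id),
                     sim$transcripts)
  calls <- call_cleavages(al, prof, window = 1)
  for (tx in unique(calls$transcript_id)) {
    tab <- tplot(profile_for(prof, tx), calls, transcript_id = tx)
    flagged <- sort(tab$position[tab$is_call_site])
    called <- sort(unique(calls$cleavage_position[calls$transcript_id == tx]))
    expect_equal(flagged, called)
  }
})
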