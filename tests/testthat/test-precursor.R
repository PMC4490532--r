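# Precursor products, self-targeting, feedback loops and functional
# miRNA* duplexes.

test_that("products carry 1-based inclusive spans that re-extract exactly", {
  mir20 <- "TTGGCATTCTGTCCACCTCC"
  pre <- paste0(strrep("A", 37), mir20, strrep("G", 40))
  prods <- locate_products(data.frame(sequence = mir20, count = 2),
                           c(`pre-x` = pre))
  expect_equal(nrow(prods), 1)
  expect_equal(prods$span_start, 38)
  expect_equal(prods$span_end, 57)                  # 38 + 20 - 1
  expect_equal(prods$length, 20)
  expect_identical(substr(pre, prods$span_start, prods$span_end), mir20)

  # absent query: empty result
  expect_equal(nrow(locate_products("CTCTCTCTCTCTCTCTCTCT",
                                    c(`pre-x` = pre))), 0)

  # a query present in two precursors yields two rows
  prods2 <- locate_products(data.frame(sequence = mir20, count = 2),
                            c(a = pre, b = paste0("TT", pre)))
  expect_equal(nrow(prods2), 2)
  expect_equal(prods2$span_start[prods2$precursor_id == "b"], 40)

  # overlapping occurrences are all reported
  ov <- locate_products("AAAA", c(p = "GAAAAAC"))
  expect_equal(ov$span_start, c(2, 3))
})

test_that("product location equals the all-offsets oracle", {
  set.seed(31)
  pre <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  queries <- vapply(1:8, function(i) {
    p <- sample(380, 1); substr(pre, p, p + sample(18:21, 1) - 1)
  }, character(1))
  got <- locate_products(data.frame(sequence = queries, count = 1),
                         c(p1 = pre))
  oracle <- list()
  for (q in unique(queries)) {
    L <- nchar(q)
    for (s in seq_len(400 - L + 1)) {
      if (substr(pre, s, s + L - 1) == q) {
        oracle[[length(oracle) + 1]] <- c(s, s + L - 1)
      }
    }
  }
  oracle <- do.call(rbind, oracle)
  expect_equal(sort(got$span_start), sort(oracle[, 1]))
  expect_true(all(got$span_end == got$span_start + got$length - 1))
})

test_that("guides call cleavage on their own precursors when signal exists", {
  cfg <- sim_config(seed = 29, n_transcripts = 5, n_mirna_families = 3,
                    sites_per_mirna = 1, signal_mean = 6,
                    background_rate = 0, contaminant_fraction = 0,
                    self_cleavage_mean = 5)
  sim <- simulate_degradome(cfg)
  pre <- preprocess_reads(sim$reads, cfg$adapter, ncrna_set = sim$ncrna)
  pc <- precursor_self_targets(sim$mature, sim$hairpins, pre$tags)
  expect_gt(nrow(pc), 0)
  # the planted mid-hairpin cuts are recovered at their exact coordinates
  planted <- sim$hairpin_truth[sim$hairpin_truth$planted_signal > 0, ]
  key_calls <- paste(pc$mirna_id, pc$transcript_id, pc$cleavage_position)
  key_truth <- paste(planted$guide_id, planted$precursor_id,
                     planted$cleavage_position)
  expect_true(all(key_truth %in% key_calls))

  # no degradome signature on precursors: no calls
  empty_tags <- data.frame(sequence = character(), count = integer(),
                           stringsAsFactors = FALSE)
  expect_equal(nrow(precursor_self_targets(sim$mature, sim$hairpins,
                                           empty_tags)), 0)
})

test_that("feedback loops require family identity and cross-reference arms", {
  catalog <- data.frame(
    id = c("famA-5p", "famA-3p", "famB-5p", "famB-3p"),
    family = c("famA", "famA", "famB", "famB"),
    arm = c("5p", "3p", "5p", "3p"),
    precursor_id = c("pre-famA", "pre-famA", "pre-famB", "pre-famB"),
    stringsAsFactors = FALSE
  )
  calls <- data.frame(
    mirna_id = c("famA-5p", "famA-3p", "famB-5p"),
    transcript_id = c("pre-famA", "pre-famA", "pre-famA"),
    cleavage_position = c(22L, 110L, 50L),
    category = c(2L, 2L, 4L),
    stringsAsFactors = FALSE
  )
  loops <- detect_feedback_loops(calls, catalog)
  # famB-5p cleaving pre-famA is no loop (family mismatch)
  expect_equal(nrow(loops), 2)
  expect_setequal(loops$cleaving_strand_id, c("famA-5p", "famA-3p"))
  # both arms cleave the same precursor: mutually partnered
  expect_equal(loops$partner_strand_id[loops$cleaving_strand_id == "famA-5p"],
               "famA-3p")
  expect_equal(loops$partner_strand_id[loops$cleaving_strand_id == "famA-3p"],
               "famA-5p")
  # a lone-arm loop carries no partner
  solo <- detect_feedback_loops(calls[1, , drop = FALSE], catalog)
  expect_true(is.na(solo$partner_strand_id))
})

test_that("star pairs need at least one call on each duplex arm", {
  catalog <- data.frame(
    id = c("famA-5p", "famA-3p", "famB-5p", "famB-3p", "famC-5p", "famC-3p"),
    family = rep(c("famA", "famB", "famC"), each = 2),
    arm = rep(c("5p", "3p"), 3),
    stringsAsFactors = FALSE
  )
  calls <- data.frame(
    mirna_id = c("famA-5p", "famA-3p", "famB-3p", "famB-3p"),
    transcript_id = c("t1", "pre-famA", "t2", "t3"),
    stringsAsFactors = FALSE
  )
  sp <- functional_star_pairs(calls, catalog)
  # famA: one transcript call on 5p, one precursor call on 3p -> emitted
  expect_equal(nrow(sp), 1)
  expect_equal(sp$duplex_id, "famA")
  expect_equal(c(sp$fivep_calls, sp$threep_calls), c(1L, 1L))
  # strands without arm annotation are skipped with a warning
  cat2 <- rbind(catalog,
                data.frame(id = "orphan", family = "famD", arm = NA,
                           stringsAsFactors = FALSE))
  expect_warning(functional_star_pairs(calls, cat2), "annotation")
})
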