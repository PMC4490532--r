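# Synthetic degradome generator: determinism, coordinate bookkeeping and
# ground-truth consistency with the scorer.

test_that("transcriptome generation respects counts, bounds and determinism", {
  cfg <- sim_config(seed = 3, n_transcripts = 30,
                    transcript_length_range = c(200L, 400L))
  tx <- generate_transcriptome(cfg)
  expect_length(tx, 30)
  expect_true(all(nchar(tx) >= 200 & nchar(tx) <= 400))
  expect_false(anyDuplicated(names(tx)) > 0)
  expect_identical(tx, generate_transcriptome(cfg))

  empty <- generate_transcriptome(sim_config(seed = 3, n_transcripts = 0))
  expect_length(empty, 0)

  expect_error(sim_config(transcript_length_range = c(500L, 100L)),
               "degenerate")
  expect_error(sim_config(mirna_length = 17), "18")
})

test_that("simulation output files are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 5, n_transcripts = 6, n_mirna_families = 2,
                    transcript_length_range = c(300L, 500L),
                    sites_per_mirna = 1, signal_mean = 5,
                    background_rate = 0.002, contaminant_fraction = 0.05,
                    corruption_fraction = 0.1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_degradome(cfg, d1)
  simulate_degradome(cfg, d2)
  for (f in c("transcripts.fasta", "mirnas.fasta", "hairpins.fasta",
              "reads.fastq", "truth_sites.tsv", "truth_hairpins.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("hairpin arms carry consistent coordinates and star complementarity", {
  cfg <- sim_config(seed = 9, n_mirna_families = 6, mirna_length = 20)
  hp <- generate_hairpins(cfg)
  expect_equal(nrow(hp$mature), 12)
  # end = start + length - 1 and substring identity for every arm
  for (i in seq_len(nrow(hp$mature))) {
    row <- hp$mature[i, ]
    expect_equal(row$end, row$start + nchar(row$sequence) - 1L)
    expect_identical(substr(hp$hairpins[[row$precursor_id]], row$start, row$end),
                     row$sequence)
  }
  # each family has one 5p and one 3p arm
  expect_true(all(tapply(hp$mature$arm, hp$mature$family, function(a) {
    setequal(a, c("5p", "3p"))
  })))
  expect_identical(generate_hairpins(cfg)$mature, hp$mature)
})

test_that("zero planted star mismatches give an exact reverse complement", {
  cfg <- sim_config(seed = 4, n_mirna_families = 3,
                    star_edit_range = c(0L, 0L))
  hp <- generate_hairpins(cfg)
  for (fam in unique(hp$mature$family)) {
    arms <- hp$mature[hp$mature$family == fam, ]
    mir <- arms$sequence[arms$role == "mir"]
    star <- arms$sequence[arms$role == "star"]
    expect_identical(star, as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(mir))))
  }
})

test_that("planted scores follow the per-position edit rules", {
  # guide chosen so position 5 (G) admits a wobble and 15 is in the
  # uncored tail
  guide <- data.frame(id = "g1", sequence = "ACGTGACGTACGTACGTACGT",
                      stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 21, n_transcripts = 6, sites_per_mirna = 1,
                    transcript_length_range = c(300L, 400L))
  tx <- generate_transcriptome(cfg)

  perfect <- plant_target_sites(tx, guide, cfg, edits = list(integer(0)))
  expect_equal(perfect$truth$planted_score, 0)

  mm15 <- plant_target_sites(tx, guide, cfg,
                             edits = list(data.frame(position = 15,
                                                     type = "mismatch")))
  expect_equal(mm15$truth$planted_score, 1.0)

  gu5 <- plant_target_sites(tx, guide, cfg,
                            edits = list(data.frame(position = 5,
                                                    type = "gu")))
  expect_equal(gu5$truth$planted_score, 1.0)  # 0.5 doubled in the 2-13 core
})

test_that("ground truth re-scores exactly and sites sit inside transcripts", {
  sim <- small_sim()
  for (i in seq_len(nrow(sim$truth))) {
    row <- sim$truth[i, ]
    aln <- score_site(sim$mature$sequence[sim$mature$id == row$mirna_id],
                      sim$transcripts[[row$transcript_id]], row$site_start)
    expect_equal(aln$score, row$planted_score)
    expect_equal(aln$canonical_cleavage, row$canonical_cleavage)
    expect_lte(aln$site_end, nchar(sim$transcripts[[row$transcript_id]]))
  }
  # canonical_cleavage = site_start + L - 10
  L <- sim$config$mirna_length
  expect_equal(sim$truth$canonical_cleavage, sim$truth$site_start + L - 10L)
})

test_that("read simulation respects zero rates and adapter construction", {
  cfg0 <- sim_config(seed = 2, n_transcripts = 4, n_mirna_families = 1,
                     sites_per_mirna = 1, signal_mean = 0,
                     signal_dist = "fixed", background_rate = 0,
                     contaminant_fraction = 0)
  tx <- generate_transcriptome(cfg0)
  hp <- generate_hairpins(cfg0)
  planted <- plant_target_sites(tx, hp$mature[hp$mature$role == "mir", ], cfg0)
  sim0 <- simulate_reads(planted$transcripts, planted$truth, config = cfg0)
  expect_length(sim0$reads, 0)

  sim <- small_sim()  # corruption_fraction = 0
  expect_true(all(grepl(paste0(sim$config$adapter, "$"), sim$reads)))
})
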