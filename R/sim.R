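# Synthetic degradome generator: transcriptomes, miRNA/miRNA* hairpins,
# ncRNA contaminants and degradome read libraries with full ground truth,
# so the whole pipeline is testable without external sequencing data.
#
# Each generation stage seeds the RNG from config$seed plus a fixed stage
# offset, so individual stages are reproducible in isolation and the
# composed simulation is byte-deterministic.

#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic degradome
#' generator. Defaults describe a desk-scale library: tags of 18-24 nt
#' dominated by 20- and 21-mers, planted cleavage signal at the canonical
#' slicing position (opposite miRNA nucleotide 10), a thin uniform
#' background of single decay 5' ends, and a small ncRNA contaminant
#' admixture.
#'
#' @param seed Integer RNG seed; fixed seed implies byte-identical outputs.
#' @param n_transcripts Number of transcripts to generate.
#' @param transcript_length_range Length range (nt), inclusive.
#' @param n_mirna_families Number of miRNA families (one hairpin each).
#' @param mirna_length Mature miRNA length in nt (18-24).
#' @param sites_per_mirna Target sites planted per guide strand.
#' @param signal_mean Expected reads per planted site (Poisson mean; also the
#'   negative-binomial mean or the exact count, see `signal_dist`).
#' @param signal_dist `"poisson"` (default), `"nbinom"` (overdispersed, see
#'   `nb_dispersion`), or `"fixed"` (every site gets exactly `signal_mean`
#'   reads, useful for forcing single-read sites).
#' @param nb_dispersion Negative-binomial size parameter when
#'   `signal_dist = "nbinom"`.
#' @param background_rate Expected background 5' ends per transcript position
#'   (Poisson mean per position).
#' @param contaminant_fraction Proportion of the final library drawn from the
#'   ncRNA set.
#' @param corruption_fraction Proportion of reads deliberately corrupted
#'   (truncated below 18 nt, given an ambiguous base, or emitted without the
#'   adapter) to exercise the preprocessing filters.
#' @param adapter 3' adapter sequence appended to every read.
#' @param tag_length_weights Named numeric vector over lengths 18-24 giving
#'   the tag length distribution (defaults favour 20/21-mers).
#' @param site_edit_max Maximum number of mismatch/G:U edits planted per
#'   target site (0-2 keeps every planted score at or below 4 penalty units,
#'   within the default discovery cutoff).
#' @param star_edit_range Range (min, max) of mismatch/G:U edits planted in
#'   the miRNA* arm relative to perfect complementarity with the miR arm.
#' @param dual_strand_families Number of families whose star strand also
#'   receives planted target sites (making both duplex strands functional
#'   guides).
#' @param self_cleavage_mean Expected reads per hairpin-internal guided
#'   cleavage site (0 disables precursor self-cleavage signal).
#' @param self_cleavage_families Number of families (taken in catalog order)
#'   whose hairpins receive self-cleavage signal; NULL (default) means all.
#' @param one_site_per_transcript If TRUE (default) sites are planted on
#'   distinct transcripts while transcripts remain, keeping per-transcript
#'   signature maxima unambiguous.
#' @param n_ncrna,ncrna_length_range Size of the synthetic ncRNA contaminant
#'   set and its length range.
#' @param read_format `"fastq"` or `"fasta"`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 50L,
                       transcript_length_range = c(500L, 2000L),
                       n_mirna_families = 10L,
                       mirna_length = 21L,
                       sites_per_mirna = 3L,
                       signal_mean = 20,
                       signal_dist = c("poisson", "nbinom", "fixed"),
                       nb_dispersion = 5,
                       background_rate = 0.005,
                       contaminant_fraction = 0.05,
                       corruption_fraction = 0,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       tag_length_weights = c(`18` = 0.002, `19` = 0.005,
                                              `20` = 0.596, `21` = 0.384,
                                              `22` = 0.007, `23` = 0.004,
                                              `24` = 0.002),
                       site_edit_max = 2L,
                       star_edit_range = c(1L, 3L),
                       dual_strand_families = 0L,
                       self_cleavage_mean = 0,
                       self_cleavage_families = NULL,
                       one_site_per_transcript = TRUE,
                       n_ncrna = 5L,
                       ncrna_length_range = c(100L, 300L),
                       read_format = c("fastq", "fasta")) {
  signal_dist <- match.arg(signal_dist)
  read_format <- match.arg(read_format)
  stopifnot(
    length(seed) == 1, is.finite(seed),
    n_transcripts >= 0,
    length(transcript_length_range) == 2,
    n_mirna_families >= 0,
    sites_per_mirna >= 0,
    signal_mean >= 0, background_rate >= 0,
    contaminant_fraction >= 0, contaminant_fraction < 1,
    corruption_fraction >= 0, corruption_fraction <= 1,
    nchar(adapter) > 0,
    site_edit_max >= 0, site_edit_max <= 3,
    length(star_edit_range) == 2, star_edit_range[1] >= 0,
    star_edit_range[2] <= 3, star_edit_range[1] <= star_edit_range[2],
    dual_strand_families <= n_mirna_families,
    self_cleavage_mean >= 0
  )
  if (transcript_length_range[1] > transcript_length_range[2]) {
    stop("degenerate transcript_length_range: min > max")
  }
  if (ncrna_length_range[1] > ncrna_length_range[2]) {
    stop("degenerate ncrna_length_range: min > max")
  }
  if (mirna_length < 18 || mirna_length > 24) {
    stop("mirna_length must lie in [18, 24]")
  }
  if (!setequal(names(tag_length_weights), as.character(18:24))) {
    stop("tag_length_weights must be named over lengths 18..24")
  }
  if (any(tag_length_weights < 0) || sum(tag_length_weights) <= 0) {
    stop("tag_length_weights must be non-negative and sum > 0")
  }
  structure(list(
    seed = as.integer(seed),
    n_transcripts = as.integer(n_transcripts),
    transcript_length_range = as.integer(transcript_length_range),
    n_mirna_families = as.integer(n_mirna_families),
    mirna_length = as.integer(mirna_length),
    sites_per_mirna = as.integer(sites_per_mirna),
    signal_mean = signal_mean,
    signal_dist = signal_dist,
    nb_dispersion = nb_dispersion,
    background_rate = background_rate,
    contaminant_fraction = contaminant_fraction,
    corruption_fraction = corruption_fraction,
    adapter = normalize_seq(adapter),
    tag_length_weights = tag_length_weights[as.character(18:24)],
    site_edit_max = as.integer(site_edit_max),
    star_edit_range = as.integer(star_edit_range),
    dual_strand_families = as.integer(dual_strand_families),
    self_cleavage_mean = self_cleavage_mean,
    self_cleavage_families = if (is.null(self_cleavage_families)) NULL else
      as.integer(self_cleavage_families),
    one_site_per_transcript = isTRUE(one_site_per_transcript),
    n_ncrna = as.integer(n_ncrna),
    ncrna_length_range = as.integer(ncrna_length_range),
    read_format = read_format
  ), class = "sim_config")
}

# Stage-specific seeds keep independently-run stages reproducible without
# sharing one RNG stream position.
#' @noRd
stage_seed <- function(config, offset) {
  set.seed((config$seed + offset) %% .Machine$integer.max)
}

#' Generate a synthetic transcript set
#'
#' Random-composition transcripts with unique identifiers and lengths drawn
#' uniformly from the configured range.
#'
#' @param config A [sim_config()].
#' @return Named character vector of transcript sequences (`tx0001`, ...).
#' @export
generate_transcriptome <- function(config) {
  stage_seed(config, 1L)
  n <- config$n_transcripts
  if (n == 0) return(stats::setNames(character(0), character(0)))
  lens <- sample(seq(config$transcript_length_range[1],
                     config$transcript_length_range[2]), n, replace = TRUE)
  seqs <- vapply(lens, random_dna, character(1))
  names(seqs) <- sprintf("tx%04d", seq_len(n))
  seqs
}

#' Generate a synthetic ncRNA contaminant set
#'
#' Stand-in for an rRNA/tRNA/snRNA/snoRNA collection used for contaminant
#' depletion.
#'
#' @param config A [sim_config()].
#' @return Named character vector (`ncrna01`, ...).
#' @export
generate_ncrna <- function(config) {
  stage_seed(config, 3L)
  n <- config$n_ncrna
  if (n == 0) return(stats::setNames(character(0), character(0)))
  lens <- sample(seq(config$ncrna_length_range[1],
                     config$ncrna_length_range[2]), n, replace = TRUE)
  seqs <- vapply(lens, random_dna, character(1))
  names(seqs) <- sprintf("ncrna%02d", seq_len(n))
  seqs
}

# Apply one edit (mismatch or G:U wobble, chosen at a given miRNA position)
# to the paired strand of a perfectly complementary window. `window` is the
# target-side sequence 5'->3'; miRNA position i faces window index L - i + 1.
# Wobble is only possible opposite a miRNA G or U; type = "auto" prefers
# wobble where possible.
#' @noRd
apply_edit <- function(window_chars, mirna_chars, mirna_pos,
                       type = c("auto", "gu", "mismatch")) {
  type <- match.arg(type)
  L <- length(mirna_chars)
  j <- L - mirna_pos + 1L
  m <- mirna_chars[mirna_pos]
  wobble_possible <- m %in% c("G", "T")
  if (type == "auto") type <- if (wobble_possible) "gu" else "mismatch"
  if (type == "gu") {
    if (!wobble_possible) stop("G:U edit impossible opposite miRNA base ", m)
    window_chars[j] <- if (m == "G") "T" else "G"
  } else {
    forbidden <- c(DNA_COMPLEMENT[[m]],
                   if (m == "G") "T" else if (m == "T") "G" else NULL)
    window_chars[j] <- sample(setdiff(DNA_BASES, forbidden), 1)
  }
  window_chars
}

#' Generate miRNA/miRNA* hairpins and the mature catalog
#'
#' Each family gets one pre-miRNA hairpin assembled as 5' flank, first arm,
#' loop (8-20 nt), second arm and 3' flank, where one arm carries the mature
#' miRNA and the other the miRNA* (reverse complement of the miR arm with
#' 1-3 planted mismatch/G:U positions, at most two of them inside the 2-13
#' core, so the guide-versus-own-precursor score stays within the default
#' discovery cutoff). Arm suffixes -5p/-3p follow arm placement; 1-based
#' inclusive arm coordinates are recorded.
#'
#' @param config A [sim_config()].
#' @return List with `mature` (data.frame: id, family, arm, role mir/star,
#'   sequence, precursor_id, start, end), `hairpins` (named character
#'   vector), and `star_edits` (list of per-family planted edit positions).
#' @export
generate_hairpins <- function(config) {
  stage_seed(config, 2L)
  L <- config$mirna_length
  nfam <- config$n_mirna_families
  mature <- list(); hairpins <- character(0); star_edits <- list()
  for (i in seq_len(nfam)) {
    fam <- sprintf("fam%02d", i)
    pre_id <- paste0("pre-", fam)
    mir <- random_dna(L)
    mir_chars <- seq_chars(mir)
    # star arm: reverse complement of the miR arm with planted
    # imperfections. Edits are constrained so that both guided directions
    # (miR scanned against the star window and star scanned against the miR
    # window) stay at or below the default 4.5 discovery cutoff, with at
    # most two edits inside the 2-13 core of either direction; mid-hairpin
    # self-targets are then discoverable by construction.
    n_edits <- sample(seq(config$star_edit_range[1],
                          config$star_edit_range[2]), 1)
    edits <- integer(0)
    star <- revcomp(mir)
    if (n_edits > 0) {
      for (try in 1:100) {
        cand <- sort(sample(seq_len(L), n_edits))
        flipped <- L - cand + 1L              # core positions seen by the star
        if (sum(cand >= CORE_START & cand <= CORE_END) > 2) next
        if (sum(flipped >= CORE_START & flipped <= CORE_END) > 2) next
        star_chars <- seq_chars(revcomp(mir))
        for (p in cand) star_chars <- apply_edit(star_chars, mir_chars, p)
        cand_star <- paste(star_chars, collapse = "")
        s1 <- score_site(mir, cand_star, 1)$score
        s2 <- score_site(cand_star, mir, 1)$score
        if (s1 <= 4.5 && s2 <= 4.5) {
          edits <- cand
          star <- cand_star
          break
        }
        if (try == 100) {              # fall back to a single wobble-ready edit
          edits <- integer(0)
          star <- revcomp(mir)
        }
      }
    }
    flank5 <- random_dna(sample(5:30, 1))
    loop <- random_dna(sample(8:20, 1))
    flank3 <- random_dna(sample(5:30, 1))
    mir_first <- sample(c(TRUE, FALSE), 1)
    arm1 <- if (mir_first) mir else star
    arm2 <- if (mir_first) star else mir
    hp <- paste0(flank5, arm1, loop, arm2, flank3)
    s1 <- nchar(flank5) + 1L
    s2 <- nchar(flank5) + L + nchar(loop) + 1L
    coords <- list(c(s1, s1 + L - 1L), c(s2, s2 + L - 1L))
    mir_coord <- coords[[if (mir_first) 1 else 2]]
    star_coord <- coords[[if (mir_first) 2 else 1]]
    mir_arm <- if (mir_first) "5p" else "3p"
    star_arm <- if (mir_first) "3p" else "5p"
    hairpins[pre_id] <- hp
    mature[[length(mature) + 1L]] <- data.frame(
      id = paste0(fam, "-", c(mir_arm, star_arm)),
      family = fam,
      arm = c(mir_arm, star_arm),
      role = c("mir", "star"),
      sequence = c(mir, star),
      precursor_id = pre_id,
      start = c(mir_coord[1], star_coord[1]),
      end = c(mir_coord[2], star_coord[2]),
      stringsAsFactors = FALSE
    )
    star_edits[[fam]] <- edits
  }
  mature <- if (length(mature)) do.call(rbind, mature) else
    data.frame(id = character(), family = character(), arm = character(),
               role = character(), sequence = character(),
               precursor_id = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  list(mature = mature, hairpins = hairpins, star_edits = star_edits)
}

#' Plant miRNA target sites into transcripts
#'
#' For each guide strand, writes `sites_per_mirna` near-complementary
#' windows into the transcript set. Each site is the reverse complement of
#' the guide with 0 to `site_edit_max` planted mismatch/G:U edits; the
#' planted score is obtained by re-scoring the edited window with
#' [score_site()], so ground truth and scorer agree by construction. Sites
#' keep a 24-nt margin downstream of the canonical cleavage coordinate so
#' full-length degradome tags fit, and never overlap each other.
#'
#' @param transcripts Named character vector of transcripts.
#' @param guides data.frame with columns `id`, `sequence` (a subset of the
#'   mature catalog), one row per guide strand to receive sites.
#' @param config A [sim_config()].
#' @param edits Optional list (one element per planted site, cycled over
#'   guides). Each element is either an integer vector of miRNA positions
#'   to edit (edit type chosen automatically, preferring G:U) or a
#'   data.frame with columns `position` and `type` (`"gu"`, `"mismatch"`,
#'   `"auto"`). NULL draws 0 to `site_edit_max` random edits per site.
#' @return List with `transcripts` (edited) and `truth` (data.frame:
#'   mirna_id, transcript_id, site_start, canonical_cleavage, planted_score,
#'   planted_signal = NA until reads are simulated).
#' @export
plant_target_sites <- function(transcripts, guides, config, edits = NULL) {
  stage_seed(config, 4L)
  L <- config$mirna_length
  margin <- 24L          # room for a full-length tag 5'-anchored at the cut
  occupied <- lapply(transcripts, function(x) integer(0))
  used_tx <- character(0)
  truth <- list()
  site_idx <- 0L
  for (g in seq_len(nrow(guides))) {
    gid <- guides$id[g]
    gseq <- normalize_seq(guides$sequence[g])
    gchars <- seq_chars(gseq)
    for (s in seq_len(config$sites_per_mirna)) {
      site_idx <- site_idx + 1L
      placed <- FALSE
      for (attempt in 1:200) {
        pool <- names(transcripts)
        if (config$one_site_per_transcript) {
          fresh <- setdiff(pool, used_tx)
          if (length(fresh)) pool <- fresh
        }
        tx <- sample(pool, 1)
        n <- nchar(transcripts[[tx]])
        max_start <- n - L + 1L - margin
        if (max_start < 1) next
        start <- sample(max_start, 1)
        span <- start:(start + L - 1L)
        if (length(intersect(span, occupied[[tx]]))) next
        window <- seq_chars(revcomp(gseq))
        site_edits <- if (!is.null(edits)) {
          edits[[(site_idx - 1L) %% length(edits) + 1L]]
        } else if (config$site_edit_max > 0) {
          k <- sample(0:config$site_edit_max, 1)
          if (k > 0) sort(sample(seq_len(L), k)) else integer(0)
        } else integer(0)
        if (is.data.frame(site_edits)) {
          for (r in seq_len(nrow(site_edits))) {
            window <- apply_edit(window, gchars, site_edits$position[r],
                                 site_edits$type[r])
          }
        } else {
          for (p in site_edits) window <- apply_edit(window, gchars, p)
        }
        substr(transcripts[[tx]], start, start + L - 1L) <-
          paste(window, collapse = "")
        occupied[[tx]] <- c(occupied[[tx]], span)
        used_tx <- c(used_tx, tx)
        aln <- score_site(gseq, transcripts[[tx]], start)
        truth[[site_idx]] <- data.frame(
          mirna_id = gid, transcript_id = tx,
          site_start = start,
          canonical_cleavage = aln$canonical_cleavage,
          planted_score = aln$score,
          planted_signal = NA_integer_,
          stringsAsFactors = FALSE
        )
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place site ", site_idx, " for ", gid,
             ": site overlaps transcript boundary or no room left")
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(mirna_id = character(), transcript_id = character(),
               site_start = integer(), canonical_cleavage = integer(),
               planted_score = numeric(), planted_signal = integer(),
               stringsAsFactors = FALSE)
  list(transcripts = transcripts, truth = truth)
}

#' @noRd
draw_signal <- function(n, config) {
  switch(config$signal_dist,
         poisson = stats::rpois(n, config$signal_mean),
         nbinom = stats::rnbinom(n, mu = config$signal_mean,
                                 size = config$nb_dispersion),
         fixed = rep(as.integer(round(config$signal_mean)), n))
}

#' @noRd
draw_tag_lengths <- function(n, config) {
  w <- config$tag_length_weights
  as.integer(sample(18:24, n, replace = TRUE, prob = w / sum(w)))
}

#' Simulate a degradome read library
#'
#' Emits reads from three sources: (i) planted cleavage signal, one read
#' bundle per ground-truth site whose 5' ends sit exactly at the canonical
#' cleavage coordinate; (ii) uniform single-decay background 5' ends at
#' `background_rate` per transcript position; (iii) ncRNA contaminant
#' windows making up `contaminant_fraction` of the library. With
#' `self_cleavage_mean > 0`, hairpins additionally yield reads at the two
#' guided mid-hairpin cleavage coordinates (each arm slicing opposite
#' nucleotide 10 of the other arm's window). Every read gets the 3' adapter
#' appended; a `corruption_fraction` of reads is deliberately spoiled
#' (truncated, given an N, or left adapterless) to exercise the filters.
#'
#' @param transcripts Named character vector (after site planting).
#' @param truth Ground-truth site table from [plant_target_sites()].
#' @param hairpins Named character vector of pre-miRNA hairpins (or NULL).
#' @param mature Mature catalog data.frame from [generate_hairpins()]
#'   (needed only when `self_cleavage_mean > 0`).
#' @param ncrna Named character vector of contaminant sequences (or NULL).
#' @param config A [sim_config()].
#' @return List with `reads` (named character vector, adapters appended),
#'   `truth` (planted_signal filled in), `hairpin_truth` (data.frame of
#'   planted precursor cleavage positions and counts), and `sources`
#'   (per-read origin labels).
#' @export
simulate_reads <- function(transcripts, truth, hairpins = NULL, mature = NULL,
                           ncrna = NULL, config) {
  stage_seed(config, 5L)
  L <- config$mirna_length
  reads <- character(0); sources <- character(0)

  emit_from <- function(seqs, id, pos, n_reads) {
    if (n_reads <= 0) return(character(0))
    lens <- draw_tag_lengths(n_reads, config)
    avail <- nchar(seqs[[id]]) - pos + 1L
    lens <- pmin(lens, avail)
    vapply(lens, function(l) substr(seqs[[id]], pos, pos + l - 1L),
           character(1))
  }

  # planted signal at canonical cleavage coordinates
  if (nrow(truth)) {
    truth$planted_signal <- draw_signal(nrow(truth), config)
    for (i in seq_len(nrow(truth))) {
      r <- emit_from(transcripts, truth$transcript_id[i],
                     truth$canonical_cleavage[i], truth$planted_signal[i])
      reads <- c(reads, r)
      sources <- c(sources, rep("signal", length(r)))
    }
  }

  # uniform background decay 5' ends
  for (tx in names(transcripts)) {
    n <- nchar(transcripts[[tx]])
    n_pos <- n - 17L                   # leave >= 18 nt downstream
    if (n_pos < 1) next
    n_bg <- stats::rpois(1, config$background_rate * n_pos)
    if (n_bg == 0) next
    pos <- sample(n_pos, n_bg, replace = TRUE)
    for (p in pos) {
      r <- emit_from(transcripts, tx, p, 1L)
      reads <- c(reads, r)
      sources <- c(sources, "background")
    }
  }

  # guided self-cleavage of precursors (both arms cut opposite the other
  # arm's nucleotide 10)
  hairpin_truth <- data.frame(precursor_id = character(),
                              guide_id = character(),
                              cleavage_position = integer(),
                              planted_signal = integer(),
                              stringsAsFactors = FALSE)
  if (!is.null(hairpins) && length(hairpins) && config$self_cleavage_mean > 0) {
    stopifnot(!is.null(mature))
    pre_ids <- names(hairpins)
    if (!is.null(config$self_cleavage_families)) {
      fams <- unique(mature$family)[seq_len(min(config$self_cleavage_families,
                                                length(unique(mature$family))))]
      pre_ids <- unique(mature$precursor_id[mature$family %in% fams])
    }
    rows <- list()
    for (pre in pre_ids) {
      arms <- mature[mature$precursor_id == pre, ]
      if (nrow(arms) != 2) next
      for (a in 1:2) {
        guide <- arms[a, ]; paired <- arms[3 - a, ]
        cut <- paired$start + L - 10L   # guide slices the opposite arm window
        n_r <- stats::rpois(1, config$self_cleavage_mean)
        if (n_r > 0) {
          r <- emit_from(hairpins, pre, cut, n_r)
          reads <- c(reads, r)
          sources <- c(sources, rep("precursor", length(r)))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          precursor_id = pre, guide_id = guide$id,
          cleavage_position = as.integer(cut),
          planted_signal = as.integer(n_r), stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) hairpin_truth <- do.call(rbind, rows)
  }

  # ncRNA contaminants as a fixed fraction of the final library
  if (!is.null(ncrna) && length(ncrna) && config$contaminant_fraction > 0 &&
      length(reads) > 0) {
    n_cont <- round(config$contaminant_fraction /
                    (1 - config$contaminant_fraction) * length(reads))
    if (n_cont > 0) {
      ids <- sample(names(ncrna), n_cont, replace = TRUE)
      lens <- draw_tag_lengths(n_cont, config)
      r <- vapply(seq_len(n_cont), function(i) {
        nc <- ncrna[[ids[i]]]
        l <- min(lens[i], nchar(nc))
        p <- sample(nchar(nc) - l + 1L, 1)
        substr(nc, p, p + l - 1L)
      }, character(1))
      reads <- c(reads, r)
      sources <- c(sources, rep("contaminant", n_cont))
    }
  }

  # corruption and adapter
  add_adapter <- rep(TRUE, length(reads))
  if (length(reads) && config$corruption_fraction > 0) {
    corrupt <- stats::runif(length(reads)) < config$corruption_fraction
    types <- sample(c("short", "ambiguous", "no_adapter"),
                    sum(corrupt), replace = TRUE)
    idx <- which(corrupt)
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (types[k] == "short") {
        reads[i] <- substr(reads[i], 1, sample(10:17, 1))
      } else if (types[k] == "ambiguous") {
        p <- sample(nchar(reads[i]), 1)
        substr(reads[i], p, p) <- "N"
      } else {
        add_adapter[i] <- FALSE
      }
    }
  }
  reads <- ifelse(add_adapter, paste0(reads, config$adapter), reads)
  if (length(reads)) names(reads) <- sprintf("read%07d", seq_along(reads))

  list(reads = reads, truth = truth, hairpin_truth = hairpin_truth,
       sources = sources)
}

#' Run the full synthetic degradome simulation
#'
#' Generates transcripts, hairpins (with mature miRNA/miRNA* catalog), the
#' ncRNA contaminant set, plants target sites for every miR guide strand
#' (plus the star strands of the first `dual_strand_families` families), and
#' simulates the read library. Optionally writes all artifacts to disk:
#' `transcripts.fasta`, `mirnas.fasta` (headers `id|arm|family`),
#' `hairpins.fasta`, `ncrna.fasta`, `reads.fastq`/`reads.fasta`,
#' `truth_sites.tsv`, `truth_hairpins.tsv`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed), or NULL to skip
#'   writing.
#' @return List with `config`, `transcripts`, `mature`, `hairpins`,
#'   `star_edits`, `ncrna`, `truth`, `hairpin_truth`, `reads`, `sources`.
#' @export
simulate_degradome <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  transcripts <- generate_transcriptome(config)
  hp <- generate_hairpins(config)
  ncrna <- generate_ncrna(config)
  guides <- hp$mature[hp$mature$role == "mir", , drop = FALSE]
  if (config$dual_strand_families > 0) {
    fams <- unique(hp$mature$family)[seq_len(config$dual_strand_families)]
    stars <- hp$mature[hp$mature$role == "star" &
                         hp$mature$family %in% fams, , drop = FALSE]
    guides <- rbind(guides, stars)
  }
  planted <- plant_target_sites(transcripts, guides, config)
  sim <- simulate_reads(planted$transcripts, planted$truth, hp$hairpins,
                        hp$mature, ncrna, config)
  out <- list(config = config,
              transcripts = planted$transcripts,
              mature = hp$mature,
              hairpins = hp$hairpins,
              star_edits = hp$star_edits,
              ncrna = ncrna,
              truth = sim$truth,
              hairpin_truth = sim$hairpin_truth,
              reads = sim$reads,
              sources = sim$sources)
  if (!is.null(out_dir)) write_simulation(out, out_dir)
  out
}

#' Write simulation artifacts to a directory
#'
#' @param sim Result of [simulate_degradome()].
#' @param out_dir Directory path.
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$transcripts, file.path(out_dir, "transcripts.fasta"))
  mirna_seqs <- sim$mature$sequence
  names(mirna_seqs) <- paste(sim$mature$id, sim$mature$arm,
                             sim$mature$family, sep = "|")
  write_fasta(mirna_seqs, file.path(out_dir, "mirnas.fasta"))
  write_fasta(sim$hairpins, file.path(out_dir, "hairpins.fasta"))
  write_fasta(sim$ncrna, file.path(out_dir, "ncrna.fasta"))
  if (sim$config$read_format == "fastq") {
    write_fastq(sim$reads, file.path(out_dir, "reads.fastq"))
  } else {
    write_fasta(sim$reads, file.path(out_dir, "reads.fasta"))
  }
  write_tsv_stable(sim$truth, file.path(out_dir, "truth_sites.tsv"))
  write_tsv_stable(sim$hairpin_truth, file.path(out_dir, "truth_hairpins.tsv"))
  write_tsv_stable(sim$mature, file.path(out_dir, "mature_catalog.tsv"))
  invisible(out_dir)
}
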