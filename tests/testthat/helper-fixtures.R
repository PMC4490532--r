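# Shared fixtures and independent mini-oracles used across test files.

# A small, fast simulation shared by several tests (built once per run).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 11, n_transcripts = 20, n_mirna_families = 4,
                        transcript_length_range = c(300L, 800L),
                        sites_per_mirna = 2, signal_mean = 12,
                        background_rate = 0.004,
                        contaminant_fraction = 0.05,
                        corruption_fraction = 0)
      cache <<- simulate_degradome(cfg)
    }
    cache
  }
})

# Independent naive pairing/penalty evaluation, written directly from the
# rules (match 0 / G:U 0.5 / mismatch 1, doubled over miRNA positions 2-13,
# miRNA nt i antiparallel to window index L - i + 1). Deliberately
# character-by-character and loop-based, independent of the package's
# vectorized scanner.
naive_site_score <- function(mirna, window) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- strsplit(mirna, "")[[1]]
  w <- strsplit(window, "")[[1]]
  L <- length(m)
  total <- 0
  for (i in seq_len(L)) {
    t <- w[L - i + 1]
    pen <- if (!t %in% names(comp) || !m[i] %in% names(comp)) {
      1
    } else if (t == comp[[m[i]]]) {
      0
    } else if ((m[i] == "G" && t == "T") || (m[i] == "T" && t == "G")) {
      0.5
    } else 1
    if (i >= 2 && i <= 13) pen <- pen * 2
    total <- total + pen
  }
  total
}

# Exhaustive window enumeration of candidate sites on one transcript.
naive_scan <- function(mirna, transcript, max_score) {
  L <- nchar(mirna)
  n <- nchar(transcript)
  starts <- integer(0); scores <- numeric(0)
  if (n >= L) {
    for (s in seq_len(n - L + 1)) {
      sc <- naive_site_score(mirna, substr(transcript, s, s + L - 1))
      if (sc <= max_score + 1e-9) {
        starts <- c(starts, s); scores <- c(scores, sc)
      }
    }
  }
  data.frame(site_start = starts, score = scores)
}

# Literal reading of the five category definitions: single read -> 4;
# unique maximum with >1 read -> 0; tied maximum -> 1; above the median ->
# 2; at or below the median -> 3.
naive_category <- function(max_count, n_max, median_count, count) {
  if (count == 1) return(4L)
  if (count == max_count && n_max == 1) return(0L)
  if (count == max_count && n_max > 1) return(1L)
  if (count > median_count) return(2L)
  3L
}

# Random occupied-position profile for classifier property tests.
random_profile_counts <- function() {
  n_pos <- sample(1:30, 1)
  counts <- 1L + stats::rpois(n_pos, lambda = sample(c(0.2, 1, 3, 10), 1))
  counts
}
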