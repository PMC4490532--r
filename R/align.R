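# Plant-style miRNA target alignment: ungapped antiparallel pairing of a
# miRNA against a transcript window, scored in penalty units.

CORE_START <- 2L
CORE_END <- 13L

#' Penalty for one miRNA:target base pair
#'
#' Implements the widely used plant target-scoring rule set: a Watson-Crick
#' match costs 0, a G:U wobble 0.5 and a mismatch 1.0 penalty unit, and the
#' penalty is doubled when the pair lies in the 5' core of the miRNA
#' (positions 2-13 counted from the miRNA 5' end), the region whose pairing
#' is critical for RISC-mediated slicing.
#'
#' @param state Pairing state, one of `"match"`, `"gu"`, `"mismatch"`.
#' @param mirna_position 1-based position on the miRNA, counted from its
#'   5' end.
#' @return Penalty in score units (numeric scalar).
#' @examples
#' position_penalty("gu", 5)   # 1.0: core positions double the 0.5 wobble
#' position_penalty("mismatch", 15)  # 1.0: outside the core
#' @export
position_penalty <- function(state, mirna_position) {
  state <- match.arg(state, c("match", "gu", "mismatch"))
  if (!is.numeric(mirna_position) || mirna_position < 1) {
    stop("mirna_position must be a positive 1-based miRNA coordinate")
  }
  base <- switch(state, match = 0, gu = 0.5, mismatch = 1)
  if (mirna_position >= CORE_START && mirna_position <= CORE_END) base * 2 else base
}

# Pairing state between a miRNA base and a transcript base (both DNA
# alphabet, read as RNA for wobble purposes): G:U and U:G are wobbles.
#' @noRd
pair_state <- function(mirna_base, transcript_base) {
  if (!transcript_base %in% DNA_BASES || !mirna_base %in% DNA_BASES) {
    return("mismatch")                         # ambiguous base: conservative
  }
  if (transcript_base == DNA_COMPLEMENT[[mirna_base]]) return("match")
  if ((mirna_base == "G" && transcript_base == "T") ||
      (mirna_base == "T" && transcript_base == "G")) return("gu")
  "mismatch"
}

#' Score a candidate miRNA target site
#'
#' Pairs a miRNA antiparallel and ungapped against the transcript window
#' starting at `site_start`: miRNA nucleotide i (5'->3') faces transcript
#' position `site_start + L - i`. Each pair is classified as Watson-Crick
#' match, G:U wobble, or mismatch and penalised with [position_penalty()].
#' The canonical slicing coordinate is the transcript position paired to
#' miRNA nucleotide 10; plant RISC cuts the target between the nucleotides
#' paired to miRNA positions 10 and 11, so a degradome tag 5' end at this
#' coordinate is the signature of miRNA-guided cleavage.
#'
#' @param mirna miRNA sequence (character, 5'->3'; U allowed).
#' @param transcript Transcript sequence (character).
#' @param site_start 1-based transcript coordinate of the first (5'-most)
#'   paired transcript nucleotide.
#' @param mirna_id,transcript_id Optional identifiers carried through.
#' @return A list of class `target_alignment` with fields `mirna_id`,
#'   `transcript_id`, `site_start`, `site_end`, `pairing` (per-miRNA-position
#'   states), `pairing_string` (`|` match, `o` G:U, `.` mismatch, in
#'   transcript 5'->3' order), `score` and `canonical_cleavage`.
#' @export
score_site <- function(mirna, transcript, site_start,
                       mirna_id = NA_character_, transcript_id = NA_character_) {
  mirna <- normalize_seq(mirna)
  transcript <- normalize_seq(transcript)
  L <- nchar(mirna)
  n <- nchar(transcript)
  site_end <- site_start + L - 1L
  if (site_start < 1L || site_end > n) {
    stop("site [", site_start, ", ", site_end, "] outside transcript of length ", n)
  }
  m <- seq_chars(mirna)
  window <- seq_chars(substr(transcript, site_start, site_end))
  # miRNA position i faces window index L - i + 1
  states <- vapply(seq_len(L), function(i) pair_state(m[i], window[L - i + 1L]),
                   character(1))
  score <- sum(vapply(seq_len(L), function(i) position_penalty(states[i], i),
                      numeric(1)))
  structure(list(
    mirna_id = mirna_id,
    transcript_id = transcript_id,
    site_start = as.integer(site_start),
    site_end = as.integer(site_end),
    pairing = states,
    pairing_string = pairing_string(states),
    score = score,
    canonical_cleavage = as.integer(site_start + L - 10L)
  ), class = "target_alignment")
}

# Textual alignment in transcript 5'->3' order (miRNA 3'->5' above it).
#' @noRd
pairing_string <- function(states) {
  glyph <- c(match = "|", gu = "o", mismatch = ".")
  paste(rev(glyph[states]), collapse = "")
}

# Integer encoding and penalty lookup used by the vectorized scanner.
#' @noRd
encode_dna <- function(x) {
  chartr_map <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  chars <- seq_chars(x)
  idx <- chartr_map[chars]
  idx[is.na(idx)] <- 5L                       # ambiguous
  idx
}

# penalty_matrix[m, t]: base penalty for miRNA base m vs transcript base t
#' @noRd
base_penalty_matrix <- function() {
  P <- matrix(1, 5, 5, dimnames = list(c(DNA_BASES, "N"), c(DNA_BASES, "N")))
  for (m in DNA_BASES) P[m, DNA_COMPLEMENT[[m]]] <- 0
  P["G", "T"] <- 0.5
  P["T", "G"] <- 0.5
  P
}

#' Scan transcripts for miRNA complementary sites
#'
#' Enumerates every ungapped window of every transcript, scores it with the
#' plant penalty scheme of [score_site()], and returns all windows at or
#' below `max_score`. The default cutoff of 4.5 penalty units reflects the
#' operating range of published Populus degradome target calls; up to the
#' conventional looser 7.0 is accepted.
#'
#' @param mirna Named character scalar or single miRNA sequence; its name (or
#'   `mirna_id`) identifies the guide in the output.
#' @param transcripts Named character vector or `DNAStringSet`.
#' @param max_score Maximum penalty score retained (>= 0).
#' @param mirna_id Identifier for the miRNA (defaults to the name of `mirna`).
#' @return data.frame with columns `mirna_id`, `transcript_id`, `site_start`,
#'   `site_end`, `score`, `canonical_cleavage`, `pairing` (textual alignment).
#' @export
scan_targets <- function(mirna, transcripts, max_score = 4.5, mirna_id = NULL) {
  stopifnot(max_score >= 0)
  if (is.null(mirna_id)) {
    mirna_id <- if (!is.null(names(mirna))) names(mirna)[1] else NA_character_
  }
  mirna <- normalize_seq(unname(mirna[1]))
  seqs <- dna_strings(transcripts)
  if (is.null(names(seqs))) names(seqs) <- paste0("tx", seq_along(seqs))
  L <- nchar(mirna)
  m_idx <- encode_dna(mirna)
  P <- base_penalty_matrix()
  w <- ifelse(seq_len(L) >= CORE_START & seq_len(L) <= CORE_END, 2, 1)

  out <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    tseq <- seqs[[k]]
    n <- nchar(tseq)
    if (n < L) next
    t_idx <- encode_dna(tseq)
    n_win <- n - L + 1L
    scores <- numeric(n_win)
    # miRNA position i faces transcript position s + L - i for window start s
    for (i in seq_len(L)) {
      scores <- scores + w[i] * P[m_idx[i], t_idx[(L - i + 1L):(n - i + 1L)]]
    }
    keep <- which(scores <= max_score + 1e-9)
    if (!length(keep)) next
    pair_str <- vapply(keep, function(s) {
      score_site(mirna, tseq, s)$pairing_string
    }, character(1))
    out[[k]] <- data.frame(
      mirna_id = mirna_id,
      transcript_id = names(seqs)[k],
      site_start = as.integer(keep),
      site_end = as.integer(keep + L - 1L),
      score = scores[keep],
      canonical_cleavage = as.integer(keep + L - 10L),
      pairing = pair_str,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- empty_alignments()
  rownames(res) <- NULL
  res
}

#' @noRd
empty_alignments <- function() {
  data.frame(mirna_id = character(), transcript_id = character(),
             site_start = integer(), site_end = integer(), score = numeric(),
             canonical_cleavage = integer(), pairing = character(),
             stringsAsFactors = FALSE)
}

#' Scan a whole miRNA catalog against transcripts
#'
#' Convenience wrapper running [scan_targets()] for every catalog entry and
#' row-binding the results.
#'
#' @param mirnas Named character vector or `DNAStringSet` of mature miRNAs.
#' @inheritParams scan_targets
#' @return Combined alignment data.frame (see [scan_targets()]).
#' @export
scan_catalog <- function(mirnas, transcripts, max_score = 4.5) {
  seqs <- dna_strings(mirnas)
  if (is.null(names(seqs))) stop("mirna catalog must be named")
  res <- lapply(names(seqs), function(id) {
    scan_targets(seqs[[id]], transcripts, max_score = max_score, mirna_id = id)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- empty_alignments()
  out
}
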