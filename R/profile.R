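# Exact sense-strand mapping of tags to transcripts and construction of
# per-transcript 5'-end signature profiles.

#' Map tags to transcripts by exact sense-strand matching
#'
#' Every exact occurrence of every tag in every transcript is reported with
#' the 1-based coordinate of the tag 5' end. Multi-mapping tags contribute
#' their full count at every locus by default; `fractional = TRUE` divides
#' each count by the tag's locus multiplicity for sensitivity analysis.
#'
#' @param tags data.frame with columns `sequence`, `count` (from
#'   [collapse_tags()]).
#' @param transcripts Named character vector or `DNAStringSet`.
#' @param fractional Divide counts by locus multiplicity.
#' @return List with `hits` (data.frame: tag, transcript_id, position,
#'   count, sorted by tag, transcript, position), `unannotated_tags` and
#'   `unannotated_reads` (tags/reads matching no transcript).
#' @export
map_tags <- function(tags, transcripts, fractional = FALSE) {
  subject <- as_dna_set(dna_strings(transcripts))
  if (is.null(names(subject))) names(subject) <- paste0("tx", seq_along(subject))
  out <- vector("list", nrow(tags))
  n_loci <- integer(nrow(tags))
  if (nrow(tags)) {
    for (i in seq_len(nrow(tags))) {
      m <- Biostrings::vmatchPattern(tags$sequence[i], subject)
      starts <- IRanges::start(m)
      k <- sum(lengths(starts))
      n_loci[i] <- k
      if (k == 0) next
      hit_tx <- rep(names(subject), lengths(starts))
      out[[i]] <- data.frame(
        tag = tags$sequence[i],
        transcript_id = hit_tx,
        position = unlist(starts, use.names = FALSE),
        count = if (fractional) tags$count[i] / k else tags$count[i],
        stringsAsFactors = FALSE
      )
    }
  }
  hits <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(hits)) {
    hits <- data.frame(tag = character(), transcript_id = character(),
                       position = integer(), count = numeric(),
                       stringsAsFactors = FALSE)
  }
  hits <- hits[order(hits$tag, hits$transcript_id, hits$position), ,
               drop = FALSE]
  rownames(hits) <- NULL
  unmatched <- n_loci == 0
  list(hits = hits,
       unannotated_tags = sum(unmatched),
       unannotated_reads = if (nrow(tags)) sum(tags$count[unmatched]) else 0L)
}

#' Build per-transcript degradome signature profiles
#'
#' Sums tag counts by transcript and 5'-end position. Transcripts without
#' hits are absent from the output.
#'
#' @param hits Hit data.frame from [map_tags()].
#' @return data.frame of class `degradome_profiles` with columns
#'   `transcript_id`, `position`, `count`, sorted for reproducible diffs.
#' @export
build_profiles <- function(hits) {
  if (nrow(hits) == 0) {
    out <- data.frame(transcript_id = character(), position = integer(),
                      count = numeric(), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(count ~ transcript_id + position, data = hits,
                            FUN = sum)
    out <- agg[order(agg$transcript_id, agg$position), , drop = FALSE]
    out <- out[, c("transcript_id", "position", "count")]
  }
  rownames(out) <- NULL
  class(out) <- c("degradome_profiles", "data.frame")
  out
}

#' Extract one transcript's signature
#'
#' @param profiles Profiles from [build_profiles()].
#' @param transcript_id Transcript identifier.
#' @return data.frame with columns `position`, `count` (possibly 0 rows).
#' @export
profile_for <- function(profiles, transcript_id) {
  p <- profiles[profiles$transcript_id == transcript_id,
                c("position", "count"), drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Summary statistics of a signature profile
#'
#' The maximum signature count, the number of positions attaining it, and
#' the median count over occupied positions (positions with zero signal are
#' excluded; an even number of occupied positions yields the mean of the
#' central pair). These are the reference quantities for category 0-4
#' classification.
#'
#' @param profile data.frame with a `count` column (one transcript's
#'   occupied positions) or a numeric vector of counts.
#' @return List with `max_count`, `n_max_positions`, `median_count`.
#' @export
profile_stats <- function(profile) {
  counts <- if (is.data.frame(profile)) profile$count else as.numeric(profile)
  if (length(counts) == 0) {
    stop("empty profile: transcript has no degradome evidence")
  }
  mx <- max(counts)
  list(max_count = mx,
       n_max_positions = sum(counts == mx),
       median_count = stats::median(counts))
}
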