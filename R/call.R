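# Cleavage calling: intersect candidate target alignments with degradome
# signature profiles and classify supported sites into CleaveLand-style
# confidence categories 0-4.

#' Classify a cleavage site into category 0-4
#'
#' Confidence classes of a degradome-supported site, judged by its
#' signature count relative to the transcript's signature maximum and
#' median:
#' \itemize{
#'   \item 4: exactly one raw read at the position (lowest confidence; this
#'     test precedes the maximum test, so a lone read that also happens to
#'     be the transcript maximum is still category 4);
#'   \item 0: the count is the unique transcript maximum, with more than one
#'     raw read (highest confidence);
#'   \item 1: the count equals a maximum attained at more than one position;
#'   \item 2: below the maximum but above the median;
#'   \item 3: equal to or below the median.
#' }
#'
#' @param stats Profile statistics from [profile_stats()].
#' @param count_at_site Signature count at the candidate position (>= 1).
#' @return Integer category in 0:4.
#' @export
classify_site <- function(stats, count_at_site) {
  if (count_at_site < 1) stop("no degradome evidence at site (count < 1)")
  if (count_at_site == 1) return(4L)
  if (count_at_site == stats$max_count) {
    return(if (stats$n_max_positions == 1) 0L else 1L)
  }
  if (count_at_site > stats$median_count) return(2L)
  3L
}

#' Call degradome-supported cleavage sites
#'
#' For each candidate alignment, every occupied profile position within
#' `window` nucleotides of the canonical cleavage coordinate (the
#' transcript position paired to miRNA nucleotide 10) becomes one
#' independently classified call. Alignments without signature in the
#' window yield nothing. The same transcript position can be called for
#' several miRNAs, and one alignment can yield several calls at adjacent
#' registers; each call records its `offset` from the canonical coordinate.
#'
#' @param alignments Alignment data.frame from [scan_targets()] /
#'   [scan_catalog()].
#' @param profiles Profiles from [build_profiles()].
#' @param window Half-width of the accepted register around the canonical
#'   cleavage coordinate (default 1; 3 is the extended register).
#' @return data.frame with columns `mirna_id`, `transcript_id`,
#'   `cleavage_position`, `category`, `raw_tags`, `score`, `offset`,
#'   `site_start`, `canonical_cleavage`.
#' @export
call_cleavages <- function(alignments, profiles, window = 1L) {
  stopifnot(window >= 0)
  out <- list()
  if (nrow(alignments)) {
    stats_cache <- list()
    for (i in seq_len(nrow(alignments))) {
      tx <- alignments$transcript_id[i]
      prof <- profile_for(profiles, tx)
      if (nrow(prof) == 0) next
      canon <- alignments$canonical_cleavage[i]
      sel <- which(abs(prof$position - canon) <= window)
      if (!length(sel)) next
      if (is.null(stats_cache[[tx]])) stats_cache[[tx]] <- profile_stats(prof)
      st <- stats_cache[[tx]]
      out[[length(out) + 1L]] <- data.frame(
        mirna_id = alignments$mirna_id[i],
        transcript_id = tx,
        cleavage_position = prof$position[sel],
        category = vapply(prof$count[sel], function(cnt) {
          classify_site(st, cnt)
        }, integer(1)),
        raw_tags = prof$count[sel],
        score = alignments$score[i],
        offset = prof$position[sel] - canon,
        site_start = alignments$site_start[i],
        canonical_cleavage = canon,
        stringsAsFactors = FALSE
      )
    }
  }
  calls <- do.call(rbind, out)
  if (is.null(calls)) {
    calls <- data.frame(mirna_id = character(), transcript_id = character(),
                        cleavage_position = integer(), category = integer(),
                        raw_tags = numeric(), score = numeric(),
                        offset = integer(), site_start = integer(),
                        canonical_cleavage = integer(),
                        stringsAsFactors = FALSE)
  }
  calls <- calls[order(calls$mirna_id, calls$transcript_id,
                       calls$cleavage_position), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Target-plot (t-plot) table for one transcript
#'
#' The t-plot shows degradome signature abundance versus transcript
#' position, with miRNA-consistent call sites flagged (rendered as
#' highlighted dots when plotted).
#'
#' @param profile One transcript's profile (data.frame `position`, `count`,
#'   e.g. from [profile_for()]).
#' @param calls Call data.frame restricted or not to this transcript;
#'   positions present in `calls` are flagged.
#' @param transcript_id Transcript identifier (used to subset `calls` and
#'   label the plot).
#' @param file Optional output image path (`.png` or `.svg`); NULL skips
#'   plotting.
#' @return data.frame with columns `position`, `count`, `is_call_site`.
#' @export
tplot <- function(profile, calls, transcript_id = NULL, file = NULL) {
  if (nrow(profile) == 0) stop("empty profile: nothing to plot")
  call_pos <- if (!is.null(transcript_id)) {
    calls$cleavage_position[calls$transcript_id == transcript_id]
  } else {
    calls$cleavage_position
  }
  tab <- data.frame(position = profile$position,
                    count = profile$count,
                    is_call_site = profile$position %in% call_pos)
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) {
      grDevices::svg(file, width = 7, height = 4)
    } else {
      grDevices::png(file, width = 900, height = 500)
    }
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot(tab$position, tab$count, type = "h", col = "grey40",
                   xlab = "Transcript position (nt)",
                   ylab = "Degradome signature (reads)",
                   main = if (is.null(transcript_id)) "" else transcript_id)
    graphics::points(tab$position[tab$is_call_site],
                     tab$count[tab$is_call_site],
                     col = "red", pch = 19)
  }
  tab
}
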