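# Tag preprocessing: adapter trimming, quality filtering, ncRNA depletion
# and collapsing of raw degradome reads into unique tags with counts.
# PARE tags are 5'-defined (the 5' end is the cleavage signature), so
# trimming never alters the 5' end; only the 3' adapter is removed.

#' Trim the 3' adapter from degradome reads
#'
#' The tag is the read prefix preceding the leftmost occurrence of the full
#' adapter; if the full adapter is absent, a terminal partial adapter (a
#' prefix of the adapter of at least `min_overlap` nt at the read 3' end) is
#' trimmed instead. Reads with neither are rejected as adapterless.
#'
#' @param reads Character vector of raw reads.
#' @param adapter 3' adapter sequence (non-empty).
#' @param min_overlap Minimum adapter prefix length accepted at the read
#'   3' end.
#' @return List with `tags` (character; `NA` where rejected) and
#'   `rejected` (logical vector).
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5L) {
  adapter <- normalize_seq(adapter)
  if (nchar(adapter) == 0) stop("adapter must be non-empty")
  reads <- normalize_seq(reads)
  n <- nchar(reads)
  tags <- rep(NA_character_, length(reads))
  # leftmost full-adapter occurrence
  pos <- regexpr(adapter, reads, fixed = TRUE)
  hit <- pos > 0
  tags[hit] <- substr(reads[hit], 1, pos[hit] - 1L)
  # terminal partial adapter: longest adapter prefix >= min_overlap at 3' end
  todo <- which(!hit)
  if (length(todo)) {
    max_k <- min(nchar(adapter) - 1L, max(n[todo]))
    for (k in seq(max_k, min_overlap)) {
      if (k < min_overlap || !length(todo)) break
      i <- todo[n[todo] >= k]
      if (!length(i)) next
      m <- substr(reads[i], n[i] - k + 1L, n[i]) == substr(adapter, 1, k)
      found <- i[m]
      tags[found] <- substr(reads[found], 1, n[found] - k)
      todo <- setdiff(todo, found)
    }
  }
  list(tags = tags, rejected = is.na(tags))
}

#' Length/ambiguity filtering of trimmed tags
#'
#' Discards tags shorter than `min_len`, tags containing an ambiguous base,
#' and (unless `truncate_long`) tags longer than `max_len`. The retained
#' 18-24 nt range reflects the length band of filtered degradome tags.
#'
#' @param tags Character vector of trimmed tags.
#' @param min_len Minimum tag length (default 18).
#' @param max_len Maximum tag length (default 24).
#' @param truncate_long If TRUE, over-long tags are truncated to `max_len`
#'   instead of rejected (the 5' end is preserved either way).
#' @param homopolymer_frac Optional: reject tags in which one base makes up
#'   at least this fraction (e.g. 0.8); NULL disables the filter.
#' @return List with `kept` (character), `keep` (logical index into `tags`)
#'   and `tallies` (named integer vector: too_short, ambiguous, too_long,
#'   homopolymer).
#' @export
filter_tags <- function(tags, min_len = 18L, max_len = 24L,
                        truncate_long = FALSE, homopolymer_frac = NULL) {
  tags <- normalize_seq(tags)
  n <- nchar(tags)
  reason <- rep(NA_character_, length(tags))
  reason[n < min_len] <- "too_short"
  ambiguous <- is.na(reason) & grepl("[^ACGT]", tags)
  reason[ambiguous] <- "ambiguous"
  long <- is.na(reason) & n > max_len
  if (truncate_long) {
    tags[long] <- substr(tags[long], 1, max_len)
  } else {
    reason[long] <- "too_long"
  }
  if (!is.null(homopolymer_frac)) {
    check <- which(is.na(reason))
    if (length(check)) {
      hp <- vapply(tags[check], function(s) {
        tab <- table(seq_chars(s))
        max(tab) / nchar(s) >= homopolymer_frac
      }, logical(1))
      reason[check[hp]] <- "homopolymer"
    }
  }
  keep <- is.na(reason)
  tallies <- c(too_short = sum(reason == "too_short", na.rm = TRUE),
               ambiguous = sum(reason == "ambiguous", na.rm = TRUE),
               too_long = sum(reason == "too_long", na.rm = TRUE),
               homopolymer = sum(reason == "homopolymer", na.rm = TRUE))
  list(kept = tags[keep], keep = keep, tallies = tallies)
}

#' Remove tags matching the ncRNA contaminant set
#'
#' A tag is removed iff it occurs as an exact substring of any ncRNA
#' sequence (rRNA/tRNA/snRNA/snoRNA stand-in for database annotation).
#'
#' @param tags Character vector of tags (reads, possibly with duplicates).
#' @param ncrna_set Named character vector of ncRNA sequences; empty or NULL
#'   is the identity transform.
#' @return List with `kept` (character), `keep` (logical), `removed` (count
#'   of removed reads).
#' @export
remove_ncrna <- function(tags, ncrna_set = NULL) {
  if (is.null(ncrna_set) || length(ncrna_set) == 0 || length(tags) == 0) {
    return(list(kept = tags, keep = rep(TRUE, length(tags)), removed = 0L))
  }
  ncrna_set <- normalize_seq(unname(ncrna_set))
  uniq <- unique(tags)
  is_nc <- vapply(uniq, function(t) {
    any(vapply(ncrna_set, function(nc) {
      grepl(t, nc, fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  keep <- !tags %in% uniq[is_nc]
  list(kept = tags[keep], keep = keep, removed = sum(!keep))
}

#' Collapse reads into unique tags with counts
#'
#' @param reads Character vector of clean (trimmed, filtered) tag sequences.
#' @return data.frame with columns `sequence`, `count`, sorted by sequence
#'   for reproducible output.
#' @export
collapse_tags <- function(reads) {
  if (length(reads) == 0) {
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(reads)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(out$sequence), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Preprocess a raw degradome library
#'
#' Full preprocessing chain: 3' adapter trimming, length/ambiguity
#' filtering, ncRNA depletion and tag collapsing, with library accounting.
#'
#' @inheritParams trim_adapter
#' @inheritParams filter_tags
#' @param ncrna_set Optional contaminant set for [remove_ncrna()].
#' @return List with `tags` (collapsed tag data.frame) and `stats`, a
#'   library-statistics list: raw_reads, retained_reads, retained_fraction,
#'   unique_tags, length_histogram (data.frame length/count/fraction),
#'   no_adapter, too_short, ambiguous, too_long, homopolymer,
#'   ncrna_removed. `raw_reads` always equals `retained_reads` plus all
#'   rejection tallies.
#' @export
preprocess_reads <- function(reads, adapter, ncrna_set = NULL,
                             min_overlap = 5L, min_len = 18L, max_len = 24L,
                             truncate_long = FALSE, homopolymer_frac = NULL) {
  raw <- length(reads)
  tr <- trim_adapter(reads, adapter, min_overlap)
  no_adapter <- sum(tr$rejected)
  fl <- filter_tags(tr$tags[!tr$rejected], min_len, max_len,
                    truncate_long, homopolymer_frac)
  nc <- remove_ncrna(fl$kept, ncrna_set)
  tags <- collapse_tags(nc$kept)
  retained <- sum(tags$count)
  hist_tab <- if (retained > 0) table(nchar(nc$kept)) else table(integer(0))
  length_histogram <- data.frame(
    length = as.integer(names(hist_tab)),
    count = as.integer(hist_tab),
    fraction = if (retained > 0) as.numeric(hist_tab) / retained else numeric(0)
  )
  stats <- list(
    raw_reads = raw,
    retained_reads = retained,
    retained_fraction = if (raw > 0) retained / raw else NA_real_,
    unique_tags = nrow(tags),
    length_histogram = length_histogram,
    no_adapter = no_adapter,
    too_short = unname(fl$tallies["too_short"]),
    ambiguous = unname(fl$tallies["ambiguous"]),
    too_long = unname(fl$tallies["too_long"]),
    homopolymer = unname(fl$tallies["homopolymer"]),
    ncrna_removed = nc$removed
  )
  list(tags = tags, stats = stats)
}
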