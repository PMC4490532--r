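# Precursor (pre-miRNA hairpin) analysis: perfectly matched degradome
# products, miRNA/miRNA*-guided self-cleavage of precursors, feedback-loop
# detection, and identification of duplexes whose two strands are both
# functional guides.

#' Locate perfectly matched products inside precursors
#'
#' Reports every exact occurrence (including overlapping ones) of each query
#' sequence in each precursor, with 1-based inclusive span coordinates and
#' the query's degradome support. Queries are typically the union of
#' observed degradome tags and catalog mature miRNAs; a catalog miRNA with
#' no tag support carries count 0.
#'
#' @param queries data.frame with columns `sequence` and `count`, or a
#'   character vector (counts then default to 0).
#' @param precursors Named character vector of hairpin sequences.
#' @return data.frame with columns `precursor_id`, `sequence`, `count`,
#'   `length`, `span_start`, `span_end` (`span_end = span_start + length -
#'   1`).
#' @export
locate_products <- function(queries, precursors) {
  if (is.character(queries)) {
    queries <- data.frame(sequence = normalize_seq(queries), count = 0,
                          stringsAsFactors = FALSE)
  }
  queries <- queries[!duplicated(queries$sequence), , drop = FALSE]
  subject <- as_dna_set(precursors)
  out <- list()
  for (i in seq_len(nrow(queries))) {
    q <- normalize_seq(queries$sequence[i])
    m <- Biostrings::vmatchPattern(q, subject)
    starts <- IRanges::start(m)
    if (sum(lengths(starts)) == 0) next
    pre_ids <- rep(names(subject), lengths(starts))
    st <- unlist(starts, use.names = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      precursor_id = pre_ids,
      sequence = q,
      count = queries$count[i],
      length = nchar(q),
      span_start = st,
      span_end = st + nchar(q) - 1L,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(precursor_id = character(), sequence = character(),
                      count = numeric(), length = integer(),
                      span_start = integer(), span_end = integer(),
                      stringsAsFactors = FALSE)
  }
  res <- res[order(res$precursor_id, res$span_start, res$sequence), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Call miRNA-guided cleavage of precursors
#'
#' Runs the full target pipeline (tag mapping, profile building, catalog
#' scan, cleavage calling) with the precursor hairpins as the transcript
#' set, so mid-hairpin cleavage directed by mature miRNAs or miRNA*s is
#' detected and classified with the same category rules as transcript
#' targets.
#'
#' @param catalog Mature catalog data.frame (columns `id`, `sequence`; extra
#'   columns ignored here).
#' @param precursors Named character vector of hairpins.
#' @param tags Collapsed tag data.frame (`sequence`, `count`).
#' @param max_score Score cutoff for the catalog scan.
#' @param window Register half-width for [call_cleavages()].
#' @return Call data.frame (see [call_cleavages()]); `transcript_id` holds
#'   precursor identifiers.
#' @export
precursor_self_targets <- function(catalog, precursors, tags,
                                   max_score = 4.5, window = 1L) {
  mapped <- map_tags(tags, precursors)
  profiles <- build_profiles(mapped$hits)
  mirnas <- stats::setNames(catalog$sequence, catalog$id)
  alignments <- scan_catalog(mirnas, precursors, max_score = max_score)
  call_cleavages(alignments, profiles, window = window)
}

#' @noRd
arm_suffix_family <- function(id) sub("-(5p|3p)$", "", id)

#' Detect miRNA/miRNA* feedback loops on precursors
#'
#' A feedback loop is emitted when a precursor cleavage call is guided by a
#' mature strand of the precursor's own family: the over-produced precursor
#' is then itself a target of its product, buffering mature-strand
#' abundance. When both arms of one duplex cleave the same precursor, the
#' two loops cross-reference each other via `partner_strand_id`.
#'
#' @param precursor_calls Calls from [precursor_self_targets()].
#' @param catalog Mature catalog data.frame with columns `id`, `family`, and
#'   (optionally) `precursor_id`; families of precursors are taken from the
#'   catalog's `precursor_id` column, or supplied via `precursor_families`.
#' @param precursor_families Optional named character vector mapping
#'   precursor identifiers to family labels, overriding the catalog map.
#' @return data.frame with columns `precursor_id`, `cleaving_strand_id`,
#'   `cleavage_position`, `category`, `partner_strand_id` (NA when the other
#'   arm does not cleave the same precursor).
#' @export
detect_feedback_loops <- function(precursor_calls, catalog,
                                  precursor_families = NULL) {
  if (is.null(precursor_families)) {
    if (!"precursor_id" %in% names(catalog)) {
      stop("need precursor_families or a catalog with precursor_id")
    }
    map <- catalog[!duplicated(catalog$precursor_id),
                   c("precursor_id", "family")]
    precursor_families <- stats::setNames(map$family, map$precursor_id)
  }
  if (!"family" %in% names(catalog)) {
    catalog$family <- arm_suffix_family(catalog$id)
  }
  strand_family <- stats::setNames(catalog$family, catalog$id)
  calls <- precursor_calls
  if (nrow(calls) == 0) return(empty_loops())
  fam_pre <- precursor_families[calls$transcript_id]
  fam_strand <- strand_family[calls$mirna_id]
  own <- !is.na(fam_pre) & !is.na(fam_strand) & fam_pre == fam_strand
  calls <- calls[own, , drop = FALSE]
  if (nrow(calls) == 0) return(empty_loops())
  loops <- unique(data.frame(
    precursor_id = calls$transcript_id,
    cleaving_strand_id = calls$mirna_id,
    cleavage_position = calls$cleavage_position,
    category = calls$category,
    stringsAsFactors = FALSE
  ))
  # partner arm: another strand of the same family cleaving the same hairpin
  loops$partner_strand_id <- NA_character_
  for (i in seq_len(nrow(loops))) {
    others <- unique(loops$cleaving_strand_id[
      loops$precursor_id == loops$precursor_id[i] &
        loops$cleaving_strand_id != loops$cleaving_strand_id[i]])
    if (length(others)) loops$partner_strand_id[i] <- others[1]
  }
  loops <- loops[order(loops$precursor_id, loops$cleaving_strand_id,
                       loops$cleavage_position), , drop = FALSE]
  rownames(loops) <- NULL
  loops
}

#' @noRd
empty_loops <- function() {
  data.frame(precursor_id = character(), cleaving_strand_id = character(),
             cleavage_position = integer(), category = integer(),
             partner_strand_id = character(), stringsAsFactors = FALSE)
}

#' Identify duplexes in which both strands are functional guides
#'
#' Counts cleavage calls per arm (-5p/-3p) of each miRNA duplex, over
#' transcript and precursor targets jointly, and emits the duplexes with at
#' least one call on each arm — the cases in which the miRNA* passenger
#' strand is not merely degraded but acts as a guide in its own right.
#'
#' @param all_calls Call data.frame (transcript and precursor calls
#'   row-bound).
#' @param catalog Mature catalog data.frame with columns `id`, `arm`
#'   (`"5p"`/`"3p"`) and optionally `family` (defaults to the id with its
#'   arm suffix stripped). Strands without arm annotation are skipped with a
#'   warning.
#' @return data.frame with columns `duplex_id`, `fivep_id`, `threep_id`,
#'   `fivep_calls`, `threep_calls` (both counts >= 1).
#' @export
functional_star_pairs <- function(all_calls, catalog) {
  if (!"family" %in% names(catalog)) {
    catalog$family <- arm_suffix_family(catalog$id)
  }
  no_arm <- is.na(catalog$arm) | !catalog$arm %in% c("5p", "3p")
  if (any(no_arm)) {
    warning("skipping ", sum(no_arm), " strand(s) without -5p/-3p annotation")
    catalog <- catalog[!no_arm, , drop = FALSE]
  }
  n_calls <- stats::setNames(rep(0L, nrow(catalog)), catalog$id)
  if (nrow(all_calls)) {
    tab <- table(all_calls$mirna_id)
    common <- intersect(names(tab), names(n_calls))
    n_calls[common] <- as.integer(tab[common])
  }
  out <- list()
  for (fam in unique(catalog$family)) {
    arms <- catalog[catalog$family == fam, , drop = FALSE]
    p5 <- arms$id[arms$arm == "5p"]
    p3 <- arms$id[arms$arm == "3p"]
    if (!length(p5) || !length(p3)) next
    c5 <- sum(n_calls[p5]); c3 <- sum(n_calls[p3])
    if (c5 >= 1 && c3 >= 1) {
      out[[length(out) + 1L]] <- data.frame(
        duplex_id = fam, fivep_id = p5[1], threep_id = p3[1],
        fivep_calls = c5, threep_calls = c3, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(duplex_id = character(), fivep_id = character(),
                      threep_id = character(), fivep_calls = integer(),
                      threep_calls = integer(), stringsAsFactors = FALSE)
  }
  res[order(res$duplex_id), , drop = FALSE] -> res
  rownames(res) <- NULL
  res
}
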