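# Reporting: category censuses with integer percentages, per-miRNA target
# tallies, and the end-to-end pipeline driver.

#' Category census of cleavage calls
#'
#' Tabulates call counts and integer percentages per category (0-4), for
#' the whole call set and, when a class annotation is supplied, per miRNA
#' class stratum (e.g. conserved / non-conserved / novel). Percentages are
#' rounded half-up (100 * count / n_sites), and a combined high-confidence
#' share (categories 0-2) is included.
#'
#' @param calls Call data.frame with columns `mirna_id` and `category`.
#' @param class_map Optional named character vector mapping `mirna_id` to a
#'   class label; calls of unmapped miRNAs form an `"unclassified"` stratum.
#' @return data.frame with one row per stratum (first row `"all"`):
#'   `stratum`, `n_sites`, `n_cat0`..`n_cat4`, `pct_cat0`..`pct_cat4`,
#'   `n_high_conf`, `pct_high_conf`.
#' @export
category_census <- function(calls, class_map = NULL) {
  census_row <- function(label, cats) {
    n <- length(cats)
    counts <- vapply(0:4, function(k) sum(cats == k), integer(1))
    row <- data.frame(stratum = label, n_sites = n, stringsAsFactors = FALSE)
    for (k in 0:4) row[[paste0("n_cat", k)]] <- counts[k + 1]
    for (k in 0:4) {
      row[[paste0("pct_cat", k)]] <-
        if (n > 0) pct_round(counts[k + 1], n) else NA_integer_
    }
    row$n_high_conf <- sum(counts[1:3])
    row$pct_high_conf <- if (n > 0) pct_round(sum(counts[1:3]), n) else
      NA_integer_
    row
  }
  out <- list(census_row("all", calls$category))
  if (!is.null(class_map)) {
    cls <- class_map[calls$mirna_id]
    cls[is.na(cls)] <- "unclassified"
    for (s in sort(unique(cls))) {
      out[[length(out) + 1L]] <- census_row(s, calls$category[cls == s])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Distinct targets per miRNA
#'
#' Counts distinct target identifiers per miRNA (several call sites on one
#' target count once) and summarises the distribution.
#'
#' @param calls Call data.frame.
#' @param class_map Optional named character vector of miRNA class labels.
#' @return List with `tally` (data.frame: mirna_id, class, n_targets,
#'   sorted by decreasing n_targets) and `summary` (list: min, max,
#'   mirnas_ge4 — identifiers with at least four distinct targets).
#' @export
targets_per_mirna <- function(calls, class_map = NULL) {
  if (nrow(calls) == 0) {
    tally <- data.frame(mirna_id = character(), class = character(),
                        n_targets = integer(), stringsAsFactors = FALSE)
    return(list(tally = tally,
                summary = list(min = NA_integer_, max = NA_integer_,
                               mirnas_ge4 = character(0))))
  }
  pairs <- unique(calls[, c("mirna_id", "transcript_id")])
  tab <- table(pairs$mirna_id)
  tally <- data.frame(mirna_id = names(tab),
                      class = if (is.null(class_map)) NA_character_ else
                        unname(class_map[names(tab)]),
                      n_targets = as.integer(tab),
                      stringsAsFactors = FALSE)
  tally <- tally[order(-tally$n_targets, tally$mirna_id), , drop = FALSE]
  rownames(tally) <- NULL
  list(tally = tally,
       summary = list(min = min(tally$n_targets),
                      max = max(tally$n_targets),
                      mirnas_ge4 = tally$mirna_id[tally$n_targets >= 4]))
}
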