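# Internal helpers shared across modules. All sequence space is the DNA
# alphabet; U is normalized to T on input so miRBase-style RNA sequences and
# transcript DNA live in one alphabet.

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' @noRd
normalize_seq <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' @noRd
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' @noRd
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(DNA_COMPLEMENT[seq_chars(s)]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Round-half-up integer percentage (100 * num / den). round() in R rounds
# half to even, which does not reproduce conventional report percentages.
#' @noRd
pct_round <- function(num, den) {
  if (den == 0) return(NA_integer_)
  as.integer(floor(100 * num / den + 0.5 + 1e-9))
}

#' @noRd
write_tsv_stable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' @noRd
as_dna_set <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  Biostrings::DNAStringSet(vapply(x, normalize_seq, character(1)))
}

#' @noRd
dna_strings <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    out
  } else {
    vapply(x, normalize_seq, character(1))
  }
}
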