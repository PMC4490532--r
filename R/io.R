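# FASTA/FASTQ input and output via Biostrings. All sequences are normalized
# to the DNA alphabet (U -> T) on the way in.

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of DNA-normalized sequences; names are
#'   truncated at the first whitespace.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- normalize_seq(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read degradome reads from FASTQ or FASTA
#'
#' Format is taken from the file extension (`.fastq`/`.fq` vs anything
#' else).
#'
#' @param path Reads file path.
#' @return Named character vector of reads.
#' @export
read_reads <- function(path) {
  fastq <- grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)
  x <- Biostrings::readBStringSet(path, format = if (fastq) "fastq" else "fasta")
  out <- normalize_seq(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write reads to FASTQ with uniform quality
#'
#' Degradome filtering in this pipeline is length/ambiguity/adapter based,
#' not base-quality based, so a uniform placeholder quality is emitted.
#'
#' @param reads Named character vector.
#' @param path Output path.
#' @param quality_char Single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  x <- Biostrings::BStringSet(reads)
  quals <- Biostrings::BStringSet(vapply(nchar(reads), function(n) {
    strrep(quality_char, n)
  }, character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Parse a mature miRNA catalog from FASTA headers
#'
#' Headers of the form `id|arm|family` (arm `5p`/`3p`) are split into a
#' catalog data.frame; plain headers fall back to deriving arm and family
#' from a trailing `-5p`/`-3p` suffix on the identifier.
#'
#' @param path FASTA path.
#' @return data.frame with columns `id`, `family`, `arm`, `sequence`.
#' @export
read_mirna_catalog <- function(path) {
  x <- Biostrings::readBStringSet(path)
  headers <- sub("\\s.*$", "", names(x))
  parts <- strsplit(headers, "|", fixed = TRUE)
  id <- vapply(parts, `[`, character(1), 1)
  arm <- vapply(parts, function(p) {
    if (length(p) >= 2) p[2] else if (grepl("-(5p|3p)$", p[1])) {
      sub("^.*-(5p|3p)$", "\\1", p[1])
    } else NA_character_
  }, character(1))
  family <- vapply(parts, function(p) {
    if (length(p) >= 3) p[3] else sub("-(5p|3p)$", "", p[1])
  }, character(1))
  data.frame(id = id, family = family, arm = arm,
             sequence = normalize_seq(as.character(x)),
             stringsAsFactors = FALSE)
}
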