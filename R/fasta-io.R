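# Thin FASTA I/O wrappers around Biostrings, returning plain named
# character vectors (the representation the rest of the package uses).

#' Read a FASTA file into a named character vector
#'
#' @param path Path to a FASTA file (nucleotide or amino acid).
#' @return Named character vector of upper-cased sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    pks_abort(sprintf("cannot read FASTA file: %s", path), "pks_input_error")
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- vapply(strsplit(names(x), "\\s+"), `[[`, character(1), 1L)
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    writeLines(wrap_fixed(seqs[[nm]], width), con)
  }
  invisible(path)
}
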