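#' Read a FASTA file into a named character vector
#'
#' IDs are the first whitespace-delimited token of each header.
#'
#' @param path FASTA path (gzip-transparent).
#' @return named character vector of uppercase sequences.
#' @export
parse_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop(sprintf("empty FASTA file: %s", path))
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path; lines wrapped at 80 columns.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}
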