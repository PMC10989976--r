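# stLFR FASTQ dialect: the barcode is appended to the read name after the
# last "#", with bead positions as numeric symbols ("123_45_678");
# "0_0_0" marks a read whose barcode could not be resolved. Mate suffixes
# "/1" and "/2" follow the barcode.

STLFR_NULL_BARCODE <- "0_0_0"

# Split one vector of FASTQ names into (read_id, barcode).
parse_stlfr_names <- function(nm) {
  nm <- sub("\\s.*$", "", nm)          # drop description after first space
  nm <- sub("/[12]$", "", nm)          # strip mate suffix first
  has_bc <- grepl("#", nm, fixed = TRUE)
  read_id <- ifelse(has_bc, sub("#[^#]*$", "", nm), nm)
  barcode <- ifelse(has_bc, sub("^.*#", "", nm), STLFR_NULL_BARCODE)
  list(read_id = read_id, barcode = barcode, n_unbarcoded = sum(!has_bc))
}

#' Read a pair of stLFR FASTQ files
#'
#' Reads two synchronized FASTQ files (gzip-transparent) whose read names
#' carry the stLFR barcode after the last \code{"#"}. Mates are paired by
#' file order. Read names lacking a \code{"#"} are assigned the null barcode
#' \code{"0_0_0"} and counted in the \code{n_unbarcoded} attribute.
#'
#' @param path_fwd,path_rev paths to the forward and reverse FASTQ files.
#' @return a \code{data.table} with columns \code{read_id}, \code{barcode},
#'   \code{seq_fwd}, \code{seq_rev}, \code{qual_fwd}, \code{qual_rev}, one
#'   row per pair, in file order; attribute \code{n_unbarcoded} counts the
#'   pairs whose name carried no barcode.
#' @export
read_stlfr_fastq <- function(path_fwd, path_rev) {
  fwd <- Biostrings::readDNAStringSet(path_fwd, format = "fastq",
                                      with.qualities = TRUE)
  rev <- Biostrings::readDNAStringSet(path_rev, format = "fastq",
                                      with.qualities = TRUE)
  if (length(fwd) != length(rev)) {
    stop(sprintf("mate count mismatch: %d forward vs %d reverse reads",
                 length(fwd), length(rev)))
  }
  nm <- parse_stlfr_names(names(fwd))
  reads <- data.table::data.table(
    read_id  = nm$read_id,
    barcode  = nm$barcode,
    seq_fwd  = as.character(fwd),
    seq_rev  = as.character(rev),
    qual_fwd = as.character(S4Vectors::mcols(fwd)$qualities),
    qual_rev = as.character(S4Vectors::mcols(rev)$qualities)
  )
  if (anyDuplicated(reads$read_id)) {
    stop("duplicate read ids in FASTQ input")
  }
  data.table::setattr(reads, "n_unbarcoded", nm$n_unbarcoded)
  reads[]
}

#' Write paired reads as stLFR-dialect FASTQ
#'
#' @param reads a read table as returned by [read_stlfr_fastq()] or the
#'   simulator (extra truth columns are ignored).
#' @param path_fwd,path_rev output FASTQ paths (".gz" suffix compresses).
#' @return invisibly, the two paths.
#' @export
write_stlfr_fastq <- function(reads, path_fwd, path_rev) {
  stopifnot(all(c("read_id", "barcode", "seq_fwd", "seq_rev",
                  "qual_fwd", "qual_rev") %in% names(reads)))
  base <- paste0(reads$read_id, "#", reads$barcode)
  write_one <- function(seqs, quals, names, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- names
    compress <- grepl("\\.gz$", path)
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(quals),
      compress = compress
    )
  }
  write_one(reads$seq_fwd, reads$qual_fwd, paste0(base, "/1"), path_fwd)
  write_one(reads$seq_rev, reads$qual_rev, paste0(base, "/2"), path_rev)
  invisible(c(path_fwd, path_rev))
}
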