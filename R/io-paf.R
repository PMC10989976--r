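# PAF: 12 mandatory tab-separated columns, 0-based half-open coordinates,
# plus SAM-style typed tags; the cg:Z tag carries the alignment CIGAR.
# For '-' strand lines the query interval is reported on the original
# (forward) query sequence, as printed by the aligner.

#' Parse a PAF alignment file
#'
#' @param path PAF path.
#' @param require_cigar error if any line lacks a \code{cg:Z} tag. Without a
#'   CIGAR the record is still usable for alignment-fraction computation
#'   (identity from the match/block columns) but not for variant calling.
#' @return a \code{data.table} of alignment records: \code{query_id},
#'   \code{query_len}, \code{query_start}, \code{query_end}, \code{strand},
#'   \code{target_id}, \code{target_len}, \code{target_start},
#'   \code{target_end}, \code{matches}, \code{block_len}, \code{mapq},
#'   \code{cigar} (NA when absent), \code{ani} (percent identity,
#'   100 * matches / block length).
#' @export
parse_paf <- function(path, require_cigar = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    stop(sprintf("malformed PAF line %d: fewer than 12 columns",
                 which(nf < 12L)[1]))
  }
  col <- function(i) vapply(fields, `[[`, "", i)
  cigar <- vapply(fields, function(f) {
    cg <- grep("^cg:Z:", f, value = TRUE)
    if (length(cg)) sub("^cg:Z:", "", cg[1]) else NA_character_
  }, "")
  if (require_cigar && anyNA(cigar)) {
    stop(sprintf("PAF line %d lacks a cg:Z CIGAR tag", which(is.na(cigar))[1]))
  }
  aln <- data.table::data.table(
    query_id     = col(1),
    query_len    = as.integer(col(2)),
    query_start  = as.integer(col(3)),
    query_end    = as.integer(col(4)),
    strand       = col(5),
    target_id    = col(6),
    target_len   = as.integer(col(7)),
    target_start = as.integer(col(8)),
    target_end   = as.integer(col(9)),
    matches      = as.integer(col(10)),
    block_len    = as.integer(col(11)),
    mapq         = as.integer(col(12)),
    cigar        = cigar
  )
  aln[, ani := ifelse(block_len > 0, 100 * matches / block_len, NA_real_)]
  aln[]
}

#' Write alignment records as PAF
#'
#' @param aln alignment table in the layout returned by [parse_paf()] or
#'   [align_contigs()].
#' @param path output path.
#' @export
write_paf <- function(aln, path) {
  aln <- data.table::as.data.table(aln)
  base <- paste(aln$query_id, aln$query_len, aln$query_start, aln$query_end,
                aln$strand, aln$target_id, aln$target_len, aln$target_start,
                aln$target_end, aln$matches, aln$block_len, aln$mapq,
                sep = "\t")
  tag <- ifelse(is.na(aln$cigar), "", paste0("\tcg:Z:", aln$cigar))
  writeLines(paste0(base, tag), path)
  invisible(path)
}

empty_alignments <- function() {
  data.table::data.table(
    query_id = character(0), query_len = integer(0),
    query_start = integer(0), query_end = integer(0),
    strand = character(0), target_id = character(0),
    target_len = integer(0), target_start = integer(0),
    target_end = integer(0), matches = integer(0),
    block_len = integer(0), mapq = integer(0),
    cigar = character(0), ani = numeric(0)
  )
}
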