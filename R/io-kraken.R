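# Kraken2 standard (5-column) per-read output:
#   C/U  <read id>  <taxid>  <read length(s)>  <k-mer LCA map>
# Column 5 is never interpreted here.

#' Parse Kraken2 standard per-read output
#'
#' @param path path to a 5-column tab-separated Kraken2 classification file.
#' @return a \code{data.table} with columns \code{read_id},
#'   \code{classified} (logical) and \code{taxid} (integer; 0 for
#'   unclassified reads). A status of \code{"U"} forces taxid 0 regardless
#'   of column 3.
#' @export
parse_kraken_classifications <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.table::data.table(read_id = character(0),
                                  classified = logical(0),
                                  taxid = integer(0)))
  }
  parts <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(parts) < 4L) {
    bad <- which(lengths(strsplit(lines, "\t", fixed = TRUE)) < 4L)[1]
    stop(sprintf("malformed classification line %d: fewer than 4 fields", bad))
  }
  status <- parts[[1]]
  ok <- status %in% c("C", "U")
  if (!all(ok)) {
    stop(sprintf("malformed classification line %d: status '%s'",
                 which(!ok)[1], status[which(!ok)[1]]))
  }
  taxid <- suppressWarnings(as.integer(parts[[3]]))
  if (anyNA(taxid)) {
    stop(sprintf("malformed classification line %d: non-integer taxid",
                 which(is.na(taxid))[1]))
  }
  classified <- status == "C"
  taxid[!classified] <- 0L
  data.table::data.table(read_id = parts[[2]],
                         classified = classified,
                         taxid = taxid)
}

#' Write classifications in Kraken2 5-column format
#'
#' Emits the same dialect [parse_kraken_classifications()] reads, so the
#' built-in fixture classifier and an external Kraken2 run are
#' interchangeable inputs to the pipeline.
#'
#' @param classifications table with \code{read_id}, \code{classified},
#'   \code{taxid}; an optional \code{read_length} column fills column 4
#'   (otherwise 0).
#' @param path output path.
#' @export
write_kraken_classifications <- function(classifications, path) {
  cl <- data.table::as.data.table(classifications)
  len <- if ("read_length" %in% names(cl)) cl$read_length else 0L
  lines <- paste(ifelse(cl$classified, "C", "U"),
                 cl$read_id,
                 ifelse(cl$classified, cl$taxid, 0L),
                 len,
                 "-",
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
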