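# Contamination removal. Barcode collisions let a refined read set carry
# reads of other species, which assemble into contaminant contigs. Each
# contig is aligned to the species reference; alignments with ANI above
# 90% contribute to the contig's alignment fraction (AF), and only
# contigs with AF above 50% survive. Both thresholds are strict
# inequalities, including the AF = 0.5 boundary.

#' Alignment fraction per contig
#'
#' For every contig, the query intervals of its alignments with
#' \code{ani > ani_min} (strict) are merged and divided by the contig
#' length.
#'
#' @param contigs a \code{contig_set} or named character vector.
#' @param alignments alignment table ([align_contigs()] or [parse_paf()])
#'   of these contigs against the species reference.
#' @param ani_min per-alignment ANI threshold in percent (default 90;
#'   strictly greater qualifies).
#' @param af_min AF threshold used to set the \code{kept} flag (default
#'   0.5; strictly greater keeps).
#' @return \code{data.table(contig_id, length, aligned_bases, af,
#'   ani_best, kept)}, one row per contig (contigs without qualifying
#'   alignments get af 0).
#' @export
compute_alignment_fraction <- function(contigs, alignments, ani_min = 90,
                                       af_min = 0.5) {
  if (inherits(contigs, "contig_set")) contigs <- contigs$contigs
  aln <- data.table::as.data.table(alignments)
  best <- if (nrow(aln)) {
    aln[, list(ani_best = max(ani)), by = "query_id"]
  } else data.table::data.table(query_id = character(0), ani_best = numeric(0))
  qual <- aln[ani > ani_min]
  cov <- if (nrow(qual)) {
    qual[, list(aligned_bases = merged_length(query_start, query_end)),
         by = "query_id"]
  } else data.table::data.table(query_id = character(0),
                                aligned_bases = numeric(0))
  out <- data.table::data.table(contig_id = names(contigs),
                                length = nchar(contigs))
  out <- merge(out, cov, by.x = "contig_id", by.y = "query_id",
               all.x = TRUE, sort = FALSE)
  out <- merge(out, best, by.x = "contig_id", by.y = "query_id",
               all.x = TRUE, sort = FALSE)
  out[is.na(aligned_bases), aligned_bases := 0]
  out[, af := aligned_bases / length]
  out[, kept := af > af_min]
  data.table::setorder(out, contig_id)
  out[]
}

#' Drop contaminant contigs by alignment fraction
#'
#' @param contig_set a \code{contig_set}.
#' @param af_results table from [compute_alignment_fraction()]; must cover
#'   every contig.
#' @param af_min AF threshold (default 0.5, strictly greater retained).
#' @return list with \code{kept} (a cleaned \code{contig_set}) and
#'   \code{report} (the AF table with the final kept flag).
#' @export
filter_contigs <- function(contig_set, af_results, af_min = 0.5) {
  stopifnot(inherits(contig_set, "contig_set"))
  af <- data.table::as.data.table(af_results)
  missing <- setdiff(names(contig_set$contigs), af$contig_id)
  if (length(missing)) {
    stop("no AF result for contig(s): ", paste(missing, collapse = ", "))
  }
  af <- af[contig_id %in% names(contig_set$contigs)]
  af[, kept := af > af_min]
  keep_ids <- af$contig_id[af$kept]
  kept <- new_contig_set(contig_set$species,
                         contig_set$contigs[names(contig_set$contigs) %in% keep_ids],
                         contig_set$provenance)
  list(kept = kept, report = af[])
}

#' Decontaminate a contig set against its species reference
#'
#' Convenience wrapper: [align_contigs()] (or supplied external PAF
#' records), [compute_alignment_fraction()], [filter_contigs()].
#'
#' @param contig_set a \code{contig_set}.
#' @param reference named character vector (the species reference).
#' @param ani_min,af_min thresholds (defaults 90 and 0.5).
#' @param alignments optional precomputed alignment table (e.g. from an
#'   external aligner's PAF); computed with the toy aligner when NULL.
#' @return list with \code{kept}, \code{report}, \code{alignments}.
#' @export
decontaminate <- function(contig_set, reference, ani_min = 90, af_min = 0.5,
                          alignments = NULL) {
  if (is.null(alignments)) {
    alignments <- align_contigs(contig_set, reference)
  }
  af <- compute_alignment_fraction(contig_set, alignments,
                                   ani_min = ani_min, af_min = af_min)
  res <- filter_contigs(contig_set, af, af_min = af_min)
  c(res, list(alignments = alignments))
}
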