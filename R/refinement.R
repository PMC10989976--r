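# Cobarcoded read refinement. Reads confidently classified at species rank
# are the taxonomy reads (TRs) of that species; barcodes attached to TRs
# are candidate barcodes; candidates are ranked by Num_T (TR count)
# descending then Ratio_T (TR fraction of the barcode's reads) descending;
# whole barcodes are collected down the ranking until the data-size cap
# (300x reference coverage by default) is reached. Collecting whole
# barcodes is what recruits the reads from inter-species repeats and from
# unique genome-specific regions that the classifier could not assign to
# the species. Only species above the 10x abundance gate are refined.

#' Refinement configuration
#'
#' @param cap_coverage data-size cap in fold coverage of the reference
#'   (default 300): barcode collection stops once the collected bases reach
#'   this many reference lengths.
#' @param min_abundance abundance gate in fold coverage (default 10):
#'   species at or below it are skipped (strictly greater passes).
#' @param include_unbarcoded include TRs carrying the null barcode
#'   \code{"0_0_0"} directly in the refined set (they carry no cobarcoding
#'   signal and are excluded by default).
#' @param min_num_t,min_ratio_t optional hard floors on a candidate
#'   barcode's Num_T / Ratio_T; both off (0) by default — ranking plus the
#'   cap is the only constraint.
#' @return an object of class \code{refinement_config}.
#' @export
refinement_config <- function(cap_coverage = 300, min_abundance = 10,
                              include_unbarcoded = FALSE,
                              min_num_t = 0L, min_ratio_t = 0) {
  stopifnot(cap_coverage > min_abundance, min_abundance > 0)
  structure(list(cap_coverage = cap_coverage, min_abundance = min_abundance,
                 include_unbarcoded = include_unbarcoded,
                 min_num_t = min_num_t, min_ratio_t = min_ratio_t),
            class = "refinement_config")
}

#' Taxonomy reads (TRs) of a species
#'
#' The reads whose classified taxid equals the species taxid exactly.
#' Assignments to strain-level descendants should be lifted with
#' [lift_to_species()] before this step.
#'
#' @param classifications classification table (\code{read_id},
#'   \code{taxid}).
#' @param species a species-rank taxid.
#' @param tree a [taxonomy_tree()] used to check the rank.
#' @return character vector of TR read ids.
#' @export
extract_taxonomy_reads <- function(classifications, species, tree) {
  species <- as.integer(species)
  if (!identical(tax_rank(tree, species), "species")) {
    stop(sprintf("taxid %d is not a species-rank node", species))
  }
  classifications$read_id[classifications$taxid == species]
}

#' Abundance of a species from its TRs
#'
#' The quotient of the total base count of the species' taxonomy reads
#' (both mates) to the reference length, in fold coverage.
#'
#' @param reads read table (for sequence lengths).
#' @param tr_read_ids TR read ids.
#' @param reference_length reference genome length in bp.
#' @return fold coverage (numeric scalar).
#' @export
estimate_abundance <- function(reads, tr_read_ids, reference_length) {
  stopifnot(reference_length > 0)
  tr <- reads[reads$read_id %in% tr_read_ids]
  sum(nchar(tr$seq_fwd) + nchar(tr$seq_rev)) / reference_length
}

#' Per-barcode cobarcoding statistics for one target species
#'
#' One row per candidate barcode (a barcode attached to at least one TR):
#' \code{num_t} TRs of the target species, \code{total_reads} and
#' \code{total_bases} of the barcode over the whole dataset, and
#' \code{ratio_t = num_t / total_reads}.
#'
#' @param reads read table with \code{read_id}, \code{barcode} and
#'   sequences.
#' @param tr_read_ids TR read ids of the target species.
#' @param include_unbarcoded keep the null barcode \code{"0_0_0"} as a
#'   candidate (default FALSE).
#' @return \code{data.table(barcode, num_t, ratio_t, total_reads,
#'   total_bases)}.
#' @export
compute_barcode_stats <- function(reads, tr_read_ids,
                                  include_unbarcoded = FALSE) {
  dt <- data.table::as.data.table(reads)[, c("read_id", "barcode",
                                             "seq_fwd", "seq_rev")]
  dt[, is_tr := read_id %in% tr_read_ids]
  stats <- dt[, list(num_t = sum(is_tr),
                     total_reads = .N,
                     total_bases = sum(nchar(seq_fwd) + nchar(seq_rev))),
              by = "barcode"]
  stats <- stats[num_t > 0L]
  if (!include_unbarcoded) stats <- stats[barcode != STLFR_NULL_BARCODE]
  stats[, ratio_t := num_t / total_reads]
  data.table::setcolorder(stats, c("barcode", "num_t", "ratio_t",
                                   "total_reads", "total_bases"))
  stats[]
}

#' Rank candidate barcodes
#'
#' Descending by \code{num_t}, then descending by \code{ratio_t}, with a
#' deterministic ascending-barcode tie-break.
#'
#' @param stats a [compute_barcode_stats()] table.
#' @return the same table, reordered.
#' @export
rank_barcodes <- function(stats) {
  stats <- data.table::as.data.table(stats)
  data.table::setorderv(stats, c("num_t", "ratio_t", "barcode"),
                        order = c(-1L, -1L, 1L))
  stats[]
}

#' Collect refined reads down the barcode ranking under the data-size cap
#'
#' Walks the ranked candidate barcodes, adding every read of each barcode
#' (TR and non-TR alike — this is how repeat-region and unique-region reads
#' are recruited). Barcodes are atomic; collection stops after the first
#' barcode whose inclusion brings the cumulative bases to at least
#' \code{cap_coverage} times the reference length (that barcode is
#' included).
#'
#' @param ranked ranked barcode stats from [rank_barcodes()].
#' @param reads full read table.
#' @param reference_length reference length (bp).
#' @param config a [refinement_config()].
#' @return list with \code{read_ids} (character), \code{barcodes}
#'   (collected barcodes in rank order), \code{refined_bases}, and
#'   \code{capped} (logical: did the cap stop collection).
#' @export
collect_refined_reads <- function(ranked, reads, reference_length,
                                  config = refinement_config()) {
  ranked <- data.table::as.data.table(ranked)
  if (config$min_num_t > 0) ranked <- ranked[num_t >= config$min_num_t]
  if (config$min_ratio_t > 0) ranked <- ranked[ratio_t >= config$min_ratio_t]
  cap_bases <- config$cap_coverage * reference_length
  cum <- cumsum(as.numeric(ranked$total_bases))
  crossing <- which(cum >= cap_bases)
  n_take <- if (length(crossing)) crossing[1] else nrow(ranked)
  take <- ranked$barcode[seq_len(n_take)]
  ids <- reads$read_id[reads$barcode %in% take]
  list(read_ids = ids,
       barcodes = take,
       refined_bases = if (n_take) cum[n_take] else 0,
       capped = length(crossing) > 0L)
}

#' Refine read sets for every species in the references
#'
#' Runs the full refinement stage: per species, extract TRs, estimate
#' abundance, gate at \code{min_abundance} (strictly greater passes),
#' compute and rank candidate barcodes, and collect the capped refined
#' read set.
#'
#' @param classifications classification table; sub-species taxids should
#'   already be lifted ([lift_to_species()]).
#' @param reads full read table.
#' @param references named character vector of reference genomes.
#' @param genome_taxids named integer vector: species taxid per reference.
#' @param tree a [taxonomy_tree()].
#' @param config a [refinement_config()].
#' @return named list (by species name) of \code{species_read_set} objects:
#'   \code{species}, \code{taxid}, \code{abundance}, \code{skipped},
#'   \code{tr_read_ids}, \code{barcode_stats}, \code{refined_read_ids},
#'   \code{refined_bases}, \code{capped}.
#' @export
refine_all_species <- function(classifications, reads, references,
                               genome_taxids, tree,
                               config = refinement_config()) {
  stopifnot(all(names(genome_taxids) %in% names(references)))
  missing_ref <- setdiff(names(genome_taxids), names(references))
  if (length(missing_ref)) {
    stop("species absent from references: ", paste(missing_ref, collapse = ", "))
  }
  classifications <- data.table::as.data.table(classifications)
  reads <- data.table::as.data.table(reads)
  out <- list()
  for (name in sort(names(genome_taxids))) {
    taxid <- genome_taxids[[name]]
    ref_len <- nchar(references[[name]])
    trs <- extract_taxonomy_reads(classifications, taxid, tree)
    abundance <- estimate_abundance(reads, trs, ref_len)
    if (abundance <= config$min_abundance) {
      out[[name]] <- structure(list(
        species = name, taxid = taxid, abundance = abundance,
        skipped = TRUE, tr_read_ids = trs,
        barcode_stats = NULL, collected_barcodes = character(0),
        refined_read_ids = character(0),
        refined_bases = 0, capped = FALSE), class = "species_read_set")
      next
    }
    stats <- rank_barcodes(compute_barcode_stats(
      reads, trs, include_unbarcoded = config$include_unbarcoded))
    got <- collect_refined_reads(stats, reads, ref_len, config)
    ids <- got$read_ids
    if (config$include_unbarcoded) {
      null_trs <- intersect(trs,
                            reads$read_id[reads$barcode == STLFR_NULL_BARCODE])
      ids <- union(ids, null_trs)
    }
    out[[name]] <- structure(list(
      species = name, taxid = taxid, abundance = abundance,
      skipped = FALSE, tr_read_ids = trs,
      barcode_stats = stats, collected_barcodes = got$barcodes,
      refined_read_ids = ids,
      refined_bases = got$refined_bases, capped = got$capped),
      class = "species_read_set")
  }
  out
}

#' @export
print.species_read_set <- function(x, ...) {
  cat(sprintf(
    "species_read_set %s (taxid %d): abundance %.1fx, %s, %d TRs, %d refined reads\n",
    x$species, x$taxid, x$abundance,
    if (x$skipped) "skipped" else "refined",
    length(x$tr_read_ids), length(x$refined_read_ids)))
  invisible(x)
}

#' Refinement report table
#'
#' @param read_sets result of [refine_all_species()].
#' @return \code{data.table} with one row per species: abundance, TR count,
#'   candidate/collected barcode counts, refined bases, cap flag, skip flag.
#' @export
refinement_report <- function(read_sets) {
  data.table::rbindlist(lapply(read_sets, function(x) {
    data.table::data.table(
      species = x$species, taxid = x$taxid,
      abundance = x$abundance, skipped = x$skipped,
      n_trs = length(x$tr_read_ids),
      n_candidate_barcodes = if (is.null(x$barcode_stats)) 0L
                             else nrow(x$barcode_stats),
      n_collected_barcodes = length(x$collected_barcodes),
      refined_reads = length(x$refined_read_ids),
      refined_bases = x$refined_bases,
      capped = x$capped)
  }))
}
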