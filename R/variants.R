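# Variant classification from whole-genome alignments. Alignments whose
# reference span is below 10 kb are discarded before calling. Mismatch
# columns become SNVs; 1 bp insertions/deletions are ignored entirely;
# indels of 2-49 bp are small, 50 bp and longer are large. Positions are
# 0-based on the reference internally; the VCF writer emits 1-based
# anchored records.

#' Call variants from alignments with extended CIGARs
#'
#' Walks each qualifying alignment's CIGAR (\code{=}/\code{X}/\code{I}/
#' \code{D} ops; plain \code{M} is rejected because mismatches cannot be
#' located) and emits one record per substitution and per indel of length
#' at least 2. Insertion records use the reference position before which
#' the sequence is inserted (\code{ref = ""}); deletion records carry the
#' deleted reference sequence (\code{alt = ""}).
#'
#' @param alignments alignment table with CIGARs ([align_contigs()] or
#'   [parse_paf()] with \code{require_cigar = TRUE}).
#' @param query_seqs named character vector with the query (contig)
#'   sequences, for allele extraction.
#' @param reference_seqs named character vector of reference sequences.
#' @param min_alignment_len minimum reference span of an alignment
#'   (default 10000; shorter alignments are discarded).
#' @param species,sample labels stamped on every record.
#' @return \code{data.table(species, sample, reference_id, position, ref,
#'   alt, class)} with class in \code{snv}, \code{small_indel},
#'   \code{large_indel}.
#' @export
call_variants <- function(alignments, query_seqs, reference_seqs,
                          min_alignment_len = 10000,
                          species = NA_character_, sample = NA_character_) {
  aln <- data.table::as.data.table(alignments)
  if (nrow(aln) && anyNA(aln$cigar)) {
    stop("variant calling requires CIGARs on every alignment")
  }
  aln <- aln[(target_end - target_start) >= min_alignment_len]
  out <- list()
  for (i in seq_len(nrow(aln))) {
    rec <- aln[i]
    qseq <- query_seqs[[rec$query_id]]
    rseq <- reference_seqs[[rec$target_id]]
    if (is.null(qseq) || is.null(rseq)) {
      stop("missing query or reference sequence for alignment ", i)
    }
    if (rec$strand == "-") {
      qseq <- revcomp(qseq)
      qpos <- rec$query_len - rec$query_end
    } else {
      qpos <- rec$query_start
    }
    runs <- cigar_runs(rec$cigar)
    if (any(runs$op %in% c("M", "S", "H"))) {
      stop("CIGAR must use =/X/I/D ops (got ", paste(
        unique(runs$op[runs$op %in% c("M", "S", "H")]), collapse = ","), ")")
    }
    rpos <- rec$target_start
    for (j in seq_along(runs$op)) {
      op <- runs$op[j]; len <- runs$len[j]
      if (op == "=") {
        qpos <- qpos + len; rpos <- rpos + len
      } else if (op == "X") {
        out[[length(out) + 1L]] <- data.table::data.table(
          reference_id = rec$target_id,
          position = rpos + seq_len(len) - 1L,
          ref = strsplit(substr(rseq, rpos + 1L, rpos + len), "")[[1]],
          alt = strsplit(substr(qseq, qpos + 1L, qpos + len), "")[[1]],
          class = "snv")
        qpos <- qpos + len; rpos <- rpos + len
      } else if (op == "I") {
        if (len >= 2L) {
          out[[length(out) + 1L]] <- data.table::data.table(
            reference_id = rec$target_id, position = rpos,
            ref = "", alt = substr(qseq, qpos + 1L, qpos + len),
            class = if (len < 50L) "small_indel" else "large_indel")
        }
        qpos <- qpos + len
      } else if (op == "D") {
        if (len >= 2L) {
          out[[length(out) + 1L]] <- data.table::data.table(
            reference_id = rec$target_id, position = rpos,
            ref = substr(rseq, rpos + 1L, rpos + len), alt = "",
            class = if (len < 50L) "small_indel" else "large_indel")
        }
        rpos <- rpos + len
      }
    }
  }
  if (length(out) == 0L) {
    return(data.table::data.table(species = character(0),
                                  sample = character(0),
                                  reference_id = character(0),
                                  position = integer(0), ref = character(0),
                                  alt = character(0), class = character(0)))
  }
  v <- data.table::rbindlist(out)
  v[, `:=`(species = species, sample = sample)]
  data.table::setcolorder(v, c("species", "sample", "reference_id",
                               "position", "ref", "alt", "class"))
  data.table::setorder(v, reference_id, position)
  v[]
}

#' Shared variants across samples
#'
#' Variants are keyed by (species, reference id, position, ref, alt): the
#' same position and the same sequence change in the same species. The
#' sharing class of a key is the set of samples containing it.
#'
#' @param variant_sets_by_sample named list of [call_variants()] tables,
#'   one per sample (names are sample ids; at least 2).
#' @return list with \code{variants} (key table with \code{n_samples} and
#'   a comma-separated \code{samples} column) and \code{summary}
#'   (\code{data.table(species, class, n_samples, n_variants)}).
#' @export
shared_variants <- function(variant_sets_by_sample) {
  stopifnot(length(variant_sets_by_sample) >= 2L,
            !is.null(names(variant_sets_by_sample)))
  all_v <- data.table::rbindlist(lapply(
    names(variant_sets_by_sample), function(s) {
      v <- data.table::as.data.table(variant_sets_by_sample[[s]])
      v[, sample := s]
      v
    }))
  keyed <- all_v[, list(
    class = class[1],
    n_samples = data.table::uniqueN(sample),
    samples = paste(sort(unique(sample)), collapse = ",")),
    by = c("species", "reference_id", "position", "ref", "alt")]
  summary <- keyed[, list(n_variants = .N),
                   by = c("species", "class", "n_samples")]
  data.table::setorder(summary, species, class, n_samples)
  list(variants = keyed[], summary = summary[])
}

#' SNV density per 100 kb of aligned reference
#'
#' @param variants a [call_variants()] table.
#' @param aligned_reference_bases total reference bases covered by the
#'   qualifying alignments the variants were called from.
#' @return SNV count per 100 kb aligned reference.
#' @export
snv_density <- function(variants, aligned_reference_bases) {
  stopifnot(aligned_reference_bases > 0)
  sum(variants$class == "snv") * 1e5 / aligned_reference_bases
}

#' Write variants as a minimal 8-column VCF
#'
#' Indels are emitted with the standard anchor base (the reference base
#' before the event) and 1-based positions.
#'
#' @param variants a [call_variants()] table.
#' @param reference_seqs named character vector (for anchor bases).
#' @param path output path.
#' @export
write_variants_vcf <- function(variants, reference_seqs, path) {
  v <- data.table::as.data.table(variants)
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", names(reference_seqs),
                      nchar(reference_seqs)),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    chrom <- v$reference_id[i]
    p <- v$position[i]
    ref <- v$ref[i]; alt <- v$alt[i]
    if (v$class[i] == "snv") {
      pos1 <- p + 1L
    } else {
      anchor <- substr(reference_seqs[[chrom]], p, p)  # base before event
      pos1 <- p
      ref <- paste0(anchor, ref)
      alt <- paste0(anchor, alt)
    }
    rows[i] <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tTYPE=%s",
                       chrom, pos1, ref, alt, v$class[i])
  }
  writeLines(c(header, rows), path)
  invisible(path)
}
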