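# Assembly assessment: reference-based genome fraction and contiguity
# (N50/NG50), truth-label completeness/contamination on simulated data,
# quality tiers, and valid cobarcoded fragment counting.

#' Genome fraction of an assembly against its reference
#'
#' Merged reference coverage by alignments with \code{ani} strictly above
#' \code{identity_min}, as a percentage of the total reference length.
#'
#' @param alignments alignment table of assembly vs reference.
#' @param reference_length total reference length (bp), or a named
#'   character vector of reference sequences.
#' @param identity_min identity threshold in percent (default 95).
#' @return percentage in \[0, 100\].
#' @export
genome_fraction <- function(alignments, reference_length, identity_min = 95) {
  if (is.character(reference_length)) {
    reference_length <- sum(nchar(reference_length))
  }
  stopifnot(reference_length > 0)
  aln <- data.table::as.data.table(alignments)[ani > identity_min]
  if (nrow(aln) == 0L) return(0)
  cov <- aln[, list(bases = merged_length(target_start, target_end)),
             by = "target_id"]
  100 * sum(cov$bases) / reference_length
}

#' N50 and NG50 contiguity statistics
#'
#' N50: the largest contig length L such that contigs of length >= L sum
#' to at least half the assembly size. NG50: the same computed against
#' half the reference length; 0 when the assembly does not reach half the
#' reference.
#'
#' @param contig_lengths positive contig lengths (bp).
#' @param reference_length reference length (bp) for NG50.
#' @return named numeric vector \code{c(n50, ng50)}.
#' @export
nx_ngx <- function(contig_lengths, reference_length) {
  if (length(contig_lengths) == 0L) return(c(n50 = 0, ng50 = 0))
  stopifnot(all(contig_lengths > 0), reference_length > 0)
  len <- sort(as.numeric(contig_lengths), decreasing = TRUE)
  cum <- cumsum(len)
  n50 <- len[which(cum >= sum(len) / 2)[1]]
  hit <- which(cum >= reference_length / 2)
  ng50 <- if (length(hit)) len[hit[1]] else 0
  c(n50 = n50, ng50 = ng50)
}

#' Cluster barcoded read placements into fragments and flag valid ones
#'
#' Per barcode and reference, read-pair positions are sorted and split
#' into clusters wherever the gap between adjacent pairs exceeds
#' \code{gap_max}; a cluster is a valid fragment iff it has strictly more
#' than 5 read pairs and spans strictly more than 10 kb.
#'
#' @param placements table with columns \code{barcode},
#'   \code{reference_id}, \code{pos} (one row per read pair, 0-based
#'   leftmost position).
#' @param gap_max cluster split gap (bp, default 50000).
#' @param min_pairs,min_span validity thresholds (strict; defaults 5 pairs
#'   and 10000 bp).
#' @return \code{data.table(barcode, reference_id, cluster, read_pair_count,
#'   span, valid)}.
#' @export
count_valid_fragments <- function(placements, gap_max = 50000,
                                  min_pairs = 5L, min_span = 10000) {
  pl <- data.table::as.data.table(placements)
  stopifnot(all(c("barcode", "reference_id", "pos") %in% names(pl)))
  if (nrow(pl) == 0L) {
    return(data.table::data.table(barcode = character(0),
                                  reference_id = character(0),
                                  cluster = integer(0),
                                  read_pair_count = integer(0),
                                  span = numeric(0), valid = logical(0)))
  }
  data.table::setorder(pl, barcode, reference_id, pos)
  pl[, cluster := cumsum(c(TRUE, diff(pos) > gap_max)),
     by = c("barcode", "reference_id")]
  out <- pl[, list(read_pair_count = .N, span = max(pos) - min(pos)),
            by = c("barcode", "reference_id", "cluster")]
  out[, valid := read_pair_count > min_pairs & span > min_span]
  out[]
}

#' Truth-label completeness and contamination of a contig set
#'
#' On simulated data each contig is attributed to the sample genome it
#' originates from (exact substring match on either strand, with a
#' canonical k-mer majority vote plus toy alignment as fallback for
#' contigs carrying sequencing errors). Completeness is the percentage of
#' the target sample genome covered by contigs originating from it;
#' contamination is the percentage of contig bases whose genome of origin
#' differs from the target.
#'
#' @param contig_set a \code{contig_set}.
#' @param sample_genomes named character vector of sample (truth) genomes.
#' @param target name of the target genome.
#' @param k k-mer size for the fallback origin vote.
#' @return list: \code{completeness}, \code{contamination} (percent), and
#'   \code{origins} (\code{data.table(contig_id, origin)}).
#' @export
truth_quality <- function(contig_set, sample_genomes, target, k = 31L) {
  stopifnot(inherits(contig_set, "contig_set"),
            target %in% names(sample_genomes))
  contigs <- contig_set$contigs
  tlen <- nchar(sample_genomes[[target]])
  if (length(contigs) == 0L) {
    return(list(completeness = 0, contamination = 0,
                origins = data.table::data.table(contig_id = character(0),
                                                 origin = character(0))))
  }
  gk <- data.table::rbindlist(lapply(names(sample_genomes), function(g) {
    data.table::data.table(
      kmer = unique(canonical_kmers_of_seq(sample_genomes[[g]], k)),
      genome = g)
  }))
  data.table::setkey(gk, kmer)
  origins <- character(length(contigs))
  cov_start <- integer(0); cov_end <- integer(0)
  tgt_seq <- sample_genomes[[target]]
  exact_hits <- function(pattern) {
    m <- gregexpr(pattern, tgt_seq, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  }
  for (i in seq_along(contigs)) {
    cseq <- contigs[[i]]
    votes <- gk[data.table::data.table(
      kmer = canonical_kmers(kmers_of(cseq, k))), on = "kmer",
      nomatch = NULL][, .N, by = "genome"]
    if (nrow(votes) == 0L) { origins[i] <- NA_character_; next }
    data.table::setorder(votes, -N, genome)
    origins[i] <- votes$genome[1]
    if (origins[i] == target) {
      s_f <- exact_hits(cseq)
      s_r <- exact_hits(revcomp(cseq))
      if (length(s_f) + length(s_r) > 0L) {
        s <- c(s_f, s_r)
        e <- s + nchar(cseq)
      } else {
        a <- align_contigs(contigs[i],
                           setNames(sample_genomes[target], target))
        s <- a$target_start; e <- a$target_end
      }
      cov_start <- c(cov_start, s); cov_end <- c(cov_end, e)
    }
  }
  completeness <- 100 * merged_length(cov_start, cov_end) / tlen
  bases <- nchar(contigs)
  foreign <- is.na(origins) | origins != target
  contamination <- if (sum(bases) > 0) 100 * sum(bases[foreign]) / sum(bases)
                   else 0
  list(completeness = min(completeness, 100),
       contamination = contamination,
       origins = data.table::data.table(contig_id = names(contigs),
                                        origin = origins))
}

#' Quality tier of an assembly
#'
#' High quality: completeness > 90 and contamination < 5. Medium quality:
#' completeness > 50 and contamination < 10, not meeting both
#' high-quality bounds. Otherwise low.
#'
#' @param completeness,contamination percentages in \[0, 100\].
#' @return \code{"high"}, \code{"medium"} or \code{"low"}.
#' @export
classify_quality <- function(completeness, contamination) {
  if (completeness < 0 || completeness > 100 ||
      contamination < 0 || contamination > 100) {
    stop("completeness and contamination must be percentages in [0, 100]")
  }
  if (completeness > 90 && contamination < 5) return("high")
  if (completeness > 50 && contamination < 10) return("medium")
  "low"
}
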