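# Fixture k-mer LCA classifier. A stand-in with the classification
# behaviour the pipeline depends on — species-specific k-mers hit the
# species, k-mers shared across species hit their LCA, novel sequence hits
# nothing — so the refinement stage can be exercised without an external
# classifier. It is not a reimplementation of any production classifier
# (no minimizers, no compact hashing).

#' Build a k-mer LCA index over reference genomes
#'
#' Every canonical k-mer of every reference is stored with the LCA (in
#' \code{tree}) of all genomes containing it.
#'
#' @param references named character vector of genome sequences; names are
#'   genome ids.
#' @param genome_taxids integer vector, parallel to \code{references}: the
#'   species taxid of each genome.
#' @param tree a [taxonomy_tree()].
#' @param k odd k-mer size in \[15, 63\] (default 31).
#' @return an object of class \code{kmer_index}: a keyed
#'   \code{data.table(kmer, taxid)} plus \code{k} and the tree.
#' @export
build_kmer_index <- function(references, genome_taxids, tree, k = 31L) {
  k <- as.integer(k)
  stopifnot(k %% 2L == 1L, k >= 15L, k <= 63L, length(references) > 0L,
            length(genome_taxids) == length(references))
  if (anyDuplicated(names(references))) stop("duplicate genome id")
  pieces <- lapply(seq_along(references), function(i) {
    data.table::data.table(
      kmer = unique(canonical_kmers_of_seq(references[[i]], k)),
      taxid = as.integer(genome_taxids[i])
    )
  })
  all_km <- data.table::rbindlist(pieces)
  # k-mers present in several genomes collapse to the LCA of those genomes
  idx <- all_km[, if (data.table::uniqueN(taxid) == 1L) {
    list(taxid = taxid[1])
  } else {
    list(taxid = lca(tree, unique(taxid)))
  }, by = "kmer"]
  data.table::setkey(idx, kmer)
  structure(list(index = idx, k = k, tree = tree), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k=%d, %d canonical k-mers\n", x$k, nrow(x$index)))
  invisible(x)
}

# Hit counts of a batch of reads against the index:
# data.table(row, taxid, n) for rows with >= 1 hit.
kmer_hits <- function(index, seqs) {
  k <- index$k
  km <- lapply(seqs, function(s) {
    if (nchar(s) < k) character(0) else kmers_of(s, k)
  })
  lens <- lengths(km)
  if (sum(lens) == 0L) {
    return(data.table::data.table(row = integer(0), taxid = integer(0),
                                  n = integer(0)))
  }
  q <- data.table::data.table(
    row = rep(seq_along(seqs), lens),
    kmer = canonical_kmers(unlist(km, use.names = FALSE)))
  hits <- index$index[q, on = "kmer", nomatch = NULL]
  hits[, list(n = .N), by = c("row", "taxid")]
}

#' Classify read pairs with the fixture k-mer classifier
#'
#' Both mates of a pair are classified jointly: the hit counts of all their
#' k-mers are pooled, each species (leaf) is scored by the summed hits along
#' its root-to-leaf path, and the read is assigned the unique maximal leaf,
#' or the LCA of the tied maximal leaves when several score equally — so a
#' read wholly inside a block shared by two species lands on their common
#' ancestor, above species rank. Reads with no k-mer hits (e.g. from sample
#' sequence absent from every reference) are unclassified.
#'
#' @param reads read table with \code{read_id}, \code{seq_fwd},
#'   \code{seq_rev}.
#' @param index a [build_kmer_index()] result.
#' @return a classification \code{data.table} (\code{read_id},
#'   \code{classified}, \code{taxid}, \code{read_length}) in input order.
#' @export
classify_reads_fixture <- function(reads, index) {
  tree <- index$tree
  n <- nrow(reads)
  out_taxid <- integer(n)
  if (n > 0L) {
    hits_f <- kmer_hits(index, reads$seq_fwd)
    hits_r <- kmer_hits(index, reads$seq_rev)
    hits <- data.table::rbindlist(list(hits_f, hits_r))
    hits <- hits[, list(n = sum(n)), by = c("row", "taxid")]
    if (nrow(hits)) {
      leaves_below <- species_under(tree)
      # expand each hit node to the leaves beneath it; a leaf's root-to-leaf
      # score is then the sum of expanded hit counts it received
      reps <- lengths(leaves_below[as.character(hits$taxid)])
      expanded <- data.table::data.table(
        row  = rep(hits$row, reps),
        leaf = unlist(leaves_below[as.character(hits$taxid)],
                      use.names = FALSE),
        n    = rep(hits$n, reps)
      )
      scores <- expanded[, list(score = sum(n)), by = c("row", "leaf")]
      assign_one <- function(leaf, score) {
        best <- leaf[score == max(score)]
        if (length(best) == 1L) best else lca(tree, best)
      }
      ass <- scores[, list(taxid = assign_one(leaf, score)), by = "row"]
      out_taxid[ass$row] <- ass$taxid
    }
  }
  data.table::data.table(
    read_id = reads$read_id,
    classified = out_taxid != 0L,
    taxid = out_taxid,
    read_length = nchar(reads$seq_fwd) + nchar(reads$seq_rev)
  )
}
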