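# Per-species assembly. Production use plugs in an external cobarcoding
# assembler through a command template; the built-in toy de Bruijn
# assembler (maximal non-branching unitigs over counted canonical k-mers)
# exists so the pipeline and its tests run with no external binary. It is
# fixture-grade: no scaffolding, no barcode awareness, no error
# correction beyond the k-mer count floor.

new_contig_set <- function(species, contigs, provenance) {
  if (length(contigs) && anyDuplicated(names(contigs))) {
    stop("duplicate contig ids")
  }
  structure(list(species = species,
                 contigs = contigs,
                 provenance = provenance),
            class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("contig_set (%s): %d contigs, %d bp total\n",
              x$provenance, length(x$contigs), sum(nchar(x$contigs))))
  invisible(x)
}

#' Run an external assembler through a command template
#'
#' The template must contain the placeholders \code{{fwd}}, \code{{rev}}
#' and \code{{out}}; \code{{out}} is the FASTA the tool is expected to
#' write. Stdout/stderr are captured to a log file whose path is included
#' in any error.
#'
#' @param path_fwd,path_rev refined paired FASTQ for one species.
#' @param command_template shell command with placeholders.
#' @param workdir working directory for logs and output.
#' @param species species label attached to the result.
#' @return a \code{contig_set} with provenance \code{"external"}.
#' @export
run_external_assembler <- function(path_fwd, path_rev, command_template,
                                   workdir, species = NA_character_) {
  if (!all(vapply(c("{fwd}", "{rev}", "{out}"), grepl, NA,
                  x = command_template, fixed = TRUE))) {
    stop("command template must contain {fwd}, {rev} and {out}")
  }
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  out_fa <- file.path(workdir, "assembly.fasta")
  log <- file.path(workdir, "assembler.log")
  fills <- c(fwd = path_fwd, rev = path_rev, out = out_fa)
  cmd <- command_template
  for (key in names(fills)) {
    cmd <- gsub(sprintf("{%s}", key), fills[[key]], cmd, fixed = TRUE)
  }
  status <- system(paste0("(", cmd, ") > ", shQuote(log), " 2>&1"))
  if (status != 0L) {
    stop(sprintf("external assembler failed (exit %d); log: %s", status, log))
  }
  if (!file.exists(out_fa) || file.size(out_fa) == 0L) {
    stop(sprintf("external assembler produced no FASTA; log: %s", log))
  }
  contigs <- parse_fasta(out_fa)
  new_contig_set(species, contigs, "external")
}

#' Toy de Bruijn assembler
#'
#' Counts canonical k-mers of both mates, drops those below
#' \code{min_kmer_count} (singleton error k-mers at low substitution
#' rates), and emits every maximal non-branching path of length at least
#' \code{2k} bp as a contig. A path and its reverse complement are the
#' same contig; the lexicographically smaller strand is reported.
#' Deterministic given the read multiset.
#'
#' @param reads read table with \code{seq_fwd}, \code{seq_rev} (or a
#'   character vector of sequences).
#' @param k odd k-mer size (default 31).
#' @param min_kmer_count minimum canonical k-mer count (default 2).
#' @param species species label for the contig set.
#' @return a \code{contig_set} with provenance \code{"toy"}; ids
#'   \code{contig_00001}... ordered by decreasing length then sequence.
#' @export
toy_debruijn_assemble <- function(reads, k = 31L, min_kmer_count = 2L,
                                  species = NA_character_) {
  k <- as.integer(k)
  stopifnot(k %% 2L == 1L, k >= 5L)
  seqs <- if (is.character(reads)) reads else c(reads$seq_fwd, reads$seq_rev)
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0L) {
    return(new_contig_set(species, character(0), "toy"))
  }
  km <- unlist(lapply(seqs, kmers_of, k = k), use.names = FALSE)
  km <- canonical_kmers(km)
  counts <- data.table::data.table(kmer = km)[, list(n = .N), by = "kmer"]
  solid_canon <- counts$kmer[counts$n >= min_kmer_count]
  if (length(solid_canon) == 0L) {
    warning("no k-mer passes the count filter; empty assembly")
    return(new_contig_set(species, character(0), "toy"))
  }
  # both orientations as directed nodes (k odd: no palindromic k-mers)
  node <- sort(unique(c(solid_canon, revcomp(solid_canon))))
  n <- length(node)
  nd <- data.table::data.table(id = seq_len(n), node = node,
                               prefix = substring(node, 1L, k - 1L),
                               suffix = substring(node, 2L, k))
  edges <- merge(nd[, list(u = id, ov = suffix)],
                 nd[, list(v = id, ov = prefix)],
                 by = "ov", allow.cartesian = TRUE)[, list(u, v)]
  out_deg <- tabulate(edges$u, nbins = n)
  in_deg <- tabulate(edges$v, nbins = n)
  # linear edges u->v (u's only exit, v's only entrance) form the unitigs
  lin <- edges[out_deg[u] == 1L & in_deg[v] == 1L]
  nxt <- rep(NA_integer_, n)
  nxt[lin$u] <- lin$v
  is_target <- rep(FALSE, n)
  is_target[lin$v] <- TRUE

  emit <- function(ids) {
    seq <- paste0(node[ids[1]],
                  paste(substring(node[ids[-1]], k, k), collapse = ""))
    rc <- revcomp(seq)
    min(seq, rc)
  }
  contigs <- character(0)
  done <- rep(FALSE, n)
  buf <- integer(n)
  for (s in which(!is_target)) {        # chain starts, in node sort order
    len <- 1L
    buf[1L] <- s
    v <- nxt[s]
    while (!is.na(v)) { len <- len + 1L; buf[len] <- v; v <- nxt[v] }
    ids <- buf[seq_len(len)]
    done[ids] <- TRUE
    seq <- emit(ids)
    if (nchar(seq) >= 2L * k) contigs <- c(contigs, seq)
  }
  for (s in which(!done)) {             # pure linear cycles
    if (done[s]) next
    len <- 1L
    buf[1L] <- s
    done[s] <- TRUE
    v <- nxt[s]
    while (!is.na(v) && !done[v]) {
      len <- len + 1L; buf[len] <- v; done[v] <- TRUE; v <- nxt[v]
    }
    seq <- emit(buf[seq_len(len)])
    if (nchar(seq) >= 2L * k) contigs <- c(contigs, seq)
  }
  contigs <- unique(contigs)
  ord <- order(-nchar(contigs), contigs)
  contigs <- contigs[ord]
  if (length(contigs)) names(contigs) <- sprintf("contig_%05d", seq_along(contigs))
  new_contig_set(species, contigs, "toy")
}
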