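# Toy contig-to-reference aligner: exact k-mer seeds (k = 19), a longest
# collinear chain per strand, exact-run merging on shared diagonals, and
# global alignment of the short regions between anchors. Emits PAF-style
# records with extended CIGARs (=/X/I/D), which downstream ANI, alignment
# fraction and variant calling consume. An external long-read aligner's
# PAF (with cg:Z) can be substituted anywhere these records are used.

.aln_cache <- new.env(parent = emptyenv())

aln_submat <- function() {
  # +1/-2 nucleotide score matrix, built once per session
  if (is.null(.aln_cache$submat)) {
    .aln_cache$submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE)
  }
  .aln_cache$submat
}

# ops of a global pairwise alignment of two non-empty strings, as a list
# of (op, len) run vectors with ops in {=, X, I, D}; I consumes query,
# D consumes reference
pairwise_ops <- function(qsub, rsub) {
  nq <- nchar(qsub); nr <- nchar(rsub)
  if (nq == 0L && nr == 0L) return(list(op = character(0), len = integer(0)))
  if (nq == 0L) return(list(op = "D", len = nr))
  if (nr == 0L) return(list(op = "I", len = nq))
  pa <- Biostrings::pairwiseAlignment(
    qsub, rsub, type = "global", substitutionMatrix = aln_submat(),
    gapOpening = 5, gapExtension = 2)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  op <- ifelse(p == "-", "D", ifelse(s == "-", "I",
                                     ifelse(p == s, "=", "X")))
  r <- rle(op)
  list(op = r$values, len = r$lengths)
}

ops_to_cigar <- function(op, len) paste0(paste0(len, op), collapse = "")

cigar_runs <- function(cigar) {
  m <- gregexpr("\\d+[=XIDMSH]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("\\d+[=XIDMSH]", cigar))[[1]]
  list(op = substring(toks, nchar(toks), nchar(toks)),
       len = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}

# longest strictly-increasing chain: anchors must be pre-sorted by
# (q asc, r desc); returns indices of the chain (increasing q and r)
lis_chain <- function(r) {
  n <- length(r)
  tails_val <- numeric(n); tails_idx <- integer(n); tl <- 0L
  parent <- integer(n)
  for (i in seq_len(n)) {
    pos <- if (tl == 0L) 0L else findInterval(r[i] - 0.5, tails_val[seq_len(tl)])
    parent[i] <- if (pos > 0L) tails_idx[pos] else 0L
    tails_val[pos + 1L] <- r[i]
    tails_idx[pos + 1L] <- i
    if (pos == tl) tl <- tl + 1L
  }
  chain <- integer(tl)
  idx <- tails_idx[tl]
  j <- tl
  while (idx > 0L) { chain[j] <- idx; idx <- parent[idx]; j <- j - 1L }
  chain
}

# merge chained anchors into exact runs (qs, qe, rs, re), trimming
# overlaps between runs on different diagonals
anchors_to_runs <- function(q, r, k) {
  diag <- r - q
  new_run <- c(TRUE, diag[-1] != diag[-length(diag)] |
                 (q[-1] - q[-length(q)]) > k)
  grp <- cumsum(new_run)
  qs <- tapply(q, grp, min); qe <- tapply(q, grp, max) + k
  rs <- tapply(r, grp, min); re <- tapply(r, grp, max) + k
  runs <- data.table::data.table(qs = as.integer(qs), qe = as.integer(qe),
                                 rs = as.integer(rs), re = as.integer(re))
  if (nrow(runs) > 1L) {
    keep <- rep(TRUE, nrow(runs))
    last <- 1L
    for (i in 2L:nrow(runs)) {
      shift <- max(runs$qe[last] - runs$qs[i], runs$re[last] - runs$rs[i], 0L)
      if (runs$qs[i] + shift >= runs$qe[i]) { keep[i] <- FALSE; next }
      runs$qs[i] <- runs$qs[i] + shift
      runs$rs[i] <- runs$rs[i] + shift
      last <- i
    }
    runs <- runs[keep]
  }
  runs
}

# one alignment record from a set of runs over (qseq_aln, rseq); returns
# NULL if empty. Coordinates are in alignment (strand) orientation.
runs_to_record <- function(runs, qseq, rseq, extend_ends = TRUE) {
  op <- character(0); len <- integer(0)
  add <- function(o, l) {
    if (l > 0L) { op <<- c(op, o); len <<- c(len, as.integer(l)) }
  }
  qstart <- runs$qs[1]; rstart <- runs$rs[1]
  # head extension: align the query flank against a same-sized (plus
  # slack) reference window ending at the first anchor; kept only when it
  # looks homologous, so novel contig ends stay unaligned
  if (extend_ends && qstart > 0L && rstart > 0L && qstart <= 1000L) {
    wl <- min(rstart, qstart + max(20L, as.integer(0.3 * qstart)))
    qf <- substr(qseq, 1L, qstart)
    rf <- substr(rseq, rstart - wl + 1L, rstart)
    ext <- pairwise_ops(qf, rf)
    nm <- sum(ext$len[ext$op == "="])
    if (nm / max(qstart, wl) >= 0.6) {
      # trim leading reference-only columns; they are outside the alignment
      while (length(ext$op) && ext$op[1] == "D") {
        wl <- wl - ext$len[1]
        ext$op <- ext$op[-1]; ext$len <- ext$len[-1]
      }
      op <- ext$op; len <- as.integer(ext$len)
      qstart <- 0L
      rstart <- rstart - wl
    }
  }
  for (i in seq_len(nrow(runs))) {
    if (i > 1L) {
      qgap <- runs$qs[i] - runs$qe[i - 1L]
      rgap <- runs$rs[i] - runs$re[i - 1L]
      gap <- pairwise_ops(substr(qseq, runs$qe[i - 1L] + 1L, runs$qs[i]),
                          substr(rseq, runs$re[i - 1L] + 1L, runs$rs[i]))
      for (j in seq_along(gap$op)) add(gap$op[j], gap$len[j])
    }
    add("=", runs$qe[i] - runs$qs[i])
  }
  qend <- runs$qe[nrow(runs)]; rend <- runs$re[nrow(runs)]
  qtail <- nchar(qseq) - qend
  if (extend_ends && qtail > 0L && rend < nchar(rseq) && qtail <= 1000L) {
    wl <- min(nchar(rseq) - rend, qtail + max(20L, as.integer(0.3 * qtail)))
    qf <- substr(qseq, qend + 1L, nchar(qseq))
    rf <- substr(rseq, rend + 1L, rend + wl)
    ext <- pairwise_ops(qf, rf)
    nm <- sum(ext$len[ext$op == "="])
    if (nm / max(qtail, wl) >= 0.6) {
      while (length(ext$op) && ext$op[length(ext$op)] == "D") {
        wl <- wl - ext$len[length(ext$op)]
        ext$op <- ext$op[-length(ext$op)]
        ext$len <- ext$len[-length(ext$len)]
      }
      for (j in seq_along(ext$op)) add(ext$op[j], ext$len[j])
      qend <- nchar(qseq)
      rend <- rend + wl
    }
  }
  # merge adjacent identical ops
  if (length(op) > 1L) {
    grp <- cumsum(c(TRUE, op[-1] != op[-length(op)]))
    len <- as.integer(tapply(len, grp, sum))
    op <- op[!duplicated(grp)]
  }
  matches <- sum(len[op == "="])
  block <- sum(len)
  list(q_start = qstart, q_end = qend, r_start = rstart, r_end = rend,
       matches = matches, block_len = block,
       cigar = ops_to_cigar(op, len))
}

#' Align contigs to a reference with the toy anchor-chain aligner
#'
#' For each contig and reference sequence, exact \code{k}-mer anchors are
#' chained per strand (the strand with more anchors wins), merged into
#' exact runs, and the gaps between runs are closed by global pairwise
#' alignment; chains separated by gaps larger than \code{max_gap} become
#' separate alignment records, as do secondary chains on query regions the
#' primary chain left uncovered.
#'
#' @param contigs a \code{contig_set} or named character vector.
#' @param reference named character vector of reference sequences.
#' @param k seed k-mer size (default 19).
#' @param max_gap maximum inter-anchor gap closed within one record (bp).
#' @param min_chain_anchors minimum anchors for a (secondary) chain.
#' @param max_seed_hits reference k-mers occurring more often are not used
#'   as seeds.
#' @return alignment \code{data.table} in the [parse_paf()] layout, with
#'   extended CIGARs and per-alignment \code{ani}. Query coordinates of
#'   reverse-strand records refer to the original contig orientation, as
#'   in PAF.
#' @export
align_contigs <- function(contigs, reference, k = 19L, max_gap = 5000L,
                          min_chain_anchors = 3L, max_seed_hits = 10L) {
  if (inherits(contigs, "contig_set")) contigs <- contigs$contigs
  if (length(contigs) == 0L) return(empty_alignments())
  stopifnot(!is.null(names(contigs)), !is.null(names(reference)))
  k <- as.integer(k)
  records <- list()
  for (rname in names(reference)) {
    rseq <- reference[[rname]]
    if (nchar(rseq) < k) next
    ridx <- data.table::data.table(kmer = kmers_of(rseq, k),
                                   rpos = seq_len(nchar(rseq) - k + 1L) - 1L)
    ridx <- ridx[, if (.N <= max_seed_hits) .SD, by = "kmer"]
    data.table::setkey(ridx, kmer)
    for (qname in names(contigs)) {
      qseq_f <- contigs[[qname]]
      if (nchar(qseq_f) < k) next
      anchors_for <- function(qs) {
        qk <- data.table::data.table(kmer = kmers_of(qs, k),
                                     qpos = seq_len(nchar(qs) - k + 1L) - 1L)
        ridx[qk, on = "kmer", nomatch = NULL][, list(qpos, rpos)]
      }
      af <- anchors_for(qseq_f)
      qseq_r <- revcomp(qseq_f)
      ar <- anchors_for(qseq_r)
      strand <- if (nrow(ar) > nrow(af)) "-" else "+"
      anc <- if (strand == "-") ar else af
      qseq <- if (strand == "-") qseq_r else qseq_f
      if (nrow(anc) == 0L) next
      data.table::setorder(anc, qpos, -rpos)
      qlen <- nchar(qseq)
      used <- logical(nrow(anc))
      for (round in 1:10) {
        avail <- which(!used)
        if (length(avail) < min_chain_anchors && round > 1L) break
        if (length(avail) == 0L) break
        sel <- anc[avail]
        chain <- avail[lis_chain(sel$rpos)]
        if (length(chain) < min_chain_anchors && round > 1L) break
        if (length(chain) == 0L) break
        cq <- anc$qpos[chain]; cr <- anc$rpos[chain]
        # mark the chained query span as used for later rounds
        used[anc$qpos >= min(cq) & anc$qpos <= max(cq)] <- TRUE
        runs <- anchors_to_runs(cq, cr, k)
        # split where a gap exceeds max_gap
        if (nrow(runs) > 1L) {
          qgaps <- runs$qs[-1] - runs$qe[-nrow(runs)]
          rgaps <- runs$rs[-1] - runs$re[-nrow(runs)]
          piece <- cumsum(c(TRUE, qgaps > max_gap | rgaps > max_gap))
        } else piece <- 1L
        for (pc in unique(piece)) {
          rec <- runs_to_record(runs[piece == pc], qseq, rseq)
          if (is.null(rec) || rec$matches < k) next
          qs <- rec$q_start; qe <- rec$q_end
          if (strand == "-") { tmp <- qs; qs <- qlen - qe; qe <- qlen - tmp }
          records[[length(records) + 1L]] <- data.table::data.table(
            query_id = qname, query_len = qlen,
            query_start = qs, query_end = qe,
            strand = strand, target_id = rname,
            target_len = nchar(rseq),
            target_start = rec$r_start, target_end = rec$r_end,
            matches = rec$matches, block_len = rec$block_len,
            mapq = 60L, cigar = rec$cigar)
        }
      }
    }
  }
  if (length(records) == 0L) return(empty_alignments())
  aln <- data.table::rbindlist(records)
  aln[, ani := 100 * matches / block_len]
  aln[]
}

#' Per-alignment average nucleotide identity
#'
#' ANI of one alignment record: \code{100 * matches / block_len}, the
#' block length counting match, mismatch, inserted and deleted columns.
#'
#' @param record one alignment row (list or single-row data.table) with
#'   \code{matches} and \code{block_len}.
#' @return percentage in \[0, 100\].
#' @export
alignment_ani <- function(record) {
  if (is.null(record$block_len) || length(record$block_len) == 0L ||
      any(record$block_len == 0)) {
    stop("alignment has zero block length")
  }
  100 * record$matches / record$block_len
}
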