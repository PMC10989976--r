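#' @import data.table
#' @importFrom stats rbinom rnorm runif setNames
#' @importFrom utils head tail
NULL

# Internal DNA string helpers. Sequences are plain uppercase character
# vectors internally; Biostrings objects appear only at format boundaries
# and inside the anchor aligner.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (ACGTN alphabet).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All k-mers of a single sequence, in order. Returns character(0) if the
# sequence is shorter than k.
kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

# Canonical form (lexicographic min of a k-mer and its reverse complement).
canonical_kmers <- function(kmers) {
  if (length(kmers) == 0L) return(character(0))
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

# Canonical k-mers of one long sequence, computed without per-kmer
# reverse complements: the rc of the i-th forward k-mer is the
# (n-k+2-i)-th k-mer of the reverse-complemented sequence.
canonical_kmers_of_seq <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  fwd <- kmers_of(seq, k)
  rcs <- rev(kmers_of(revcomp(seq), k))
  ifelse(fwd <= rcs, fwd, rcs)
}

# Random DNA of given length from a supplied RNG stream.
random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Apply point substitutions at the given per-base rate; returns the mutated
# string and the number of substitutions applied.
mutate_substitutions <- function(seq, rate) {
  n <- nchar(seq)
  if (n == 0L || rate <= 0) return(list(seq = seq, n_subs = 0L))
  n_mut <- rbinom(1L, n, rate)
  if (n_mut == 0L) return(list(seq = seq, n_subs = 0L))
  pos <- sample.int(n, n_mut)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  list(seq = paste(chars, collapse = ""), n_subs = n_mut)
}

# Merge 0-based half-open intervals; returns a data.table(start, end) of
# disjoint sorted intervals. Thin wrapper over IRanges::reduce so every
# coverage computation in the package shares one merge routine.
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(data.table::data.table(start = integer(0), end = integer(0)))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  data.table::data.table(
    start = IRanges::start(ir) - 1L,
    end   = IRanges::end(ir)
  )
}

# Total merged length of 0-based half-open intervals.
merged_length <- function(start, end) {
  m <- merge_intervals(start, end)
  sum(as.numeric(m$end - m$start))
}
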