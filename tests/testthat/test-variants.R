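count_classes <- function(v) {
  c(snv = sum(v$class == "snv"),
    small = sum(v$class == "small_indel"),
    large = sum(v$class == "large_indel"))
}

test_that("planted SNV + 30 bp del + 60 bp ins in 12 kb give (1, 1, 1)", {
  set.seed(101)
  ref <- c(r = cobin:::random_dna(30000))
  q <- c(q1 = plant_variants(ref[[1]], 4000L, 12000L))
  aln <- align_contigs(q, ref)
  v <- call_variants(aln, q, ref)
  expect_equal(unname(count_classes(v)), c(1L, 1L, 1L))
  del <- v[v$class == "small_indel"]
  expect_equal(nchar(del$ref), 30L)
  expect_equal(del$alt, "")
  ins <- v[v$class == "large_indel"]
  expect_equal(nchar(ins$alt), 60L)
  expect_equal(ins$ref, "")
  snv <- v[v$class == "snv"]
  expect_equal(substr(ref[[1]], snv$position + 1, snv$position + 1), snv$ref)
})

test_that("alignments under 10 kb are filtered out before calling", {
  set.seed(102)
  ref <- c(r = cobin:::random_dna(30000))
  q <- c(q1 = plant_variants(ref[[1]], 4000L, 8000L))
  aln <- align_contigs(q, ref)
  v <- call_variants(aln, q, ref)
  expect_equal(nrow(v), 0L)
  # the same alignments pass with the filter relaxed
  v2 <- call_variants(aln, q, ref, min_alignment_len = 1000)
  expect_equal(unname(count_classes(v2)), c(1L, 1L, 1L))
})

test_that("single-base indels are ignored entirely", {
  set.seed(103)
  ref <- c(r = cobin:::random_dna(30000))
  q <- substr(ref[[1]], 1001, 16000)
  q <- paste0(substr(q, 1, 7000), substr(q, 7002, nchar(q)))     # 1 bp del
  q <- paste0(substr(q, 1, 11000), "A", substr(q, 11001, nchar(q)))  # 1 bp ins
  q <- c(q1 = q)
  aln <- align_contigs(q, ref)
  v <- call_variants(aln, q, ref)
  expect_equal(nrow(v[v$class != "snv"]), 0L)
})

test_that("small/large indel classes split at 50 bp", {
  set.seed(104)
  ref <- c(r = cobin:::random_dna(40000))
  q <- substr(ref[[1]], 1, 30000)
  # deletions of 2, 49, 50 bp at well-separated positions
  for (spec in list(c(25000L, 50L), c(15000L, 49L), c(5000L, 2L))) {
    q <- paste0(substr(q, 1, spec[1]), substr(q, spec[1] + spec[2] + 1L,
                                              nchar(q)))
  }
  q <- c(q1 = q)
  aln <- align_contigs(q, ref)
  v <- call_variants(aln, q, ref)
  idl <- v[v$class != "snv"]
  expect_equal(sort(nchar(idl$ref)), c(2L, 49L, 50L))
  expect_equal(idl$class[order(nchar(idl$ref))],
               c("small_indel", "small_indel", "large_indel"))
})

test_that("planted variant sets are recovered from seeded genomes", {
  # divergence-only sample genomes: recovered SNV rate tracks divergence
  sp <- data.frame(name = "s1", genome_length = 50000L, abundance = 5,
                   divergence = 0.01, unique_insertion_fraction = 0)
  com <- generate_community(community_spec(sp, seed = 105))
  q <- setNames(com$sample_genomes, "s1_asm")
  aln <- align_contigs(q, com$references)
  v <- call_variants(aln, q, com$references)
  aligned <- sum(aln$target_end - aln$target_start)
  rate <- sum(v$class == "snv") / aligned
  expect_lt(abs(rate - 0.01) / 0.01, 0.10)
  expect_equal(snv_density(v, aligned), sum(v$class == "snv") * 1e5 / aligned)
})

test_that("plain-M CIGARs and missing CIGARs are rejected", {
  aln <- data.table::data.table(
    query_id = "q", query_len = 12000L, query_start = 0L,
    query_end = 12000L, strand = "+", target_id = "r",
    target_len = 20000L, target_start = 0L, target_end = 12000L,
    matches = 12000L, block_len = 12000L, mapq = 60L,
    cigar = "12000M", ani = 100)
  seqs <- c(q = strrep("A", 12000)); refs <- c(r = strrep("A", 20000))
  expect_error(call_variants(aln, seqs, refs), "=/X/I/D")
  aln$cigar <- NA_character_
  expect_error(call_variants(aln, seqs, refs), "CIGAR")
})

test_that("shared variants key on position and sequence within a species", {
  v <- function(pos, ref, alt, class, sample) data.table::data.table(
    species = "sp1", sample = sample, reference_id = "r",
    position = pos, ref = ref, alt = alt, class = class)
  s1 <- rbind(v(100L, "A", "G", "snv", "s1"), v(200L, "", "ACGT", "small_indel", "s1"))
  s2 <- rbind(v(100L, "A", "G", "snv", "s2"), v(300L, "A", "T", "snv", "s2"))
  s3 <- rbind(v(100L, "A", "G", "snv", "s3"), v(300L, "A", "C", "snv", "s3"))
  sh <- shared_variants(list(s1 = s1, s2 = s2, s3 = s3))
  k <- sh$variants
  expect_equal(k$n_samples[k$position == 100], 3L)
  # same position, different alt: two distinct unshared keys
  expect_equal(sort(k$n_samples[k$position == 300]), c(1L, 1L))
  expect_equal(k$n_samples[k$position == 200], 1L)
  smry <- sh$summary
  expect_equal(smry$n_variants[smry$class == "snv" & smry$n_samples == 3], 1L)
})

test_that("sharing counts equal brute-force set algebra on random sets", {
  set.seed(106)
  samples <- c("sA", "sB", "sC", "sD")
  pool <- data.table::data.table(
    species = "sp", reference_id = "r",
    position = sample.int(5000L, 300), ref = "A",
    alt = sample(c("C", "G", "T"), 300, replace = TRUE), class = "snv")
  sets <- lapply(samples, function(s) {
    v <- pool[sample.int(300, 150)]
    v[, sample := s]
    v
  })
  names(sets) <- samples
  sh <- shared_variants(sets)
  key_of <- function(v) paste(v$position, v$alt)
  keys <- lapply(sets, key_of)
  all_keys <- unique(unlist(keys))
  brute_n <- vapply(all_keys, function(k)
    sum(vapply(keys, function(x) k %in% x, NA)), 0L)
  got <- sh$variants
  expect_equal(nrow(got), length(all_keys))
  expect_equal(got$n_samples[match(all_keys, key_of(got))],
               unname(brute_n))
})

test_that("snv density uses the per-100 kb convention", {
  v <- data.table::data.table(class = rep("snv", 90))
  expect_equal(snv_density(v, 1e6), 9.0)
  expect_equal(snv_density(v[0], 1e6), 0)
  expect_error(snv_density(v, 0))
})

test_that("the VCF writer emits anchored 1-based records", {
  set.seed(107)
  refs <- c(r = cobin:::random_dna(200))
  v <- data.table::data.table(
    species = "s", sample = "x", reference_id = "r",
    position = c(9L, 49L), ref = c("A", substr(refs[[1]], 51, 60)),
    alt = c("", ""), class = c("snv", "small_indel"))
  v$ref[1] <- substr(refs[[1]], 10, 10)
  v$alt[1] <- setdiff(c("A", "C", "G", "T"), v$ref[1])[1]
  path <- tempfile(fileext = ".vcf")
  write_variants_vcf(v, refs, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  f1 <- strsplit(body[1], "\t")[[1]]
  expect_equal(as.integer(f1[2]), 10L)         # 1-based SNV position
  f2 <- strsplit(body[2], "\t")[[1]]
  expect_equal(as.integer(f2[2]), 49L)         # anchor base position
  expect_equal(substr(f2[4], 1, 1), substr(refs[[1]], 49, 49))
  expect_equal(f2[5], substr(refs[[1]], 49, 49))
})
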