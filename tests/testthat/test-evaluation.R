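mk_aln <- function(ts, te, ani, target = "r", tlen = 10000L) {
  data.table::data.table(
    query_id = sprintf("q%d", seq_along(ts)), query_len = te - ts,
    query_start = 0L, query_end = te - ts, strand = "+",
    target_id = target, target_len = tlen, target_start = ts,
    target_end = te, matches = 1L, block_len = 1L, mapq = 60L,
    cigar = NA_character_, ani = ani)
}

test_that("genome fraction is merged high-identity reference coverage", {
  expect_equal(genome_fraction(mk_aln(0L, 9000L, 99), 10000L), 90)
  expect_equal(genome_fraction(cobin:::empty_alignments(), 10000L), 0)
  # identity threshold is strict
  expect_equal(genome_fraction(mk_aln(0L, 9000L, 95), 10000L), 0)
})

test_that("genome fraction equals a per-base bitmap on random intervals", {
  set.seed(90)
  for (rep in 1:100) {
    n <- sample(1:30, 1)
    ts <- sample.int(10000L, n, replace = TRUE) - 1L
    te <- pmin(ts + sample.int(3000L, n, replace = TRUE), 10000L)
    ani <- runif(n, 90, 100)
    got <- genome_fraction(mk_aln(ts, te, ani), 10000L)
    bitmap <- logical(10000)
    for (i in seq_len(n)) if (ani[i] > 95 && te[i] > ts[i]) {
      bitmap[(ts[i] + 1):te[i]] <- TRUE
    }
    expect_equal(got, 100 * sum(bitmap) / 10000)
  }
})

test_that("N50 and NG50 follow their cumulative-sum definitions", {
  got <- nx_ngx(c(5000, 4000, 3000, 2000, 1000), 10000)
  expect_equal(unname(got["n50"]), 4000)   # assembly 15 kb, half 7.5 kb
  expect_equal(unname(got["ng50"]), 5000)  # half reference 5 kb
  expect_equal(unname(nx_ngx(7000, 10000)), c(7000, 7000))
  expect_equal(unname(nx_ngx(7000, 20000)["ng50"]), 0)  # short assembly
  expect_equal(unname(nx_ngx(rep(2000, 5), 10000)), c(2000, 2000))
  expect_equal(unname(nx_ngx(numeric(0), 10000)), c(0, 0))
})

test_that("nx_ngx equals a brute-force implementation on random multisets", {
  brute <- function(lens, rlen) {
    lens <- sort(lens, decreasing = TRUE)
    n50 <- 0; ng50 <- 0
    for (thr in c(sum(lens) / 2, rlen / 2)) {
      acc <- 0
      val <- 0
      for (l in lens) { acc <- acc + l; if (acc >= thr) { val <- l; break } }
      if (thr == sum(lens) / 2) n50 <- val else ng50 <- val
    }
    c(n50 = n50, ng50 = ng50)
  }
  set.seed(91)
  for (rep in 1:200) {
    lens <- sample.int(50000L, sample(1:100, 1), replace = TRUE)
    rlen <- sample.int(2000000L, 1)
    expect_equal(nx_ngx(lens, rlen), brute(lens, rlen))
  }
})

test_that("valid fragments need more than 5 pairs spanning more than 10 kb", {
  mk <- function(pos) data.table::data.table(
    barcode = "b1", reference_id = "r", pos = pos)
  v6 <- count_valid_fragments(mk(seq(0, 12000, length.out = 6)))
  expect_true(v6$valid)
  v5 <- count_valid_fragments(mk(seq(0, 12000, length.out = 5)))
  expect_false(v5$valid)                       # exactly 5 pairs: invalid
  v_short <- count_valid_fragments(mk(seq(0, 8000, length.out = 6)))
  expect_false(v_short$valid)                  # 8 kb span: invalid
  # exact boundaries: 6 pairs spanning exactly 10,000 bp are invalid
  v_edge <- count_valid_fragments(mk(seq(0, 10000, length.out = 6)))
  expect_equal(v_edge$span, 10000)
  expect_false(v_edge$valid)
})

test_that("fragment clustering matches a brute-force gap split", {
  set.seed(92)
  n <- 1000
  pl <- data.table::data.table(
    barcode = sprintf("b%d", sample.int(40, n, replace = TRUE)),
    reference_id = sample(c("r1", "r2"), n, replace = TRUE),
    pos = sample.int(3000000L, n, replace = TRUE))
  got <- count_valid_fragments(pl, gap_max = 50000)
  brute_rows <- list()
  for (b in unique(pl$barcode)) for (r in unique(pl$reference_id)) {
    pos <- sort(pl$pos[pl$barcode == b & pl$reference_id == r])
    if (!length(pos)) next
    cl <- cumsum(c(TRUE, diff(pos) > 50000))
    for (ci in unique(cl)) {
      p <- pos[cl == ci]
      brute_rows[[length(brute_rows) + 1]] <- data.frame(
        barcode = b, reference_id = r, n = length(p),
        span = max(p) - min(p),
        valid = length(p) > 5 && (max(p) - min(p)) > 10000)
    }
  }
  brute <- do.call(rbind, brute_rows)
  expect_equal(nrow(got), nrow(brute))
  expect_equal(sum(got$valid), sum(brute$valid))
  expect_equal(sort(paste(got$barcode, got$reference_id,
                          got$read_pair_count, got$span)),
               sort(paste(brute$barcode, brute$reference_id,
                          brute$n, brute$span)))
})

test_that("truth quality scores perfect and mixed reconstructions", {
  set.seed(93)
  genomes <- c(tgt = cobin:::random_dna(8000), other = cobin:::random_dna(8000))
  perfect <- cobin:::new_contig_set("tgt", c(c1 = genomes[["tgt"]]), "toy")
  tq <- truth_quality(perfect, genomes, "tgt")
  expect_equal(tq$completeness, 100)
  expect_equal(tq$contamination, 0)

  mixed <- cobin:::new_contig_set("tgt", c(
    good = substr(genomes[["tgt"]], 1, 4000),
    bad = substr(genomes[["other"]], 1, 4000)), "toy")
  tq2 <- truth_quality(mixed, genomes, "tgt")
  expect_equal(tq2$contamination, 50)
  expect_equal(tq2$completeness, 50)
  expect_equal(tq2$origins$origin, c("tgt", "other"))
})

test_that("truth quality equals brute-force base accounting on planted mixtures", {
  set.seed(94)
  genomes <- c(a = cobin:::random_dna(6000), b = cobin:::random_dna(6000))
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    src <- sample(names(genomes), n, replace = TRUE)
    st <- sample.int(4000, n, replace = TRUE)
    len <- sample(500:2000, n, replace = TRUE)
    ctg <- setNames(substring(genomes[src], st, pmin(st + len, 6000)),
                    sprintf("c%d", seq_len(n)))
    cs <- cobin:::new_contig_set("a", ctg, "toy")
    tq <- truth_quality(cs, genomes, "a")
    bitmap <- logical(6000)
    for (i in seq_len(n)) if (src[i] == "a") {
      bitmap[st[i]:pmin(st[i] + len[i], 6000)] <- TRUE
    }
    expect_equal(tq$completeness, 100 * sum(bitmap) / 6000, tolerance = 1e-9)
    expect_equal(tq$contamination,
                 100 * sum(nchar(ctg[src == "b"])) / sum(nchar(ctg)))
  }
})

test_that("quality tiers follow the completeness/contamination bounds", {
  expect_equal(classify_quality(92, 3), "high")
  expect_equal(classify_quality(92, 6), "medium")   # fails the 5% bound
  expect_equal(classify_quality(49, 2), "low")
  expect_equal(classify_quality(90, 4), "medium")   # strict > 90
  expect_equal(classify_quality(51, 9.5), "medium")
  expect_equal(classify_quality(51, 10), "low")     # strict < 10
  expect_error(classify_quality(120, 0), "percentages")
})
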