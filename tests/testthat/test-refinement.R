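mk_tree <- function() {
  taxonomy_tree(c(1, 10, 100, 101), c(1, 1, 10, 10),
                c("root", "genus", "species", "species"),
                c("r", "g", "s1", "s2"))
}

test_that("taxonomy reads are exactly the species-taxid assignments", {
  tr <- mk_tree()
  cl <- data.table::data.table(read_id = c("r1", "r2", "r3", "r4"),
                               classified = c(TRUE, TRUE, FALSE, TRUE),
                               taxid = c(100L, 10L, 0L, 101L))
  expect_equal(extract_taxonomy_reads(cl, 100L, tr), "r1")
  expect_equal(extract_taxonomy_reads(cl[0], 100L, tr), character(0))
  expect_error(extract_taxonomy_reads(cl, 10L, tr), "not a species")
})

test_that("TR extraction equals a brute-force filter on simulated data", {
  fx <- fx_clean5()
  tr <- fx$ds$taxonomy
  taxid <- fx$ds$genome_taxids[["sp03"]]
  got <- extract_taxonomy_reads(fx$classifications, taxid, tr)
  brute <- fx$classifications$read_id[
    vapply(seq_len(nrow(fx$classifications)),
           function(i) fx$classifications$taxid[i] == taxid, NA)]
  expect_setequal(got, brute)
})

test_that("abundance is TR bases over reference bases", {
  reads <- data.table::data.table(
    read_id = sprintf("r%d", 1:5000),
    seq_fwd = strrep("A", 100), seq_rev = strrep("C", 100))
  expect_equal(estimate_abundance(reads, reads$read_id, 100000L), 10.0)
  expect_equal(estimate_abundance(reads, character(0), 100000L), 0)
  expect_error(estimate_abundance(reads, reads$read_id, 0))
})

test_that("barcode stats count TRs against whole-dataset barcode totals", {
  reads <- data.table::data.table(
    read_id = sprintf("r%d", 1:12),
    barcode = c(rep("1_1_1", 8), rep("2_2_2", 3), "0_0_0"),
    seq_fwd = strrep("A", 100), seq_rev = strrep("T", 100))
  trs <- sprintf("r%d", 1:6)          # 6 TRs, all in barcode 1_1_1
  st <- compute_barcode_stats(reads, trs)
  expect_equal(nrow(st), 1L)          # zero-TR barcodes are not candidates
  expect_equal(st$num_t, 6L)
  expect_equal(st$ratio_t, 0.75)
  expect_equal(st$total_reads, 8L)
  expect_equal(st$total_bases, 1600L)
})

test_that("barcode stats equal a brute-force two-pass count", {
  set.seed(12)
  n <- 3000
  reads <- data.table::data.table(
    read_id = sprintf("r%05d", 1:n),
    barcode = sprintf("%d_1_1", sample.int(120, n, replace = TRUE)),
    seq_fwd = strrep("A", 100), seq_rev = strrep("T", 100))
  trs <- sample(reads$read_id, 700)
  st <- compute_barcode_stats(reads, trs)
  for (i in sample.int(nrow(st), 25)) {
    b <- st$barcode[i]
    in_b <- reads$read_id[reads$barcode == b]
    expect_equal(st$total_reads[i], length(in_b))
    expect_equal(st$num_t[i], sum(in_b %in% trs))
    expect_equal(st$ratio_t[i], sum(in_b %in% trs) / length(in_b))
  }
  # every barcode with >= 1 TR present, none without
  tr_bcs <- unique(reads$barcode[reads$read_id %in% trs])
  expect_setequal(st$barcode, setdiff(tr_bcs, "0_0_0"))
})

test_that("barcodes rank by Num_T then Ratio_T, both descending", {
  st <- data.table::data.table(
    barcode = c("b1", "b2", "b3"),
    num_t = c(5L, 7L, 5L), ratio_t = c(0.5, 0.3, 0.9),
    total_reads = 10L, total_bases = 2000L)
  expect_equal(rank_barcodes(st)$barcode, c("b2", "b3", "b1"))
  tie <- data.table::data.table(barcode = c("bB", "bA"),
                                num_t = 3L, ratio_t = 0.5,
                                total_reads = 6L, total_bases = 1200L)
  expect_equal(rank_barcodes(tie)$barcode, c("bA", "bB"))
})

test_that("ranking equals a brute-force sort on 1,000 random stats", {
  set.seed(77)
  st <- data.table::data.table(
    barcode = sprintf("b%04d", sample.int(9999, 1000)),
    num_t = sample.int(20, 1000, replace = TRUE),
    ratio_t = round(runif(1000), 2),
    total_reads = 30L, total_bases = 6000L)
  got <- rank_barcodes(data.table::copy(st))
  brute <- st[order(-st$num_t, -st$ratio_t, st$barcode)]
  expect_equal(got$barcode, brute$barcode)
})

test_that("the cap includes the crossing barcode then stops", {
  reads <- data.table::data.table(
    read_id = sprintf("r%d", 1:9),
    barcode = rep(c("b1", "b2", "b3"), each = 3),
    seq_fwd = strrep("A", 100), seq_rev = strrep("T", 100))
  ranked <- data.table::data.table(
    barcode = c("b1", "b2", "b3"),
    num_t = c(3L, 2L, 1L), ratio_t = 1,
    total_reads = 3L, total_bases = 150000L)
  cfg <- refinement_config(cap_coverage = 300, min_abundance = 10)
  got <- collect_refined_reads(ranked, reads, 1000L, cfg)
  expect_equal(got$barcodes, c("b1", "b2"))   # 150k + 150k reaches 300k cap
  expect_true(got$capped)
  expect_setequal(got$read_ids, sprintf("r%d", 1:6))

  below <- data.table::copy(ranked)[, total_bases := 50000L]
  got2 <- collect_refined_reads(below, reads, 1000L, cfg)
  expect_equal(got2$barcodes, c("b1", "b2", "b3"))
  expect_false(got2$capped)
})

test_that("collection equals a brute-force walk and is cap-monotone", {
  fx <- fx_clean5()
  rs <- fx$read_sets[["sp04"]]
  reads <- fx$ds$reads
  ref_len <- nchar(fx$ds$references[["sp04"]])
  ranked <- rs$barcode_stats
  for (cap in c(15, 25, 300)) {
    cfg <- refinement_config(cap_coverage = cap, min_abundance = 10)
    got <- collect_refined_reads(ranked, reads, ref_len, cfg)
    # brute force: walk ranked barcodes accumulating whole-barcode bases
    acc <- 0; takes <- character(0)
    for (i in seq_len(nrow(ranked))) {
      acc <- acc + ranked$total_bases[i]
      takes <- c(takes, ranked$barcode[i])
      if (acc >= cap * ref_len) break
    }
    expect_equal(got$barcodes, takes)
    expect_setequal(got$read_ids, reads$read_id[reads$barcode %in% takes])
  }
  c1 <- collect_refined_reads(ranked, reads, ref_len,
                              refinement_config(15, 10))
  c2 <- collect_refined_reads(ranked, reads, ref_len,
                              refinement_config(25, 10))
  expect_equal(c1$barcodes, head(c2$barcodes, length(c1$barcodes)))
  expect_true(all(c1$read_ids %in% c2$read_ids))
})

test_that("the abundance gate is strict at its boundary", {
  tr <- mk_tree()
  refs <- c(s1 = cobin:::random_dna(1000), s2 = cobin:::random_dna(1000))
  taxids <- c(s1 = 100L, s2 = 101L)
  mk_reads <- function(n1, n2) {
    data.table::data.table(
      read_id = sprintf("r%d", seq_len(n1 + n2)),
      barcode = sprintf("%d_1_1", seq_len(n1 + n2)),
      seq_fwd = strrep("A", 50), seq_rev = strrep("T", 49))
  }
  # 50 pairs x 99 bases = 4950 bases on 1 kb -> 4.95x; 102 pairs -> 10.098x
  reads <- mk_reads(50, 102)
  cl <- data.table::data.table(
    read_id = reads$read_id, classified = TRUE,
    taxid = c(rep(100L, 50), rep(101L, 102)))
  rs <- refine_all_species(cl, reads, refs, taxids, tr)
  expect_true(rs$s1$skipped)           # 4.95 <= 10
  expect_false(rs$s2$skipped)          # 10.098 > 10
  expect_equal(rs$s1$abundance, 50 * 99 / 1000)
})

test_that("refinement keeps perfect precision without collisions", {
  fx <- fx_clean5()
  reads <- fx$ds$reads
  for (nm in names(fx$read_sets)) {
    rs <- fx$read_sets[[nm]]
    expect_false(rs$skipped)
    origin <- reads$truth_genome[reads$read_id %in% rs$refined_read_ids]
    expect_true(all(origin == nm))
  }
})

test_that("barcode recruitment lifts recall over TRs alone and above 0.9", {
  fx <- fx_unique2()
  reads <- fx$ds$reads
  for (nm in c("spU", "spV")) {
    rs <- fx$read_sets[[nm]]
    target_reads <- reads$read_id[reads$truth_genome == nm]
    recall_tr <- length(intersect(rs$tr_read_ids, target_reads)) /
      length(target_reads)
    recall_ref <- length(intersect(rs$refined_read_ids, target_reads)) /
      length(target_reads)
    expect_gt(recall_ref, recall_tr)
    expect_gt(recall_ref, 0.9)
    # and the unclassifiable unique-region reads are the ones recruited
    uniq <- reads$read_id[reads$truth_genome == nm &
                            reads$truth_region == "unique_genome_specific"]
    expect_gt(length(intersect(rs$refined_read_ids, uniq)) / length(uniq),
              0.9)
  }
})

test_that("a 20x species' abundance estimate lands in [18, 20]", {
  fx <- fx_clean5()
  ab <- fx$read_sets[["sp01"]]$abundance
  expect_gte(ab, 18)
  expect_lte(ab, 20)
})

test_that("refined sets are invariant to read-order permutation", {
  fx <- fx_tiny()
  cl <- data.table::copy(fx$classifications)
  cl[, taxid := lift_to_species(fx$ds$taxonomy, taxid)]
  reads <- fx$ds$reads
  rs1 <- refine_all_species(cl, reads, fx$ds$references,
                            fx$ds$genome_taxids, fx$ds$taxonomy)
  set.seed(4)
  perm <- sample.int(nrow(reads))
  rs2 <- refine_all_species(cl[sample.int(nrow(cl))], reads[perm],
                            fx$ds$references, fx$ds$genome_taxids,
                            fx$ds$taxonomy)
  for (nm in names(rs1)) {
    expect_setequal(rs1[[nm]]$refined_read_ids, rs2[[nm]]$refined_read_ids)
    expect_equal(rs1[[nm]]$abundance, rs2[[nm]]$abundance)
  }
})
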