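# Shared simulated fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# small 3-species community: divergence 0, no errors, no collisions; one
# shared repeat block and one species with unique insertions — the regimes
# the classifier and refinement tests rely on
fx_tiny <- function() {
  fx_get("tiny", function() {
    sp <- data.frame(name = c("spA", "spB", "spC"),
                     genome_length = 20000L,
                     abundance = c(25, 25, 25),
                     divergence = 0,
                     unique_insertion_fraction = c(0.1, 0, 0))
    spec <- community_spec(
      sp,
      shared_repeats = data.frame(species_a = "spA", species_b = "spB",
                                  length = 1500L),
      collision_rate = 0, error_rate = 0, seed = 7)
    com <- generate_community(spec)
    ds <- simulate_cobarcoded_reads(spec, com)
    idx <- build_kmer_index(ds$references, ds$genome_taxids, ds$taxonomy)
    cl <- classify_reads_fixture(ds$reads, idx)
    list(spec = spec, ds = ds, index = idx, classifications = cl)
  })
}

# 5-species 50 kb community, error-free and collision-free, with one
# species at 20x: refinement precision and abundance-recovery conditions
fx_clean5 <- function() {
  fx_get("clean5", function() {
    sp <- data.frame(name = sprintf("sp%02d", 1:5),
                     genome_length = 50000L,
                     abundance = c(20, 15, 25, 30, 12),
                     divergence = 0,
                     unique_insertion_fraction = 0.01)
    spec <- community_spec(
      sp,
      shared_repeats = data.frame(species_a = "sp01", species_b = "sp02",
                                  length = 1500L),
      collision_rate = 0, error_rate = 0, seed = 42)
    com <- generate_community(spec)
    ds <- simulate_cobarcoded_reads(spec, com)
    idx <- build_kmer_index(ds$references, ds$genome_taxids, ds$taxonomy)
    cl <- classify_reads_fixture(ds$reads, idx)
    cl[, taxid := cobin::lift_to_species(ds$taxonomy, taxid)]
    rs <- refine_all_species(cl, ds$reads, ds$references, ds$genome_taxids,
                             ds$taxonomy)
    list(spec = spec, ds = ds, classifications = cl, read_sets = rs)
  })
}

# heavy unique-insertion community (20% novel sequence, 30 kb fragments):
# the regime where barcode recruitment must rescue unclassifiable reads
fx_unique2 <- function() {
  fx_get("unique2", function() {
    sp <- data.frame(name = c("spU", "spV"),
                     genome_length = 50000L,
                     abundance = c(25, 25),
                     divergence = 0,
                     unique_insertion_fraction = 0.2)
    spec <- community_spec(sp, collision_rate = 0, error_rate = 0,
                           fragment_median = 30000, seed = 17)
    com <- generate_community(spec)
    ds <- simulate_cobarcoded_reads(spec, com)
    idx <- build_kmer_index(ds$references, ds$genome_taxids, ds$taxonomy)
    cl <- classify_reads_fixture(ds$reads, idx)
    cl[, taxid := cobin::lift_to_species(ds$taxonomy, taxid)]
    rs <- refine_all_species(cl, ds$reads, ds$references, ds$genome_taxids,
                             ds$taxonomy)
    list(spec = spec, ds = ds, classifications = cl, read_sets = rs)
  })
}

# end-to-end study conditions: five species spanning 12-50x plus one at 5x
# to exercise the abundance gate, with sequencing errors, divergence and
# barcode collisions on
fx_e2e_spec <- function(seed = 11L) {
  sp <- data.frame(name = sprintf("sp%02d", 1:5),
                   genome_length = 50000L,
                   abundance = c(12, 20, 30, 50, 5),
                   divergence = 5e-4,
                   unique_insertion_fraction = 0.01)
  community_spec(
    sp,
    shared_repeats = data.frame(species_a = "sp01", species_b = "sp02",
                                length = 1500L),
    collision_rate = 0.005, error_rate = 5e-4, seed = seed)
}

fx_e2e <- function() {
  fx_get("e2e", function() {
    spec <- fx_e2e_spec()
    com <- generate_community(spec)
    ds <- simulate_cobarcoded_reads(spec, com)
    res <- run_pipeline(ds$reads, ds$references, ds$genome_taxids,
                        ds$taxonomy, sample_genomes = ds$sample_genomes)
    list(spec = spec, ds = ds, result = res)
  })
}

# random taxonomy tree with n nodes (node i's parent drawn among 1..i-1)
random_tree <- function(n, seed) {
  set.seed(seed)
  taxid <- seq_len(n) * 10L
  parent <- c(taxid[1], vapply(2:n, function(i) taxid[sample.int(i - 1L, 1L)], 0L))
  rank <- c("root", ifelse(vapply(2:n, function(i)
    any(parent[-1] == taxid[i]), NA), "clade", "species"))
  taxonomy_tree(taxid, parent, rank, paste0("n", taxid))
}

# plant a substitution, a deletion and an insertion into a reference
# slice and return the mutated query plus the truth
plant_variants <- function(ref, start, len, del_len = 30L, ins_len = 60L,
                           seed = 1L) {
  set.seed(seed)
  q <- substr(ref, start + 1L, start + len)
  # SNV at query offset ~len/5
  p_snv <- as.integer(len / 5)
  old <- substr(q, p_snv, p_snv)
  new <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(q, p_snv, p_snv) <- new
  # deletion at ~2/5
  p_del <- as.integer(2 * len / 5)
  q <- paste0(substr(q, 1, p_del), substr(q, p_del + del_len + 1L, nchar(q)))
  # insertion at ~3/5 (relative to current query)
  p_ins <- as.integer(3 * len / 5)
  q <- paste0(substr(q, 1, p_ins), cobin:::random_dna(ins_len),
              substr(q, p_ins + 1L, nchar(q)))
  q
}

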