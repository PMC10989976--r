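# Synthetic cobarcoded communities. The generator plants the three read
# regimes that drive the binning-first design: species-specific sequence,
# inter-species repeat blocks shared verbatim between reference genomes,
# and unique genome-specific insertions present in the sample genome but
# absent from every reference. Long fragments are partitioned into
# barcodes with a small collision probability, and 100 bp read pairs are
# sampled along each fragment, so barcodes carry the long-range linkage
# that refinement exploits.

#' Specify a synthetic community
#'
#' @param species data.frame with columns \code{name},
#'   \code{genome_length} (bp), \code{abundance} (fold coverage),
#'   \code{divergence} (substitutions/bp of the sample genome relative to
#'   its reference) and \code{unique_insertion_fraction} (fraction of the
#'   sample genome made of novel insertions absent from the reference).
#' @param shared_repeats data.frame with columns \code{species_a},
#'   \code{species_b} (names in \code{species}) and \code{length}: blocks
#'   copied verbatim between the two references (inter-species repeats).
#' @param fragment_median,fragment_sdlog log-normal long-fragment length
#'   model (bp); the median default of 30 kb gives fragments long enough to
#'   span several unique insertions and to satisfy the >10 kb
#'   valid-fragment span.
#' @param fragment_coverage per-fragment read coverage (read bases per
#'   fragment base); 0.3x gives a read pair roughly every 670 bp.
#' @param read_length read length per mate (bp).
#' @param insert_mean,insert_sd sequencing insert size model (bp).
#' @param collision_rate probability that a long fragment joins an
#'   already-used barcode instead of a fresh one.
#' @param error_rate per-base substitution sequencing error rate.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the spec including this seed.
#' @return an object of class \code{community_spec}.
#' @export
community_spec <- function(species,
                           shared_repeats = NULL,
                           fragment_median = 30000,
                           fragment_sdlog = 0.35,
                           fragment_coverage = 0.3,
                           read_length = 100L,
                           insert_mean = 350,
                           insert_sd = 35,
                           collision_rate = 0.005,
                           error_rate = 5e-4,
                           seed = 1L) {
  species <- data.table::as.data.table(species)
  need <- c("name", "genome_length", "abundance", "divergence",
            "unique_insertion_fraction")
  if (!all(need %in% names(species))) {
    stop("species table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(species$name)) stop("duplicate species names")
  stopifnot(all(species$abundance > 0),
            all(species$divergence >= 0),
            all(species$unique_insertion_fraction >= 0),
            all(species$unique_insertion_fraction < 1),
            read_length <= fragment_median,
            fragment_coverage > 0)
  if (is.null(shared_repeats)) {
    shared_repeats <- data.table::data.table(species_a = character(0),
                                             species_b = character(0),
                                             length = integer(0))
  } else {
    shared_repeats <- data.table::as.data.table(shared_repeats)
    ok <- shared_repeats$species_a %in% species$name &
      shared_repeats$species_b %in% species$name
    if (!all(ok)) stop("shared_repeats names species not in the community")
    if (any(shared_repeats$length >
            species$genome_length[match(shared_repeats$species_a, species$name)]) ||
        any(shared_repeats$length >
            species$genome_length[match(shared_repeats$species_b, species$name)])) {
      stop("shared repeat block longer than a genome")
    }
  }
  structure(list(species = species, shared_repeats = shared_repeats,
                 fragment_median = fragment_median,
                 fragment_sdlog = fragment_sdlog,
                 fragment_coverage = fragment_coverage,
                 read_length = as.integer(read_length),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 collision_rate = collision_rate,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf(
    "community_spec: %d species, %d shared blocks, seed %d\n",
    nrow(x$species), nrow(x$shared_repeats), x$seed))
  invisible(x)
}

#' Default mock community specification
#'
#' A ten-member mock: eight bacteria at equal high relative abundance (12%
#' each) and two fungi at 2% each, scaled to \code{total_coverage}; at the
#' 250x default the bacteria sit at 30x and the fungi at 5x, below the 10x
#' refinement gate. Genomes are miniaturised to 50 kb so the full pipeline
#' runs at desk scale; one modest inter-species repeat links the first two
#' bacteria.
#'
#' @param total_coverage total community fold coverage distributed by
#'   relative abundance.
#' @param seed integer seed.
#' @return a [community_spec()].
#' @export
mock_default_spec <- function(total_coverage = 250, seed = 1L) {
  rel <- c(rep(0.12, 8), rep(0.02, 2))
  species <- data.table::data.table(
    name = c(sprintf("bacterium_%02d", 1:8), sprintf("fungus_%02d", 1:2)),
    genome_length = 50000L,
    abundance = rel * total_coverage,
    divergence = 5e-4,
    unique_insertion_fraction = 0.01
  )
  shared <- data.table::data.table(species_a = "bacterium_01",
                                   species_b = "bacterium_02",
                                   length = 1500L)
  community_spec(species, shared, seed = seed)
}

# union-find over species names: species pairs sharing a repeat block are
# placed in the same genus so the block's k-mers collapse to a genus LCA
genus_components <- function(species_names, shared_repeats) {
  parent <- setNames(seq_along(species_names), species_names)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(shared_repeats)) {
    for (j in seq_len(nrow(shared_repeats))) {
      a <- find(match(shared_repeats$species_a[j], species_names))
      b <- find(match(shared_repeats$species_b[j], species_names))
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_along(species_names), find, 0L)
  match(roots, unique(roots))
}

#' Generate reference and sample genomes for a community
#'
#' References are i.i.d. uniform DNA with the specified shared-repeat
#' blocks copied verbatim across species pairs. Each sample genome is its
#' reference with point substitutions at the species' divergence plus
#' novel random insertions totalling \code{unique_insertion_fraction} of
#' the genome length. The taxonomy is a star of genera (root - genus -
#' species) in which block-sharing species share a genus.
#'
#' @param spec a [community_spec()].
#' @return an object of class \code{community}: \code{references} and
#'   \code{sample_genomes} (named character vectors), \code{taxonomy}
#'   (a [taxonomy_tree()]), \code{genome_taxids} (named integer vector),
#'   and per-species truth interval tables \code{repeat_blocks} and
#'   \code{insertions} (0-based half-open, on sample-genome coordinates;
#'   repeat blocks also carry reference coordinates).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  sp <- spec$species
  n_sp <- nrow(sp)

  references <- setNames(vapply(sp$genome_length, random_dna, ""), sp$name)

  # plant shared blocks; track occupied reference intervals per genome so
  # blocks and (later) insertions avoid each other
  blocks <- data.table::data.table(species = character(0), block_id = integer(0),
                                   ref_start = integer(0), ref_end = integer(0))
  occupied <- setNames(vector("list", n_sp), sp$name)
  pick_free <- function(name, len) {
    L <- nchar(references[[name]])
    if (len > L) stop("repeat block longer than genome")
    for (try in 1:200) {
      s <- sample.int(L - len + 1L, 1L) - 1L
      occ <- occupied[[name]]
      clash <- !is.null(occ) &&
        any(s < occ$end & (s + len) > occ$start)
      if (!clash) return(s)
    }
    stop("could not place repeat block without overlap")
  }
  if (nrow(spec$shared_repeats)) {
    for (j in seq_len(nrow(spec$shared_repeats))) {
      b <- spec$shared_repeats[j]
      blockseq <- random_dna(b$length)
      for (name in c(b$species_a, b$species_b)) {
        s <- pick_free(name, b$length)
        substr(references[[name]], s + 1L, s + b$length) <- blockseq
        iv <- data.table::data.table(start = s, end = s + b$length)
        occupied[[name]] <- data.table::rbindlist(list(occupied[[name]], iv))
        blocks <- data.table::rbindlist(list(blocks, data.table::data.table(
          species = name, block_id = j, ref_start = s, ref_end = s + b$length)))
      }
    }
  }

  # sample genomes: substitutions, then insertions at positions outside
  # shared blocks (so a repeat-labelled read never contains novel bases)
  sample_genomes <- character(n_sp)
  names(sample_genomes) <- sp$name
  ins_tab <- list()
  blk_tab <- list()
  for (i in seq_len(n_sp)) {
    name <- sp$name[i]
    g <- mutate_substitutions(references[[name]], sp$divergence[i])$seq
    L <- nchar(g)
    total_ins <- as.integer(round(sp$unique_insertion_fraction[i] * L))
    ins <- data.table::data.table(start = integer(0), end = integer(0))
    if (total_ins > 0L) {
      n_ins <- max(1L, as.integer(round(total_ins / 2000)))
      lens <- rep(total_ins %/% n_ins, n_ins)
      if (total_ins %% n_ins) lens[1] <- lens[1] + total_ins %% n_ins
      occ <- occupied[[name]]
      repeat {
        pos <- sort(sample.int(L - 1L, n_ins))   # ref position before which to insert
        clash <- !is.null(occ) &&
          any(vapply(pos, function(p) any(p > occ$start & p < occ$end), NA))
        if (!clash && !anyDuplicated(pos)) break
      }
      # splice insertions right-to-left so earlier positions stay valid
      shift <- cumsum(c(0L, lens))[seq_len(n_ins)]
      for (j in rev(seq_len(n_ins))) {
        g <- paste0(substr(g, 1L, pos[j]), random_dna(lens[j]),
                    substr(g, pos[j] + 1L, nchar(g)))
      }
      ins <- data.table::data.table(start = pos + shift,
                                    end = pos + shift + lens)
      ins_tab[[name]] <- data.table::data.table(species = name, ins)
      # shift this species' block coordinates into sample space
      shift_at <- function(x) {
        vapply(x, function(p) as.integer(p + sum(lens[pos <= p])), 0L)
      }
    } else {
      shift_at <- identity
    }
    bl <- blocks[blocks$species == name]
    if (nrow(bl)) {
      blk_tab[[name]] <- data.table::data.table(
        species = name, block_id = bl$block_id,
        ref_start = bl$ref_start, ref_end = bl$ref_end,
        start = as.integer(shift_at(bl$ref_start)),
        end = as.integer(shift_at(bl$ref_end)))
    }
    sample_genomes[name] <- g
  }

  # taxonomy: root 1; genera 100+; species 1000+
  genus_of <- genus_components(sp$name, spec$shared_repeats)
  sp_taxid <- 1000L + seq_len(n_sp)
  genus_taxid <- 100L + genus_of
  tax <- taxonomy_tree(
    taxid = c(1L, unique(genus_taxid), sp_taxid),
    parent_taxid = c(1L, rep(1L, length(unique(genus_taxid))), genus_taxid),
    rank = c("root", rep("genus", length(unique(genus_taxid))),
             rep("species", n_sp)),
    name = c("root", sprintf("genus_%02d", unique(genus_taxid) - 100L),
             sp$name))
  structure(list(
    references = references,
    sample_genomes = sample_genomes,
    taxonomy = tax,
    genome_taxids = setNames(sp_taxid, sp$name),
    repeat_blocks = if (length(blk_tab)) data.table::rbindlist(blk_tab)
                    else data.table::data.table(species = character(0),
                                                block_id = integer(0),
                                                ref_start = integer(0),
                                                ref_end = integer(0),
                                                start = integer(0),
                                                end = integer(0)),
    insertions = if (length(ins_tab)) data.table::rbindlist(ins_tab)
                 else data.table::data.table(species = character(0),
                                             start = integer(0),
                                             end = integer(0)),
    spec = spec), class = "community")
}

# truth_region of a read interval set: unique if every mate lies wholly in
# an insertion, repeat if every mate lies wholly in a shared block,
# species_specific otherwise
label_regions <- function(starts1, ends1, starts2, ends2, ins, blk) {
  within_any <- function(s, e, tab) {
    if (nrow(tab) == 0L) return(rep(FALSE, length(s)))
    q <- IRanges::IRanges(s + 1L, e)
    subj <- IRanges::IRanges(tab$start + 1L, tab$end)
    IRanges::overlapsAny(q, subj, type = "within")
  }
  in_ins <- within_any(starts1, ends1, ins) & within_any(starts2, ends2, ins)
  in_blk <- within_any(starts1, ends1, blk) & within_any(starts2, ends2, blk)
  ifelse(in_ins, "unique_genome_specific",
         ifelse(in_blk, "inter_species_repeat", "species_specific"))
}

#' Simulate cobarcoded read pairs over a community
#'
#' Long fragments are drawn per species until the target fold coverage in
#' read bases is reached; each fragment receives a barcode (fresh, or an
#' already-used one with probability \code{collision_rate}); read pairs are
#' placed uniformly along the fragment at the per-fragment coverage. Truth
#' labels record each read's genome, fragment and region regime.
#'
#' @param spec a [community_spec()].
#' @param community a [generate_community()] result for the same spec.
#' @return an object of class \code{simulated_dataset}: \code{reads} (read
#'   table with \code{truth_genome}, \code{truth_fragment},
#'   \code{truth_region}), \code{fragments} (fragment_id, genome, barcode,
#'   start, end on sample-genome coordinates), plus the community fields.
#' @export
simulate_cobarcoded_reads <- function(spec, community) {
  stopifnot(inherits(spec, "community_spec"), inherits(community, "community"))
  set.seed(spec$seed + 1L)
  rl <- spec$read_length
  sp <- spec$species
  min_frag <- max(1000, 2 * spec$insert_mean)

  frag_rows <- list()
  read_rows <- list()
  frag_n <- 0L
  for (i in seq_len(nrow(sp))) {
    name <- sp$name[i]
    g <- community$sample_genomes[[name]]
    L <- nchar(g)
    target <- sp$abundance[i] * L
    ins <- community$insertions[community$insertions$species == name]
    blk <- community$repeat_blocks[community$repeat_blocks$species == name]
    got <- 0
    sp_frags <- list()
    while (got < target) {
      flen <- round(exp(log(spec$fragment_median) +
                          rnorm(1, 0, spec$fragment_sdlog)))
      flen <- min(flen, L)
      # start may fall before the origin so edge positions keep uniform
      # coverage; the fragment is clipped to the genome
      s0 <- sample.int(L + flen - 1L, 1L) - flen
      fs <- max(0L, s0)
      fe <- min(s0 + flen, L)
      if (fe - fs < min(min_frag, L)) next
      flen_eff <- fe - fs
      n_pairs <- max(1L, round(spec$fragment_coverage * flen_eff / (2 * rl)))
      frag_n <- frag_n + 1L
      fid <- sprintf("frag%06d", frag_n)
      inserts <- as.integer(pmin(pmax(round(rnorm(n_pairs, spec$insert_mean,
                                                  spec$insert_sd)),
                                      2L * rl), flen_eff))
      starts <- fs + vapply(flen_eff - inserts + 1L,
                            function(m) sample.int(m, 1L) - 1L, 0L)
      s1 <- starts; e1 <- starts + rl
      s2 <- starts + inserts - rl; e2 <- starts + inserts
      fwd <- substring(g, s1 + 1L, e1)
      rev <- revcomp(substring(g, s2 + 1L, e2))
      if (spec$error_rate > 0) {
        fwd <- vapply(fwd, function(x)
          mutate_substitutions(x, spec$error_rate)$seq, "",
          USE.NAMES = FALSE)
        rev <- vapply(rev, function(x)
          mutate_substitutions(x, spec$error_rate)$seq, "",
          USE.NAMES = FALSE)
      }
      sp_frags[[length(sp_frags) + 1L]] <- data.table::data.table(
        fragment_id = fid, genome = name, start = fs, end = fe)
      read_rows[[length(read_rows) + 1L]] <- data.table::data.table(
        fragment_id = fid,
        seq_fwd = fwd, seq_rev = rev,
        truth_genome = name,
        truth_region = label_regions(s1, e1, s2, e2, ins, blk),
        pos_fwd = s1, pos_rev = s2)
      got <- got + 2 * rl * n_pairs
    }
    frag_rows[[i]] <- data.table::rbindlist(sp_frags)
  }
  fragments <- data.table::rbindlist(frag_rows)
  reads <- data.table::rbindlist(read_rows)

  # barcode assignment: fragments visited in random order; with probability
  # collision_rate a fragment joins a uniformly chosen used barcode
  nf <- nrow(fragments)
  order_idx <- sample.int(nf)
  bc_idx <- integer(nf)
  n_bc <- 0L
  collide <- runif(nf) < spec$collision_rate
  for (j in seq_len(nf)) {
    i <- order_idx[j]
    if (collide[j] && n_bc > 0L) {
      bc_idx[i] <- sample.int(n_bc, 1L)
    } else {
      n_bc <- n_bc + 1L
      bc_idx[i] <- n_bc
    }
  }
  fragments[, barcode := sprintf("%d_%d_%d",
                                 (bc_idx - 1L) %% 1536L + 1L,
                                 (bc_idx - 1L) %/% 1536L %% 1536L + 1L,
                                 (bc_idx - 1L) %/% (1536L * 1536L) + 1L)]

  reads[, barcode := fragments$barcode[match(fragment_id, fragments$fragment_id)]]
  reads[, read_id := sprintf("r%07d", .I)]
  reads[, `:=`(qual_fwd = strrep("I", nchar(seq_fwd)),
               qual_rev = strrep("I", nchar(seq_rev)))]
  data.table::setnames(reads, "fragment_id", "truth_fragment")
  data.table::setcolorder(reads, c("read_id", "barcode", "seq_fwd", "seq_rev",
                                   "qual_fwd", "qual_rev", "truth_genome",
                                   "truth_fragment", "truth_region"))
  structure(c(list(reads = reads[], fragments = fragments[]),
              community[setdiff(names(community), "spec")],
              list(spec = spec)),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "simulated_dataset: %d read pairs, %d fragments, %d barcodes, %d species\n",
    nrow(x$reads), nrow(x$fragments),
    data.table::uniqueN(x$fragments$barcode), length(x$references)))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the reference and sample-genome FASTA, paired stLFR-dialect
#' FASTQ, the taxonomy TSV, and truth tables (read and fragment level) as
#' TSV into \code{dir}.
#'
#' @param dataset a [simulate_cobarcoded_reads()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written paths.
#' @export
write_simulated_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    references = file.path(dir, "references.fasta"),
    sample_genomes = file.path(dir, "sample_genomes.fasta"),
    fastq_fwd = file.path(dir, "reads_1.fastq.gz"),
    fastq_rev = file.path(dir, "reads_2.fastq.gz"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    genome_taxids = file.path(dir, "genome_taxids.tsv"),
    read_truth = file.path(dir, "read_truth.tsv"),
    fragment_truth = file.path(dir, "fragment_truth.tsv"))
  write_fasta(dataset$references, paths$references)
  write_fasta(dataset$sample_genomes, paths$sample_genomes)
  write_stlfr_fastq(dataset$reads, paths$fastq_fwd, paths$fastq_rev)
  write_taxonomy_table(dataset$taxonomy, paths$taxonomy)
  data.table::fwrite(data.table::data.table(
    genome = names(dataset$genome_taxids),
    taxid = as.integer(dataset$genome_taxids)),
    paths$genome_taxids, sep = "\t")
  data.table::fwrite(dataset$reads[, c("read_id", "barcode", "truth_genome",
                                       "truth_fragment", "truth_region")],
                     paths$read_truth, sep = "\t")
  data.table::fwrite(dataset$fragments, paths$fragment_truth, sep = "\t")
  invisible(paths)
}
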