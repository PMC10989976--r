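# End-to-end orchestration: classify (external classifications or the
# built-in fixture classifier) -> refine per species -> assemble ->
# decontaminate -> evaluate. Species are processed independently in
# deterministic taxid order; a failure in one species is recorded in the
# manifest and does not stop the others.

#' Pipeline configuration
#'
#' @param refinement a [refinement_config()].
#' @param ani_min,af_min decontamination thresholds (percent / fraction).
#' @param identity_min evaluation identity threshold (percent) for genome
#'   fraction.
#' @param min_alignment_len minimum alignment reference span (bp) for
#'   variant calling.
#' @param assembler \code{"toy"} or \code{"external"}.
#' @param assembler_cmd command template with \code{{fwd}} \code{{rev}}
#'   \code{{out}} placeholders (external assembler only).
#' @param assembly_k,min_kmer_count toy assembler parameters.
#' @param classifier_k fixture classifier k-mer size.
#' @param output_dir directory for per-species FASTQ/FASTA and report
#'   TSVs; nothing is written when NULL.
#' @return an object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(refinement = refinement_config(),
                            ani_min = 90, af_min = 0.5,
                            identity_min = 95, min_alignment_len = 10000,
                            assembler = c("toy", "external"),
                            assembler_cmd = NULL,
                            assembly_k = 31L, min_kmer_count = 2L,
                            classifier_k = 31L, output_dir = NULL) {
  assembler <- match.arg(assembler)
  stopifnot(ani_min >= 0, ani_min <= 100, af_min >= 0, af_min <= 1,
            identity_min >= 0, identity_min <= 100)
  if (assembler == "external" && is.null(assembler_cmd)) {
    stop("assembler_cmd required for the external assembler")
  }
  structure(list(refinement = refinement, ani_min = ani_min,
                 af_min = af_min, identity_min = identity_min,
                 min_alignment_len = min_alignment_len,
                 assembler = assembler, assembler_cmd = assembler_cmd,
                 assembly_k = as.integer(assembly_k),
                 min_kmer_count = as.integer(min_kmer_count),
                 classifier_k = as.integer(classifier_k),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the binning-first-and-assembly-later pipeline
#'
#' @param reads read table (simulator output or [read_stlfr_fastq()], the
#'   latter optionally joined with truth tables).
#' @param references named character vector of reference genomes.
#' @param genome_taxids named integer vector: species taxid per reference.
#' @param tree a [taxonomy_tree()].
#' @param classifications optional classification table (e.g. parsed
#'   Kraken2 output); when NULL the fixture classifier is run on
#'   \code{references}.
#' @param sample_genomes optional named character vector of truth sample
#'   genomes; enables truth-label completeness/contamination and quality
#'   tiers when the reads carry truth columns.
#' @param config a [pipeline_config()].
#' @return list with \code{manifest} (one row per species, taxid order),
#'   \code{species} (named list of per-species detail: read set, contig
#'   sets, decontamination report, evaluation), and
#'   \code{classifications}. Attribute \code{n_failed} counts species
#'   whose processing errored.
#' @export
run_pipeline <- function(reads, references, genome_taxids, tree,
                         classifications = NULL, sample_genomes = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  reads <- data.table::as.data.table(reads)
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  if (is.null(classifications)) {
    index <- build_kmer_index(references, genome_taxids, tree,
                              k = config$classifier_k)
    classifications <- classify_reads_fixture(reads, index)
  }
  classifications <- data.table::as.data.table(classifications)
  classifications[, taxid := lift_to_species(tree, taxid)]

  read_sets <- refine_all_species(classifications, reads, references,
                                  genome_taxids, tree,
                                  config = config$refinement)
  ord <- names(sort(genome_taxids))
  manifest <- list()
  detail <- list()
  n_failed <- 0L
  with_truth <- !is.null(sample_genomes) && "truth_genome" %in% names(reads)
  for (name in ord) {
    rs <- read_sets[[name]]
    taxid <- genome_taxids[[name]]
    row <- data.table::data.table(
      species = name, taxid = taxid, status = "ok",
      abundance = rs$abundance, n_trs = length(rs$tr_read_ids),
      n_refined = length(rs$refined_read_ids), capped = rs$capped,
      n_contigs = NA_integer_, n_kept = NA_integer_,
      genome_fraction = NA_real_, n50 = NA_real_, ng50 = NA_real_,
      completeness = NA_real_, contamination = NA_real_,
      tier = NA_character_, assembly_path = NA_character_)
    if (rs$skipped) {
      row$status <- "skipped: abundance"
      manifest[[name]] <- row
      detail[[name]] <- list(read_set = rs)
      next
    }
    res <- tryCatch({
      refined <- reads[reads$read_id %in% rs$refined_read_ids]
      sp_dir <- if (!is.null(out_dir)) file.path(out_dir, name) else NULL
      if (!is.null(sp_dir)) {
        dir.create(sp_dir, recursive = TRUE, showWarnings = FALSE)
        write_stlfr_fastq(refined, file.path(sp_dir, "refined_1.fastq.gz"),
                          file.path(sp_dir, "refined_2.fastq.gz"))
      }
      contigs <- if (config$assembler == "toy") {
        toy_debruijn_assemble(refined, k = config$assembly_k,
                              min_kmer_count = config$min_kmer_count,
                              species = name)
      } else {
        wd <- if (!is.null(sp_dir)) sp_dir else tempfile("asm")
        dir.create(wd, recursive = TRUE, showWarnings = FALSE)
        fq1 <- file.path(wd, "refined_1.fastq")
        fq2 <- file.path(wd, "refined_2.fastq")
        write_stlfr_fastq(refined, fq1, fq2)
        run_external_assembler(fq1, fq2, config$assembler_cmd, wd,
                               species = name)
      }
      ref <- references[name]
      dec <- decontaminate(contigs, ref, ani_min = config$ani_min,
                           af_min = config$af_min)
      kept <- dec$kept
      keep_aln <- dec$alignments[
        dec$alignments$query_id %in% names(kept$contigs)]
      gf <- genome_fraction(keep_aln, nchar(ref),
                            identity_min = config$identity_min)
      contig_stats <- nx_ngx(nchar(kept$contigs), nchar(ref))
      tq <- if (with_truth) {
        truth_quality(kept, sample_genomes, name)
      } else NULL
      path <- NA_character_
      if (!is.null(sp_dir) && length(kept$contigs)) {
        path <- file.path(sp_dir, "assembly_cleaned.fasta")
        write_fasta(kept$contigs, path)
        data.table::fwrite(dec$report,
                           file.path(sp_dir, "decontamination.tsv"),
                           sep = "\t")
      }
      list(contigs = contigs, dec = dec, kept = kept, gf = gf,
           stats = contig_stats, tq = tq, path = path)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$status <- paste0("failed: ", conditionMessage(res))
      n_failed <- n_failed + 1L
      manifest[[name]] <- row
      detail[[name]] <- list(read_set = rs, error = res)
      next
    }
    row$n_contigs <- length(res$contigs$contigs)
    row$n_kept <- length(res$kept$contigs)
    row$genome_fraction <- res$gf
    row$n50 <- res$stats[["n50"]]
    row$ng50 <- res$stats[["ng50"]]
    if (!is.null(res$tq)) {
      row$completeness <- res$tq$completeness
      row$contamination <- res$tq$contamination
      row$tier <- classify_quality(res$tq$completeness, res$tq$contamination)
    }
    row$assembly_path <- res$path
    manifest[[name]] <- row
    detail[[name]] <- c(list(read_set = rs), res)
  }
  manifest <- data.table::rbindlist(manifest)
  if (!is.null(out_dir)) {
    data.table::fwrite(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t")
    data.table::fwrite(refinement_report(read_sets),
                       file.path(out_dir, "refinement_report.tsv"),
                       sep = "\t")
  }
  out <- list(manifest = manifest, species = detail,
              classifications = classifications)
  attr(out, "n_failed") <- n_failed
  out
}
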