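#' Generate a complete synthetic cohort in one call
#'
#' Convenience wrapper: evolves the mtDNA lineage, builds the genomes,
#' plants NumtS and returns the cohort object. All randomness flows from
#' `config$seed`.
#'
#' @param tree A [species_tree()] (default [demo_tree()]).
#' @param samples Named list species -> sample IDs (default
#'   [demo_samples()]).
#' @param config A [sim_config()].
#' @param params A [plant_params()].
#' @param frame Frame species for cross-species coordinates.
#' @return A `numt_cohort`.
#' @export
simulate_cohort <- function(tree = demo_tree(), samples = demo_samples(),
                            config = sim_config(), params = plant_params(),
                            frame = "human") {
  root_seq <- with_seed(sub_seed(config$seed, 7L), random_dna(config$mt_length))
  lineage <- evolve_mt(tree, root_seq, config$mt_sub_rate,
                       seed = sub_seed(config$seed, 8L))
  genomes <- build_genomes(tree, config, frame = frame)
  plant_numts(genomes, lineage, samples, params = params)
}

#' Write a cohort to disk
#'
#' Emits, under `outdir`: per-species reference FASTA (`<sp>.fa`) and
#' mtDNA FASTA (`<sp>_MT.fa`); UCSC chain files `<sp>To<frame>.chain`
#' mapping species coordinates (target) to frame coordinates (query);
#' truth tables as JSON and BED6; and per-sample SAM alignments under
#' `sams/` when `sams = TRUE`.
#'
#' @param cohort A [plant_numts()] cohort.
#' @param outdir Output directory (created if needed).
#' @param sams Whether to simulate and write per-sample SAM files.
#' @return Invisibly, a named list of written paths.
#' @export
write_cohort <- function(cohort, outdir, sams = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  tips <- tree_species(cohort$tree)
  for (sp in tips) {
    fa <- file.path(outdir, paste0(sp, ".fa"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(unlist(cohort$ref_seq[[sp]])), fa)
    paths[[paste0("ref_", sp)]] <- fa
    mfa <- file.path(outdir, paste0(sp, "_MT.fa"))
    mt <- Biostrings::DNAStringSet(cohort$lineage$sequences[[sp]])
    names(mt) <- mt_contig_name(sp)
    Biostrings::writeXStringSet(mt, mfa)
    paths[[paste0("mt_", sp)]] <- mfa
    if (sp != cohort$frame) {
      cf <- file.path(outdir, paste0(sp, "To", cohort$frame, ".chain"))
      t_sizes <- vapply(cohort$ref_seq[[sp]], nchar, 0L)
      q_sizes <- vapply(cohort$ref_seq[[cohort$frame]], nchar, 0L)
      writeLines(chain_text(cohort$blocks[[sp]], t_sizes, q_sizes), cf)
      paths[[paste0("chain_", sp)]] <- cf
    }
  }
  tj <- file.path(outdir, "truth.json")
  jsonlite::write_json(list(truth = cohort$truth,
                            by_species = cohort$truth_by_species),
                       tj, digits = NA)
  paths$truth_json <- tj
  tb <- file.path(outdir, "truth.bed")
  bs <- cohort$truth_by_species
  utils::write.table(
    data.frame(bs$chrom, bs$ref_start, pmax(bs$ref_end, bs$ref_start + 1L),
               paste0(bs$numt_id, ":", bs$species), 0L, bs$strand),
    tb, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths$truth_bed <- tb
  if (sams) {
    sdir <- file.path(outdir, "sams")
    dir.create(sdir, showWarnings = FALSE)
    for (sm in sort(unlist(cohort$samples, use.names = FALSE))) {
      p <- file.path(sdir, paste0(sm, ".sam"))
      simulate_alignments(cohort, sm, p)
      paths[[paste0("sam_", sm)]] <- p
    }
  }
  invisible(paths)
}
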