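#' Simulation configuration for the synthetic cohort
#'
#' Bundles every tunable of the cohort generator. Defaults describe the
#' package's reference cohort: 5 Mb nuclear genomes, a 16.5 kb circular
#' mtDNA, 10x paired-end coverage with 100 bp reads and a 400 +/- 50 bp
#' insert size (typical of the moderate-coverage great-ape cohorts the
#' analysis is designed for), an mtDNA substitution rate of 0.01
#' substitutions/site/MY (the ~1e-8/site/year primate mtDNA clock), and a
#' uniform 0.1% per-base sequencing error.
#'
#' @param genome_length Total nuclear genome length in bp.
#' @param n_chroms Number of equally sized chromosomes.
#' @param mt_length Circular mtDNA length in bp.
#' @param coverage Nuclear fold coverage per sample.
#' @param mt_coverage Fold coverage of the mtDNA contig per sample
#'   (mtDNA is at high copy number, so this exceeds nuclear coverage).
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Fragment (insert) size model in bp;
#'   `insert_mean` must exceed `2 * read_length`.
#' @param mt_sub_rate mtDNA substitutions per site per MY.
#' @param nuclear_indel_rate Per-bp rate of small indels distinguishing a
#'   species genome from the frame genome (drives chain-file structure).
#' @param error_rate Uniform per-base sequencing error probability.
#' @param mt_snps_per_sample Private mtDNA SNPs per sample (individual
#'   mtDNA variation the consensus builder must recover).
#' @param min_anchor Minimum aligned bases for a junction-spanning read to
#'   be emitted as mapped (idealized aligner behaviour).
#' @param seed Integer master seed; fixed seed implies byte-identical
#'   FASTA/SAM/chain/truth outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 5e6,
                       n_chroms = 1L,
                       mt_length = 16500L,
                       coverage = 10,
                       mt_coverage = 30,
                       read_length = 100L,
                       insert_mean = 400,
                       insert_sd = 50,
                       mt_sub_rate = 0.01,
                       nuclear_indel_rate = 2e-6,
                       error_rate = 0.001,
                       mt_snps_per_sample = 3L,
                       min_anchor = 20L,
                       seed = 1L) {
  stopifnot(insert_mean > 2 * read_length, coverage > 0, mt_length >= 1000)
  cfg <- list(
    genome_length = as.numeric(genome_length), n_chroms = as.integer(n_chroms),
    mt_length = as.integer(mt_length), coverage = coverage,
    mt_coverage = mt_coverage, read_length = as.integer(read_length),
    insert_mean = insert_mean, insert_sd = insert_sd,
    mt_sub_rate = mt_sub_rate, nuclear_indel_rate = nuclear_indel_rate,
    error_rate = error_rate, mt_snps_per_sample = as.integer(mt_snps_per_sample),
    min_anchor = as.integer(min_anchor), seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Demo species tree: human frame, one great ape, one old-world monkey
#'
#' Divergence times follow the primate consensus: 6 MY for the
#' human-chimpanzee split and 25 MY for the catarrhine (macaque) split.
#' @return A [species_tree()].
#' @export
demo_tree <- function() {
  species_tree("((human:6,chimp:6)hominini:19,macaque:25)catarrhini;")
}

#' Default sample layout for the demo cohort (3 samples in each of the two
#' non-frame species).
#' @return Named list: species -> character vector of sample IDs.
#' @export
demo_samples <- function() {
  list(chimp = paste0("chimp", 1:3), macaque = paste0("macaque", 1:3))
}
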