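# mtDNA consensus building and reference augmentation.

# hand-rolled SAM emitter for tiny deterministic read sets
write_tiny_sam <- function(path, contig, contig_len, reads) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len))
  body <- vapply(seq_along(reads$pos), function(i) {
    paste(sprintf("r%03d", i), 0L, contig, reads$pos[i], 60L,
          paste0(nchar(reads$seq[i]), "M"), "*", 0L, 0L, reads$seq[i],
          strrep("I", nchar(reads$seq[i])), sep = "\t")
  }, "")
  writeLines(c(hdr, body), path)
}

tile_reads <- function(seq, rl = 100L, step = 25L) {
  starts <- seq(1L, nchar(seq) - rl + 1L, by = step)
  list(pos = starts, seq = substring(seq, starts, starts + rl - 1L))
}

test_that("variant-free reads reproduce the reference in one iteration", {
  ref <- with_seed(10, rdna(2000))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_tiny_sam(sam, "MT", 2000L, tile_reads(ref))
  cons <- build_consensus_mt(sam, ref, "MT")
  expect_identical(cons$sequence, ref)
  expect_equal(cons$n_iterations, 1L)
  expect_false(cons$low_confidence)
})

test_that("a uniformly carried SNP flips exactly its own position", {
  ref <- with_seed(11, rdna(2000))
  alt <- ref
  substr(alt, 500, 500) <- if (substr(ref, 500, 500) == "A") "C" else "A"
  sam <- withr::local_tempfile(fileext = ".sam")
  write_tiny_sam(sam, "MT", 2000L, tile_reads(alt))
  cons <- build_consensus_mt(sam, ref, "MT")
  expect_equal(numtforge:::str_mismatches(cons$sequence, ref), 1L)
  expect_identical(substr(cons$sequence, 500, 500), substr(alt, 500, 500))
})

test_that("thirty seeded sample SNPs are recovered without false calls", {
  tr <- demo_tree()
  cfg <- sim_config(genome_length = 5e4, mt_snps_per_sample = 30L,
                    seed = 21)
  lin <- evolve_mt(tr, with_seed(1, rdna(16500)), 0.01, seed = 2)
  g <- build_genomes(tr, cfg)
  co <- plant_numts(g, lin, list(chimp = "c1"),
                    plant_params(n_poly_per_species = 0L,
                                 n_fixed_per_species = 0L,
                                 n_fixed_frame = 0L, n_ancestral = 0L))
  sam <- withr::local_tempfile(fileext = ".sam")
  simulate_alignments(co, "c1", sam)
  cons <- build_consensus_mt(sam, lin$sequences[["chimp"]], "chimp_MT")
  truth <- sample_mt_sequence(co, "c1")
  expect_identical(cons$sequence, truth)
})

test_that("zero coverage over half the contig warns and keeps the reference", {
  ref <- with_seed(12, rdna(2000))
  sam <- withr::local_tempfile(fileext = ".sam")
  rd <- tile_reads(substr(ref, 1, 500))
  write_tiny_sam(sam, "MT", 2000L, rd)
  expect_warning(cons <- build_consensus_mt(sam, ref, "MT"),
                 "zero coverage")
  expect_true(cons$low_confidence)
  expect_identical(substr(cons$sequence, 501, 2000),
                   substr(ref, 501, 2000))
  # no reads at all is an error
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:MT\tLN:2000"),
             sam2 <- withr::local_tempfile(fileext = ".sam"))
  expect_error(build_consensus_mt(sam2, ref, "MT"), "no aligned reads")
})

test_that("augmenting a reference is reversible and rejects name clashes", {
  dir <- withr::local_tempdir()
  ref_fa <- file.path(dir, "ref.fa")
  refs <- Biostrings::DNAStringSet(c(chr1 = rdna(3000), chr2 = rdna(1000)))
  Biostrings::writeXStringSet(refs, ref_fa)
  cons <- rdna(2000)
  out <- file.path(dir, "aug.fa")
  augment_reference(ref_fa, cons, "sample_MT", out)
  aug <- Biostrings::readDNAStringSet(out)
  expect_equal(names(aug), c("chr1", "chr2", "sample_MT"))
  expect_identical(as.character(aug[["chr1"]]), as.character(refs[["chr1"]]))
  expect_identical(as.character(aug[["sample_MT"]]), cons)
  # strip the added contig -> byte-identical to the input
  back <- file.path(dir, "back.fa")
  Biostrings::writeXStringSet(aug[1:2], back)
  expect_identical(unname(tools::md5sum(back)),
                   unname(tools::md5sum(ref_fa)))
  expect_error(augment_reference(out, cons, "sample_MT", out),
               "already present")
})
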