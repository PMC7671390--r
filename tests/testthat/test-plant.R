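make_lineage <- function(seed = 2) {
  tr <- demo_tree()
  lin <- evolve_mt(tr, with_seed(1, rdna(16500)), 0.01, seed = seed)
  cfg <- sim_config(genome_length = 2e5, seed = seed)
  list(tr = tr, lin = lin, g = build_genomes(tr, cfg))
}

plant_one <- function(fx, age, mt_start = 2000L, mt_end = 2500L,
                      strand = "+", branch = "chimp",
                      status = "polymorphic", carriers = "chimp1") {
  d <- data.frame(branch = branch, status = status, chrom = "chr1",
                  base_pos = 50000L, mt_start = mt_start, mt_end = mt_end,
                  strand = strand, age = age, carriers = carriers,
                  stringsAsFactors = FALSE)
  plant_numts(fx$g, fx$lin, list(chimp = c("chimp1", "chimp2")),
              directives = d)
}

test_that("a zero-age Numt copies the present-day consensus segment", {
  fx <- make_lineage()
  co <- plant_one(fx, age = 0)
  expect_identical(co$truth$seq,
                   circ_extract(fx$lin$sequences[["chimp"]], 2000L, 2500L))
})

test_that("a divergence-age Numt copies the ancestral node segment", {
  fx <- make_lineage()
  co <- plant_one(fx, age = 6)
  expect_identical(co$truth$seq,
                   circ_extract(fx$lin$sequences[["hominini"]], 2000L,
                                2500L))
})

test_that("origin-wrapping segments have circular length and sequence", {
  fx <- make_lineage()
  co <- plant_one(fx, age = 0, mt_start = 16000L, mt_end = 300L)
  expect_equal(co$truth$length, 800L)
  cons <- fx$lin$sequences[["chimp"]]
  expect_identical(co$truth$seq,
                   paste0(substr(cons, 16001, 16500), substr(cons, 1, 300)))
  # minus strand flips the copied segment
  co2 <- plant_one(fx, age = 0, mt_start = 16000L, mt_end = 300L,
                   strand = "-")
  expect_identical(co2$truth$seq, revcomp(co$truth$seq))
})

test_that("planting rejects invalid ages, carriers and colliding loci", {
  fx <- make_lineage()
  expect_error(plant_one(fx, age = 7), "outside the span")
  expect_error(plant_one(fx, age = 1, carriers = "gorilla1"),
               "unknown carriers")
  d <- data.frame(branch = "chimp", status = "polymorphic", chrom = "chr1",
                  base_pos = c(50000L, 50200L), mt_start = 100L,
                  mt_end = 700L, strand = "+", age = 1,
                  carriers = "chimp1", stringsAsFactors = FALSE)
  expect_error(plant_numts(fx$g, fx$lin, list(chimp = "chimp1"),
                           directives = d),
               "inside or too near")
})

test_that("cohort truth conserves counts, carriers and fixed semantics", {
  co <- small_cohort()$cohort
  p <- co$params
  expect_equal(sum(co$truth$status == "polymorphic"),
               2L * p$n_poly_per_species)
  expect_equal(sum(co$truth$status == "fixed"),
               2L * p$n_fixed_per_species + p$n_fixed_frame +
                 p$n_ancestral)
  all_samples <- unlist(co$samples, use.names = FALSE)
  for (i in seq_len(nrow(co$truth_by_species))) {
    row <- co$truth_by_species[i, ]
    carr <- strsplit(row$carriers, ",")[[1]]
    expect_true(all(carr %in% all_samples) || row$species == "human")
    if (row$status == "fixed" && row$species %in% names(co$samples)) {
      expect_setequal(carr, co$samples[[row$species]])
    }
    if (row$status == "polymorphic") expect_gte(length(carr), 1L)
  }
  # fixed NumtS are materialized in the reference sequence
  tb <- chimp_truth("fixed")
  ref <- co$ref_seq$chimp$chr1
  for (i in seq_len(nrow(tb))) {
    planted <- co$truth$seq[co$truth$numt_id == tb$numt_id[i]]
    expect_identical(substr(ref, tb$ref_start[i] + 1L, tb$ref_end[i]),
                     planted)
  }
})
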