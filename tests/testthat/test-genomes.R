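# Coordinate bookkeeping: event maps, chain emission, liftover identity.

ev <- function(...) {
  rbind(numtforge:::empty_events(), data.frame(..., stringsAsFactors = FALSE))
}

test_that("a zero indel rate yields single-block identity chains", {
  tr <- demo_tree()
  cfg <- sim_config(genome_length = 1e5, nuclear_indel_rate = 0, seed = 3)
  g <- build_genomes(tr, cfg)
  lin <- evolve_mt(tr, with_seed(1, rdna(16500)), 0.01, seed = 2)
  co <- plant_numts(g, lin, demo_samples(),
                    plant_params(n_poly_per_species = 2L,
                                 n_fixed_per_species = 0L,
                                 n_fixed_frame = 0L, n_ancestral = 0L))
  bl <- co$blocks$chimp$chr1
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$size, 1e5)
  dir <- withr::local_tempdir()
  write_cohort(co, dir, sams = FALSE)
  ch <- read_chain(file.path(dir, "chimpTohuman.chain"))
  x <- data.frame(chrom = "chr1", start = c(0L, 500L, 99990L),
                  end = c(10L, 600L, 100000L))
  lo <- liftover_intervals(x, ch)
  expect_equal(lo$status, rep("mapped", 3))
  expect_equal(lo$h_start, x$start)
  expect_equal(lo$h_end, x$end)
})

test_that("a deletion shifts downstream species coordinates by its length", {
  # species lacks 10 bases at base position 1000; species coordinate 2000
  # is base (and frame) coordinate 2010
  events_s <- ev(chrom = "chr1", base_pos = 1000L, ins_len = 0L,
                 del_len = 10L, seq = "", id = NA_character_)
  events_f <- numtforge:::empty_events()
  bl <- numtforge:::chain_blocks(events_s, events_f, 10000L)
  expect_equal(nrow(bl), 2L)
  expect_equal(bl$size, c(1000L, 8990L))
  expect_equal(bl$t_start, c(0L, 1000L))
  expect_equal(bl$q_start, c(0L, 1010L))
  # map through: species coord 2000 sits in block 2
  expect_equal(bl$q_start[2] + (2000L - bl$t_start[2]), 2010L)
  g <- numtforge:::map_base_to_genome(c(999L, 1005L, 2010L), events_s)
  expect_equal(g, c(999L, NA, 2000L))
})

test_that("species -> frame -> species round trip is exact on a toy genome", {
  events_s <- ev(chrom = "chr1",
                 base_pos = c(1000L, 3000L, 6000L),
                 ins_len = c(50L, 0L, 7L),
                 del_len = c(0L, 30L, 0L),
                 seq = c(strrep("A", 50), "", "CCCCCCC"),
                 id = NA_character_)
  events_f <- numtforge:::empty_events()
  base_len <- 10000L
  bl <- numtforge:::chain_blocks(events_s, events_f, base_len)
  s_len <- numtforge:::genome_length_after(base_len, events_s)
  to_frame <- rep(NA_integer_, s_len)
  for (k in seq_len(nrow(bl))) {
    idx <- bl$t_start[k] + seq_len(bl$size[k])
    to_frame[idx] <- bl$q_start[k] + seq_len(bl$size[k]) - 1L
  }
  # every frame base reached at most once, and the reverse map returns the
  # original species coordinate for all aligned bases
  mapped <- to_frame[!is.na(to_frame)]
  expect_false(any(duplicated(mapped)))
  back <- rep(NA_integer_, base_len)
  back[mapped + 1L] <- which(!is.na(to_frame)) - 1L
  for (k in seq_len(nrow(bl))) {
    idx <- bl$t_start[k] + seq_len(bl$size[k]) - 1L
    expect_equal(back[to_frame[idx + 1L] + 1L], idx)
  }
})

test_that("shared insertions become aligned blocks, private ones gaps", {
  id <- "N001"
  numt <- ev(chrom = "chr1", base_pos = 5000L, ins_len = 300L, del_len = 0L,
             seq = strrep("G", 300), id = id)
  bl_shared <- numtforge:::chain_blocks(numt, numt, 10000L)
  expect_equal(nrow(bl_shared), 1L)   # fully colinear
  expect_equal(bl_shared$size, 10300L)
  bl_private <- numtforge:::chain_blocks(numt, numtforge:::empty_events(),
                                         10000L)
  expect_equal(nrow(bl_private), 2L)
  expect_equal(bl_private$t_start, c(0L, 5300L))
  expect_equal(bl_private$q_start, c(0L, 5000L))
})

test_that("planted fixed loci lift onto their recorded frame coordinates", {
  fx <- small_cohort()
  co <- fx$cohort
  dir <- withr::local_tempdir()
  write_cohort(co, dir, sams = FALSE)
  for (sp in c("chimp", "macaque")) {
    tb <- co$truth_by_species
    tb <- tb[tb$species == sp & tb$status == "fixed", , drop = FALSE]
    ch <- read_chain(file.path(dir, paste0(sp, "Tohuman.chain")))
    # lift the base immediately left of each insertion
    x <- data.frame(chrom = tb$chrom, start = tb$ref_start - 1L,
                    end = tb$ref_start)
    lo <- liftover_intervals(x, ch)
    expect_true(all(lo$status == "mapped"))
    expect_equal(lo$h_end, tb$human_start)
  }
})
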