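# Chain parsing and interval liftover semantics.

write_chain_file <- function(path, chains) {
  writeLines(unlist(lapply(chains, function(x) c(x, ""))), path)
}

test_that("identity chains map intervals unchanged", {
  p <- withr::local_tempfile(fileext = ".chain")
  write_chain_file(p, list(c(
    "chain 1000 chr1 10000 + 0 10000 chr1 10000 + 0 10000 1", "10000")))
  ch <- read_chain(p)
  x <- data.frame(chrom = "chr1", start = c(0L, 1234L), end = c(100L, 5678L))
  lo <- liftover_intervals(x, ch)
  expect_equal(lo$status, c("mapped", "mapped"))
  expect_equal(lo$h_start, x$start)
  expect_equal(lo$h_end, x$end)
})

test_that("a target gap shifts downstream intervals by its width", {
  p <- withr::local_tempfile(fileext = ".chain")
  # 10 bases of the query (frame) are absent from the target before 1000
  write_chain_file(p, list(c(
    "chain 900 chr1 9990 + 0 9990 chr1 10000 + 0 10000 1",
    "1000 0 10", "8990")))
  ch <- read_chain(p)
  lo <- liftover_intervals(data.frame(chrom = "chr1", start = 2000L,
                                      end = 2100L), ch)
  expect_equal(lo$status, "mapped")
  expect_equal(lo$h_start, 2010L)
  expect_equal(lo$h_end, 2110L)
})

test_that("coverage below the ratio floor fails as unmapped", {
  p <- withr::local_tempfile(fileext = ".chain")
  write_chain_file(p, list(c(
    "chain 900 chr1 10000 + 0 10000 chr1 9900 + 0 9900 1",
    "1000 100 0", "8900")))
  ch <- read_chain(p)
  # interval half inside the 100 bp unaligned target stretch
  lo <- liftover_intervals(data.frame(chrom = "chr1", start = 1050L,
                                      end = 1150L), ch)
  expect_equal(lo$status, "unmapped")
  lo2 <- liftover_intervals(data.frame(chrom = "chr1", start = 1050L,
                                       end = 1150L), ch,
                            min_map_ratio = 0.4)
  expect_equal(lo2$status, "mapped")
})

test_that("pieces on different chromosomes classify as split", {
  p <- withr::local_tempfile(fileext = ".chain")
  write_chain_file(p, list(
    c("chain 500 chr1 10000 + 0 500 chrA 5000 + 0 500 1", "500"),
    c("chain 500 chr1 10000 + 500 1000 chrB 5000 + 0 500 2", "500")))
  ch <- read_chain(p)
  lo <- liftover_intervals(data.frame(chrom = "chr1", start = 400L,
                                      end = 600L), ch)
  expect_equal(lo$status, "split")
})

test_that("malformed chains are rejected with a line number", {
  p <- withr::local_tempfile(fileext = ".chain")
  writeLines(c("chain 100 chr1 1000 + 0 100 chr1 1000 + 0 100 1",
               "50 x 0", "50"), p)
  expect_error(read_chain(p), "line 2")
  writeLines(c("chain 100 chr1 1000 + 0 100 chr1 1000 + 0 120 1",
               "100"), p)
  expect_error(read_chain(p), "do not match the header")
})

test_that("interval liftover equals the per-base oracle on cohort chains", {
  fx <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(fx$cohort, dir, sams = FALSE)
  for (sp in c("chimp", "macaque")) {
    path <- file.path(dir, paste0(sp, "Tohuman.chain"))
    blocks <- oracle_chain_blocks(path)
    ch <- read_chain(path)
    L <- nchar(fx$cohort$ref_seq[[sp]]$chr1)
    set.seed(17)
    n <- 200
    s <- sample.int(L - 3000L, n)
    w <- sample.int(2000L, n)
    x <- data.frame(chrom = "chr1", start = s, end = s + w)
    lo <- liftover_intervals(x, ch)
    for (i in seq_len(n)) {
      o <- oracle_liftover(blocks, "chr1", x$start[i], x$end[i])
      expect_identical(lo$status[i], o$status)
      if (o$status == "mapped") {
        expect_identical(lo$h_start[i], o$lo)
        expect_identical(lo$h_end[i], o$hi)
      }
    }
  }
})
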