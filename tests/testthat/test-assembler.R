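# Greedy overlap-consensus assembly and annotation.

test_that("two reads with an exact 30 bp overlap merge into one contig", {
  s <- with_seed(42, rdna(170))
  reads <- c(r1 = substr(s, 1, 100), r2 = substr(s, 71, 170))
  ctg <- assemble_reads(reads)
  expect_length(ctg, 1L)
  expect_identical(ctg[[1]]$seq, s)
  expect_equal(ctg[[1]]$n_reads, 2L)
})

test_that("reads without admissible overlaps stay singletons", {
  reads <- c(a = rdna(100), b = rdna(100), c = rdna(100))
  ctg <- assemble_reads(reads)
  expect_length(ctg, 3L)
  expect_setequal(vapply(ctg, function(x) x$seq, ""), unname(reads))
})

test_that("error-free tiling reads reassemble the planted sequence exactly", {
  flank_l <- with_seed(1, rdna(150))
  numt <- with_seed(2, rdna(300))
  flank_r <- with_seed(3, rdna(150))
  s <- paste0(flank_l, numt, flank_r)
  starts <- seq(1, nchar(s) - 99, by = 20)
  reads <- setNames(substring(s, starts, starts + 99),
                    sprintf("t%03d", seq_along(starts)))
  ctg <- assemble_reads(reads)
  expect_length(ctg, 1L)
  expect_identical(ctg[[1]]$seq, s)
})

test_that("assembly output is invariant under read-order permutation", {
  s <- with_seed(5, rdna(400))
  starts <- seq(1, 301, by = 30)
  reads <- setNames(substring(s, starts, starts + 99),
                    sprintf("t%03d", seq_along(starts)))
  a <- assemble_reads(reads)
  b <- assemble_reads(with_seed(9, sample(reads)))
  expect_identical(lapply(a, `[[`, "seq"), lapply(b, `[[`, "seq"))
})

test_that("read pooling deduplicates identical reads across carrier files", {
  fx <- small_cohort()
  cl <- small_cohort_calls()
  # a call carried by chimp1, whose SAM we alias under three sample names
  idx <- which(grepl("chimp1", cl$merged$carriers))[1]
  call <- cl$merged[idx, ]
  call$carriers <- "s1,s2,s3"
  sams <- setNames(rep(fx$sams[["chimp1"]], 3), c("s1", "s2", "s3"))
  reads <- extract_reads(sams, call, "chimp_MT")
  expect_false(any(duplicated(names(reads))))
  call1 <- cl$merged[idx, ]
  call1$carriers <- "s1"
  once <- extract_reads(sams["s1"], call1, "chimp_MT")
  expect_equal(length(reads), length(once))
  expect_gt(length(once), 0L)
  # a missing carrier file is skipped with a warning
  call2 <- cl$merged[idx, ]
  call2$carriers <- "s1,ghost"
  expect_warning(extract_reads(sams["s1"], call2, "chimp_MT"),
                 "no alignment file")
})

test_that("annotation recovers exact, wrapped and reverse segments", {
  mt <- with_seed(7, rdna(16500))
  ref <- with_seed(8, rdna(4000))
  call <- data.frame(chrom = "chr1", pos = 2000L)
  a <- annotate_contig(substr(mt, 1001, 1400), mt, ref, call)
  expect_equal(a$mt_start, 1000L)
  expect_equal(a$mt_end, 1400L)
  expect_equal(a$strand, "+")
  expect_equal(a$identity, 100)
  w <- annotate_contig(paste0(substr(mt, 16401, 16500),
                              substr(mt, 1, 200)), mt, ref, call)
  expect_equal(w$mt_start, 16400L)
  expect_equal(w$mt_end, 200L)
  expect_equal(circ_length(w$mt_start, w$mt_end, 16500L), 300L)
  r <- annotate_contig(revcomp(substr(mt, 1001, 1400)), mt, ref, call)
  expect_equal(r$mt_start, 1000L)
  expect_equal(r$mt_end, 1400L)
  expect_equal(r$strand, "-")
  # a random contig is flagged non-mt
  n <- annotate_contig(rdna(400), mt, ref, call)
  expect_false(n$is_mt)
})

test_that("full contigs classify by junction flanks and estimate lengths", {
  mt <- with_seed(17, rdna(16500))
  ref <- with_seed(18, rdna(10000))
  pos <- 5000L
  numt <- substr(mt, 3001, 3400)
  call <- data.frame(chrom = "chr1", pos = pos)
  full <- paste0(substr(ref, pos - 79, pos), numt,
                 substr(ref, pos + 1, pos + 80))
  a <- annotate_call(list(list(seq = full)), mt, ref, call)
  expect_equal(a$completeness, "full")
  # local alignment may extend a base or two into a chance-matching flank
  expect_lte(abs(a$mt_start - 3000L), 2L)
  expect_lte(abs(a$mt_end - 3400L), 2L)
  expect_lte(abs(a$est_length - 400L), 4L)
  left <- paste0(substr(ref, pos - 79, pos), substr(mt, 3001, 3150))
  right <- paste0(substr(mt, 3251, 3400), substr(ref, pos + 1, pos + 80))
  b <- annotate_call(list(list(seq = left), list(seq = right)), mt, ref,
                     call)
  expect_equal(b$completeness, "partial-two-side")
  expect_lte(abs(b$est_length - 400L), 4L)
  c_ <- annotate_call(list(list(seq = left)), mt, ref, call)
  expect_equal(c_$completeness, "partial-one-side")
})
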