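# Discordant-pair clustering, thresholds, merging.

fake_signals <- function(n_pairs, pos = 10000L, mt_pos = 5000L,
                         n_clip = 0L, clip_pos = pos + 200L) {
  half <- ceiling(n_pairs / 2)
  disc <- data.frame(
    qname = sprintf("q%02d", seq_len(n_pairs)),
    chrom = "chr1",
    pos = c(pos - 300L - seq_len(half) * 10L,
            clip_pos + seq_len(n_pairs - half) * 10L),
    end = 0L, strand = rep(c("+", "-"), c(half, n_pairs - half)),
    mapq = 60L, mt_pos = mt_pos + seq_len(n_pairs),
    mt_strand = rep(c("-", "+"), c(half, n_pairs - half)),
    orientation = "+", stringsAsFactors = FALSE)
  disc$end <- disc$pos + 100L
  clip <- if (n_clip > 0L) {
    data.frame(qname = sprintf("c%02d", seq_len(n_clip)), chrom = "chr1",
               clip_pos = clip_pos, side = "right", seq = strrep("A", 20),
               mapq = 60L, stringsAsFactors = FALSE)
  } else {
    data.frame(qname = character(), chrom = character(),
               clip_pos = integer(), side = character(), seq = character(),
               mapq = integer(), stringsAsFactors = FALSE)
  }
  structure(list(discordant = disc, clipped = clip, mt_contig = "MT"),
            class = "numt_signals")
}

test_that("the support threshold is a hard floor", {
  expect_equal(nrow(cluster_and_call(fake_signals(3), min_support = 4L)), 0L)
  calls <- cluster_and_call(fake_signals(4), min_support = 4L)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$filter, "PASS")
  # raising min_support never increases the number of calls
  n_calls <- vapply(2:8, function(ms) {
    nrow(cluster_and_call(fake_signals(6), min_support = ms))
  }, 0L)
  expect_true(all(diff(n_calls) <= 0L))
})

test_that("breakpoints come from modal clips, else innermost mates", {
  calls <- cluster_and_call(fake_signals(6, n_clip = 5L,
                                         clip_pos = 10123L))
  expect_equal(calls$pos, 10123L)
  expect_true(calls$ci_lo <= calls$pos & calls$pos <= calls$ci_hi)
  no_clip <- cluster_and_call(fake_signals(6))
  fwd_inner <- max(no_clip$ci_lo)
  expect_true(no_clip$pos >= no_clip$ci_lo & no_clip$pos <= no_clip$ci_hi)
})

test_that("collect_signals rejects a missing mt contig and ignores decoys", {
  fx <- small_cohort()
  expect_error(collect_signals(fx$sams[["chimp1"]], "gorilla_MT"),
               "not in the SAM header")
  # clipped tails that do not match the mtDNA are filtered out
  sig_all <- collect_signals(fx$sams[["chimp1"]], "chimp_MT")
  decoy <- rdna(16500)
  sig_decoy <- collect_signals(fx$sams[["chimp1"]], "chimp_MT",
                               mt_seq = decoy)
  sig_mt <- collect_signals(fx$sams[["chimp1"]], "chimp_MT",
                            mt_seq = fx$lin$sequences[["chimp"]])
  expect_equal(nrow(sig_decoy$clipped), 0L)
  expect_gt(nrow(sig_mt$clipped), 0L)
  expect_lte(nrow(sig_mt$clipped), nrow(sig_all$clipped))
})

test_that("well-separated NumtS give separate exact calls per sample", {
  fx <- small_cohort()
  co <- fx$cohort
  calls <- call_numts(fx$sams[["chimp1"]], "chimp_MT", "chimp1",
                      mt_seq = fx$lin$sequences[["chimp"]])
  ins <- sample_insertions(co, "chimp1")
  expect_equal(nrow(calls), nrow(ins))
  expect_equal(calls$pos, ins$ref_pos)
  expect_equal(calls$orientation, ins$strand)
  expect_true(all(calls$chrom != "chimp_MT"))
})

test_that("calls are invariant to SAM record order", {
  fx <- small_cohort()
  lines <- readLines(fx$sams[["chimp1"]])
  hdr <- grepl("^@", lines)
  shuf <- withr::local_tempfile(fileext = ".sam")
  set.seed(1)
  writeLines(c(lines[hdr], sample(lines[!hdr])), shuf)
  a <- call_numts(fx$sams[["chimp1"]], "chimp_MT", "chimp1",
                  mt_seq = fx$lin$sequences[["chimp"]])
  b <- call_numts(shuf, "chimp_MT", "chimp1",
                  mt_seq = fx$lin$sequences[["chimp"]])
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("sample merging unions carriers within the window only", {
  mk <- function(pos, sample) {
    calls <- cluster_and_call(fake_signals(5, pos = pos), sample = sample)
    calls
  }
  five <- setNames(lapply(1:5, function(i) mk(10000L, paste0("s", i))),
                   paste0("s", 1:5))
  merged <- merge_samples(five)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_samples, 5L)
  expect_setequal(strsplit(merged$carriers, ",")[[1]], paste0("s", 1:5))
  # breakpoints 501+ bp apart stay distinct
  far <- list(s1 = mk(10000L, "s1"), s2 = mk(10000L + 501L + 340L, "s2"))
  expect_equal(nrow(merge_samples(far, window = 500L)), 2L)
  near <- list(s1 = mk(10000L, "s1"), s2 = mk(10300L, "s2"))
  expect_equal(nrow(merge_samples(near, window = 500L)), 1L)
})

test_that("species-level merging recovers the planted polymorphic set", {
  cl <- small_cohort_calls()
  truth <- chimp_truth("polymorphic")
  merged <- cl$merged
  expect_equal(nrow(merged), nrow(truth))
  o <- order(truth$ref_start)
  expect_equal(merged$pos, truth$ref_start[o])
  # carriers equal the planted carrier sets
  expect_equal(merged$carriers,
               vapply(strsplit(truth$carriers[o], ","), function(x) {
                 paste(sort(x), collapse = ",")
               }, ""))
})
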