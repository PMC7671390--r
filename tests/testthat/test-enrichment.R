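# Complete-gene counts, permutation null, Z-scores.

test_that("whole-mtDNA segments contain every gene; half-covered genes count zero", {
  genes <- mt_gene_table(make_mt_genes(16500, 12, seed = 2), 16500)
  full <- data.frame(mt_start = 0L, mt_end = 16500L)
  cnt <- complete_gene_counts(full, genes, 16500)
  expect_true(all(cnt == 1L))
  g1 <- genes[2, ]
  half <- data.frame(mt_start = g1$start,
                     mt_end = (g1$start + g1$length %/% 2) %% 16500L)
  cnt2 <- complete_gene_counts(half, genes, 16500)
  expect_equal(unname(cnt2[g1$name]), 0L)
})

test_that("circular containment equals the brute-force position-set oracle", {
  set.seed(31)
  mt_len <- 2000L
  genes <- mt_gene_table(
    data.frame(name = paste0("G", 1:6),
               start = c(0L, 300L, 700L, 1100L, 1500L, 1900L),
               end = c(200L, 600L, 1000L, 1400L, 1800L, 80L)), mt_len)
  segs <- data.frame(mt_start = sample.int(mt_len, 200L) - 1L,
                     mt_end = sample.int(mt_len, 200L) - 1L)
  segs <- segs[segs$mt_start != segs$mt_end, ]
  cnt <- complete_gene_counts(segs, genes, mt_len)
  for (k in seq_len(nrow(genes))) {
    brute <- sum(vapply(seq_len(nrow(segs)), function(i) {
      oracle_contains(segs$mt_start[i], segs$mt_end[i],
                      genes$start[k], genes$end[k], mt_len)
    }, TRUE))
    expect_equal(unname(cnt[k]), brute)
  }
})

test_that("degenerate null placements behave as analysed", {
  genes <- mt_gene_table(make_mt_genes(16500, 10, seed = 5), 16500)
  # a full-length fragment covers every gene in every set
  null_full <- permute_null(16500, genes, 16500, n_sets = 20, seed = 1)
  expect_true(all(null_full == 1L))
  # a fragment shorter than every gene never contains one
  shortest <- min(genes$length)
  null_short <- permute_null(shortest - 1L, genes, 16500, n_sets = 20,
                             seed = 1)
  expect_true(all(null_short == 0L))
  expect_error(permute_null(0, genes, 16500), "lengths > 0")
})

test_that("null means match the closed-form placement probability", {
  mt_len <- 16500L
  genes <- mt_gene_table(make_mt_genes(mt_len, 8, seed = 7), mt_len)
  L <- 6000L   # longer than every gene, as the closed form requires
  n_sets <- 3000L
  null <- permute_null(L, genes, mt_len, n_sets = n_sets, seed = 13)
  for (k in seq_len(nrow(genes))) {
    G <- genes$length[k]
    p <- (L - G + 1) / mt_len
    mc_sigma <- sqrt(p * (1 - p) / n_sets)
    expect_lt(abs(mean(null[k, ]) - p), 3 * mc_sigma + 1e-9)
  }
})

test_that("z-scores follow the definition and classify at |z| = 1", {
  null <- matrix(c(rep(4, 10), rep(2, 10)), nrow = 2, byrow = TRUE)
  null[1, 1:5] <- 2; null[1, 6:10] <- 6   # mu 4, sd ~2.11
  obs <- c(g1 = 10L, g2 = 2L)
  z <- numt_zscores(obs, null)
  expect_equal(z$z[1], (10 - mean(null[1, ])) / sd(null[1, ]))
  expect_equal(z$class[1], "enriched")
  # zero-variance gene flagged neutral/degenerate
  expect_true(is.na(z$z[2]))
  expect_equal(z$class[2], "neutral")
  expect_true(z$degenerate[2])
  # x equal to the null mean is neutral at z = 0
  obs2 <- c(g1 = 4L, g2 = 2L)
  z2 <- numt_zscores(obs2, null)
  expect_equal(z2$z[1], 0)
  expect_equal(z2$class[1], "neutral")
})

test_that("seeded nulls reproduce and ignore gene order", {
  genes <- mt_gene_table(make_mt_genes(16500, 6, seed = 9), 16500)
  a <- permute_null(c(500, 1500, 3000), genes, 16500, n_sets = 50,
                    seed = 4)
  b <- permute_null(c(500, 1500, 3000), genes, 16500, n_sets = 50,
                    seed = 4)
  expect_identical(a, b)
  perm <- sample(nrow(genes))
  c_ <- permute_null(c(500, 1500, 3000), genes[perm, ], 16500, n_sets = 50,
                     seed = 4)
  expect_identical(a[genes$name[perm], ], c_)
})
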