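# Diagnostic-site profiles, allele-ratio dating, characterization.

lineage_fx <- function() {
  fixture("dating_lineage", function() {
    tr <- demo_tree()
    lin <- evolve_mt(tr, with_seed(61, rdna(16500)), 0.01, seed = 62)
    list(tr = tr, lin = lin,
         anc = lin$sequences[["hominini"]],
         cons = lin$sequences[["chimp"]])
  })
}

test_that("profiles list exactly the differing positions", {
  s <- with_seed(1, rdna(2000))
  expect_equal(nrow(build_profile(s, s, 6)), 0L)
  s2 <- s
  substr(s2, 101, 101) <- if (substr(s, 101, 101) == "A") "G" else "A"
  p <- build_profile(s, s2, 6)
  expect_equal(nrow(p), 1L)
  expect_equal(p$pos, 100L)
  expect_equal(p$ancestral, substr(s, 101, 101))
  expect_equal(p$derived, substr(s2, 101, 101))
  expect_error(build_profile(s, substr(s, 1, 1999), 6), "lengths differ")
})

test_that("profiles equal the recorded event list net of reversions", {
  fx <- lineage_fx()
  p <- build_profile(fx$anc, fx$cons, 6, "chimp")
  ev <- fx$lin$events
  ev <- ev[ev$node == "chimp", ]
  # positions hit once must all be diagnostic; multi-hit positions may
  # revert to the ancestral allele and drop out
  once <- as.integer(names(which(table(ev$pos) == 1L)))
  expect_true(all(once %in% p$pos))
  expect_true(all(p$pos %in% ev$pos))
})

test_that("boundary allele patterns date to 0 and T exactly", {
  fx <- lineage_fx()
  p <- build_profile(fx$anc, fx$cons, 6, "chimp")
  all_der <- date_numt(substr(fx$cons, 2001, 3500), fx$cons, p)
  expect_equal(all_der$age, 0)
  expect_equal(all_der$n_other, 0L)
  expect_true(all_der$qc_pass)
  all_anc <- date_numt(substr(fx$anc, 2001, 3500), fx$cons, p)
  expect_equal(all_anc$age, 6)
  # counts partition the covered sites
  mid <- date_numt(substr(mt_sequence_at(fx$lin, "chimp", 2.5), 2001, 3500),
                   fx$cons, p)
  expect_equal(mid$n_derived + mid$n_ancestral + mid$n_other,
               mid$n_covered)
  expect_true(mid$allele_ratio >= 0 && mid$allele_ratio <= 1)
  expect_true(mid$age >= 0 && mid$age <= 6)
})

test_that("the allele ratio is invariant under a strand flip", {
  fx <- lineage_fx()
  p <- build_profile(fx$anc, fx$cons, 6, "chimp")
  seg <- substr(mt_sequence_at(fx$lin, "chimp", 3.5), 5001, 6500)
  a <- date_numt(seg, fx$cons, p)
  b <- date_numt(revcomp(seg), fx$cons, p)
  expect_equal(a$allele_ratio, b$allele_ratio)
  expect_equal(a$age, b$age)
})

test_that("sparse segments fail QC; third alleles obey the chosen rule", {
  fx <- lineage_fx()
  p <- build_profile(fx$anc, fx$cons, 6, "chimp")
  tiny <- date_numt(substr(fx$cons, 1001, 1080), fx$cons, p, min_sites = 5)
  expect_false(isTRUE(tiny$qc_pass) && tiny$n_covered < 5)
  seg <- substr(fx$cons, 2001, 3500)
  # inject third alleles at two covered diagnostic sites
  covered <- p$pos[p$pos >= 2000 & p$pos < 3500][1:2]
  for (pos in covered) {
    cur <- substr(seg, pos - 2000 + 1, pos - 2000 + 1)
    third <- setdiff(c("A", "C", "G", "T"),
                     c(p$ancestral[p$pos == pos], p$derived[p$pos == pos]))
    substr(seg, pos - 2000 + 1, pos - 2000 + 1) <- third[1]
  }
  ex <- date_numt(seg, fx$cons, p, other_rule = "exclude")
  expect_equal(ex$n_other, 2L)
  expect_equal(ex$age, 0)   # remaining sites are all derived
  anc <- date_numt(seg, fx$cons, p, other_rule = "ancestral")
  expect_equal(anc$n_other, 0L)
  expect_gt(anc$age, 0)
})

test_that("increasing true age never decreases the median estimate", {
  fx <- lineage_fx()
  p <- build_profile(fx$anc, fx$cons, 6, "chimp")
  meds <- vapply(c(0.5, 2, 4, 5.5), function(a) {
    aged <- mt_sequence_at(fx$lin, "chimp", a)
    est <- vapply(seq(1, 14000, by = 2000), function(s) {
      date_numt(substr(aged, s, s + 1999), fx$cons, p)$age
    }, 0)
    median(est)
  }, 0)
  expect_true(all(diff(meds) >= -0.3))
})

test_that("rate histograms bin by MY and reject empty input", {
  ages <- data.frame(species = "chimp", age = c(0.1, 0.4, 0.9, NA))
  h <- insertion_rate_histogram(ages)
  expect_equal(nrow(h$histogram), 1L)
  expect_equal(h$histogram$count, 3L)
  expect_equal(h$n_undated, 1L)
  expect_error(insertion_rate_histogram(ages[0, ]), "no dated")
  expect_error(
    insertion_rate_histogram(data.frame(species = "x", age = NA_real_)),
    "no dated")
})

test_that("GC content follows the definition on planted sequences", {
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(gc_percent("ATAT"), 0)
  expect_equal(gc_percent("GGCCNN"), 100)  # ambiguity codes ignored
  co <- small_cohort()$cohort
  seqs <- setNames(co$truth$seq, co$truth$numt_id)
  chr <- characterize_numts(seqs, class = co$truth$status,
                            mt_seq = co$lineage$sequences[["chimp"]])
  direct <- vapply(strsplit(co$truth$seq, ""), function(x) {
    100 * sum(x %in% c("G", "C")) / length(x)
  }, 0)
  expect_equal(chr$table$gc, unname(direct), tolerance = 1e-12)
  expect_equal(chr$table$length, nchar(co$truth$seq))
})
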