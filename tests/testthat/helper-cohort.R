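# Shared fixtures: cohorts are expensive, so they are built once per test
# run and cached in this environment, keyed by their parameters.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

rdna <- function(n) numtforge:::random_dna(n)

# small two-species cohort (0.5 Mb) with SAMs for the chimp samples
small_cohort <- function() {
  fixture("small_cohort", function() {
    tr <- demo_tree()
    cfg <- sim_config(genome_length = 5e5, seed = 7)
    lin <- evolve_mt(tr, with_seed(1, rdna(16500)), 0.01, seed = 2)
    g <- build_genomes(tr, cfg)
    co <- plant_numts(g, lin, demo_samples())
    dir <- file.path(tempdir(), "numtforge_small")
    dir.create(dir, showWarnings = FALSE)
    sams <- character(0)
    for (sm in co$samples$chimp) {
      p <- file.path(dir, paste0(sm, ".sam"))
      if (!file.exists(p)) simulate_alignments(co, sm, p)
      sams[sm] <- p
    }
    list(tree = tr, cfg = cfg, lin = lin, cohort = co, dir = dir,
         sams = sams)
  })
}

small_cohort_calls <- function() {
  fixture("small_cohort_calls", function() {
    fx <- small_cohort()
    per <- lapply(names(fx$sams), function(sm) {
      call_numts(fx$sams[[sm]], "chimp_MT", sm,
                 mt_seq = fx$lin$sequences[["chimp"]])
    })
    names(per) <- names(fx$sams)
    list(per_sample = per, merged = merge_samples(per))
  })
}

chimp_truth <- function(status = "polymorphic") {
  tb <- small_cohort()$cohort$truth_by_species
  tb[tb$species == "chimp" & tb$status == status, , drop = FALSE]
}

# ---- independent oracles ---------------------------------------------

# parse a chain file into per-block coordinates (independent of the
# package's chain writer/reader pair)
oracle_chain_blocks <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i])) { i <- i + 1L; next }
    f <- strsplit(lines[i], "\\s+")[[1]]
    stopifnot(f[1] == "chain")
    t0 <- as.integer(f[6]); q0 <- as.integer(f[11]); ch <- f[3]
    repeat {
      i <- i + 1L
      b <- as.integer(strsplit(lines[i], "\\s+")[[1]])
      out[[length(out) + 1L]] <- data.frame(chrom = ch, t = t0, q = q0,
                                            size = b[1])
      if (length(b) == 1L) break
      t0 <- t0 + b[1] + b[2]; q0 <- q0 + b[1] + b[3]
    }
    i <- i + 1L
  }
  do.call(rbind, out)
}

# per-base species -> frame mapping from parsed chain blocks
oracle_base_map <- function(blocks, chrom, pos) {
  vapply(pos, function(p) {
    r <- blocks[blocks$chrom == chrom & blocks$t <= p &
                  p < blocks$t + blocks$size, , drop = FALSE]
    if (nrow(r) != 1L) NA_integer_ else r$q[1L] + (p - r$t[1L])
  }, integer(1))
}

# brute-force interval liftover with the package's documented semantics
oracle_liftover <- function(blocks, chrom, s, e, ratio = 0.95) {
  m <- oracle_base_map(blocks, chrom, s:(e - 1L))
  cov <- sum(!is.na(m))
  if (cov < ratio * (e - s)) return(list(status = "unmapped"))
  list(status = "mapped", lo = min(m, na.rm = TRUE),
       hi = max(m, na.rm = TRUE) + 1L)
}

# brute-force circular containment by explicit position sets
oracle_contains <- function(s, e, gs, ge, len) {
  seg <- if (e > s) s:(e - 1L) else c(s:(len - 1L), seq_len(e) - 1L)
  gene <- if (ge > gs) gs:(ge - 1L) else c(gs:(len - 1L), seq_len(ge) - 1L)
  all(gene %in% seg)
}

# percent identity of a contig against a reference sequence over the
# contig's best local alignment
contig_identity <- function(contig, target) {
  a <- Biostrings::pairwiseAlignment(contig, target, type = "local")
  p <- strsplit(as.character(Biostrings::alignedPattern(a)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(a)), "")[[1]]
  100 * sum(p == s) / length(p)
}

# reciprocal overlap of two circular segments
circ_reciprocal_overlap <- function(s1, e1, s2, e2, len) {
  pos <- function(s, e) {
    if (e > s) s:(e - 1L) else c(s:(len - 1L), seq_len(e) - 1L)
  }
  a <- pos(s1, e1); b <- pos(s2, e2)
  ov <- length(intersect(a, b))
  min(ov / length(a), ov / length(b))
}
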