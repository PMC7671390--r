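# Mitochondrial gene-level insertion bias: permutation null and Z-scores.

#' Read (or canonicalize) an mtDNA gene table
#'
#' Accepts a BED6 path or a data.frame with `name`, `start`, `end`
#' (0-based half-open; `end <= start` wraps the origin, as the D-loop
#' does). Overlapping genes are canonicalized by trimming each gene's
#' start to the end of the previous one (mtDNA genes overlap by a few bp
#' at ATP8/ATP6- and ND4L/ND4-style boundaries).
#'
#' @param genes BED path or data.frame.
#' @param mt_len mtDNA length (bp).
#' @return data.frame `name`, `start`, `end`, `length`, `is_trna`.
#' @export
mt_gene_table <- function(genes, mt_len) {
  if (is.character(genes) && length(genes) == 1L) {
    bed <- utils::read.table(genes, sep = "\t", stringsAsFactors = FALSE)
    genes <- data.frame(name = bed[[4L]], start = bed[[2L]], end = bed[[3L]],
                        stringsAsFactors = FALSE)
  }
  g <- genes
  g$length <- circ_length(g$start, g$end, mt_len)
  g$is_trna <- grepl("^(MT-)?T[A-Z]", g$name) & g$length < 100L
  # canonicalize small overlaps between linearly ordered genes
  o <- order(g$start)
  g <- g[o, , drop = FALSE]
  if (nrow(g) > 1L) {
    for (i in 2:nrow(g)) {
      prev_end <- g$end[i - 1L]
      if (g$end[i - 1L] > g$start[i] && g$start[i - 1L] < g$start[i]) {
        g$start[i] <- prev_end %% mt_len
      }
    }
  }
  g$length <- circ_length(g$start, g$end, mt_len)
  rownames(g) <- NULL
  g
}

#' Complete-gene insertion counts
#'
#' Counts, per mtDNA gene, the Numt segments that fully contain it
#' (circular containment: origin-wrapping segments and genes are
#' honoured).
#'
#' @param segments data.frame with `mt_start`, `mt_end` (0-based
#'   half-open circular).
#' @param genes A [mt_gene_table()].
#' @param mt_len mtDNA length.
#' @return Named integer vector of per-gene counts.
#' @export
complete_gene_counts <- function(segments, genes, mt_len) {
  counts <- stats::setNames(integer(nrow(genes)), genes$name)
  if (!nrow(segments)) return(counts)
  for (k in seq_len(nrow(genes))) {
    counts[k] <- sum(circ_contains(segments$mt_start, segments$mt_end,
                                   genes$start[k], genes$end[k], mt_len))
  }
  counts
}

#' Permutation null for complete-gene insertion counts
#'
#' Generates `n_sets` random placements of the observed fragment lengths
#' at independent uniform starts on the mtDNA circle (maximum-entropy
#' null: every coordinate equally likely, wrapping allowed) and counts
#' complete gene insertions per set.
#'
#' @param lengths Observed Numt fragment lengths (bp, each in
#'   `(0, mt_len]`).
#' @param genes A [mt_gene_table()].
#' @param mt_len mtDNA length.
#' @param n_sets Number of permutation sets.
#' @param seed Integer seed.
#' @return Integer matrix genes x sets.
#' @export
permute_null <- function(lengths, genes, mt_len, n_sets = 1000L, seed = 1L) {
  stopifnot(all(lengths > 0), all(lengths <= mt_len))
  nf <- length(lengths)
  null <- matrix(0L, nrow(genes), n_sets,
                 dimnames = list(genes$name, NULL))
  with_seed(seed, {
    starts <- matrix(floor(stats::runif(nf * n_sets, 0, mt_len)),
                     nrow = nf)
    for (k in seq_len(nrow(genes))) {
      gs <- genes$start[k]
      glen <- genes$length[k]
      # containment: ((gs - start) mod M) + glen <= fragment length; a
      # full-circle fragment contains every gene in any phase
      off <- (gs - starts) %% mt_len
      null[k, ] <- colSums(off + glen <= lengths | lengths == mt_len)
    }
  })
  null
}

#' Permutation Z-scores for gene insertion bias
#'
#' `z = (x - mu) / sigma` with `mu`/`sigma` the mean and SD of the
#' per-gene permutation counts; genes with `z >= 1` are classed enriched
#' and `z <= -1` depleted. Genes with zero permutation variance are
#' flagged neutral with `z = NA`.
#'
#' @param observed Named vector of observed per-gene counts.
#' @param null Matrix from [permute_null()] (genes x sets, >= 2 sets).
#' @return data.frame: `gene`, `x`, `mu`, `sigma`, `z`, `class`,
#'   `degenerate`.
#' @export
numt_zscores <- function(observed, null) {
  stopifnot(ncol(null) >= 2L, nrow(null) == length(observed))
  mu <- rowMeans(null)
  sigma <- apply(null, 1L, stats::sd)
  z <- ifelse(sigma > 0, (observed - mu) / sigma, NA_real_)
  cls <- ifelse(is.na(z), "neutral",
                ifelse(z >= 1, "enriched",
                       ifelse(z <= -1, "depleted", "neutral")))
  data.frame(gene = names(observed), x = as.integer(observed), mu = mu,
             sigma = sigma, z = z, class = cls, degenerate = sigma == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gene enrichment analysis for a set of annotated NumtS
#'
#' Convenience wrapper: observed complete-gene counts, permutation null
#' from the observed fragment lengths, Z-scores. tRNA genes are counted
#' but dropped from the report unless `include_trna`.
#'
#' @param segments data.frame with `mt_start`, `mt_end`.
#' @param genes Gene table or BED path.
#' @param mt_len mtDNA length.
#' @param n_sets Permutation sets.
#' @param seed Seed.
#' @param include_trna Keep tRNA genes in the report.
#' @return A [numt_zscores()] data.frame.
#' @export
gene_enrichment <- function(segments, genes, mt_len, n_sets = 1000L,
                            seed = 1L, include_trna = FALSE) {
  g <- mt_gene_table(genes, mt_len)
  obs <- complete_gene_counts(segments, g, mt_len)
  lens <- circ_length(segments$mt_start, segments$mt_end, mt_len)
  null <- permute_null(lens, g, mt_len, n_sets = n_sets, seed = seed)
  z <- numt_zscores(obs, null)
  if (!include_trna) z <- z[!g$is_trna, , drop = FALSE]
  rownames(z) <- NULL
  z
}
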