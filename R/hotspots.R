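# Cross-species insertion hotspots over fixed-width genome bins.

#' Per-species insertion frequencies over fixed-width genome bins
#'
#' Tiles the frame genome into `bin_width` bins with
#' [GenomicRanges::tileGenome()] (the last bin of a chromosome may be
#' short) and assigns every call to the bin containing its breakpoint.
#'
#' @param calls_by_species Named list: species -> data.frame with
#'   `h_chrom`, `h_pos` (frame coordinates; `NA` positions are dropped).
#' @param seqlengths Named vector of frame chromosome lengths.
#' @param bin_width Bin width in bp (25 Mb in the primate analysis).
#' @param drop_short Drop terminal bins shorter than `bin_width`.
#' @return Object of class `bin_table`: `bins` (data.frame chrom, start,
#'   end) and `counts` (bins x species matrix).
#' @export
bin_frequencies <- function(calls_by_species, seqlengths,
                            bin_width = 25e6, drop_short = FALSE) {
  tiles <- GenomicRanges::tileGenome(seqlengths, tilewidth = bin_width,
                                     cut.last.tile.in.chrom = TRUE)
  bins <- data.frame(chrom = as.character(GenomicRanges::seqnames(tiles)),
                     start = GenomicRanges::start(tiles) - 1L,
                     end = GenomicRanges::end(tiles),
                     stringsAsFactors = FALSE)
  if (drop_short) {
    full <- bins$end - bins$start == bin_width
    tiles <- tiles[full]
    bins <- bins[full, , drop = FALSE]
    rownames(bins) <- NULL
  }
  counts <- matrix(0L, nrow(bins), length(calls_by_species),
                   dimnames = list(NULL, names(calls_by_species)))
  for (sp in names(calls_by_species)) {
    x <- calls_by_species[[sp]]
    x <- x[!is.na(x$h_pos), , drop = FALSE]
    if (!nrow(x)) next
    too_far <- x$h_pos >= seqlengths[x$h_chrom] | x$h_pos < 0L
    if (any(too_far, na.rm = TRUE)) {
      stop("call beyond chromosome end for species ", sp,
           " (first at ", x$h_chrom[which(too_far)[1L]], ":",
           x$h_pos[which(too_far)[1L]], ")")
    }
    gr <- GenomicRanges::GRanges(x$h_chrom,
                                 IRanges::IRanges(x$h_pos + 1L, x$h_pos + 1L))
    hit <- GenomicRanges::findOverlaps(gr, tiles, select = "first")
    tab <- table(hit)
    counts[as.integer(names(tab)), sp] <-
      counts[as.integer(names(tab)), sp] + as.integer(tab)
  }
  structure(list(bins = bins, counts = counts), class = "bin_table")
}

#' @export
print.bin_table <- function(x, ...) {
  cat("bin_table:", nrow(x$bins), "bins x", ncol(x$counts), "species;",
      sum(x$counts), "calls\n")
  invisible(x)
}

#' Cross-species deviation statistic per bin
#'
#' `D(bin) = sqrt( sum_i (xbar_i - x_i(bin))^2 )` over species `i`, where
#' `xbar_i` is species `i`'s mean per-bin frequency. Invariant to species
#' and bin order.
#'
#' @param table A [bin_frequencies()] result (or a bare counts matrix).
#' @return Numeric vector of D, one per bin.
#' @export
hotspot_statistic <- function(table) {
  counts <- if (inherits(table, "bin_table")) table$counts else table
  xbar <- colMeans(counts)
  sqrt(rowSums((rep(xbar, each = nrow(counts)) - counts)^2))
}

#' Permutation threshold controlling the hotspot FDR
#'
#' Each permutation redistributes every species' calls uniformly over the
#' binned genome (multinomial with probability proportional to bin width,
#' preserving per-species totals) and recomputes D for all bins. The
#' threshold is the smallest observed D value `t` with estimated FDR
#' `mean permuted #\{D >= t\} / observed #\{D >= t\} <= fdr` (inclusive
#' counting, so the top-ranked bin can itself qualify); `+Inf` (no
#' hotspots) when no threshold qualifies or `fdr = 0`.
#'
#' @param table A [bin_frequencies()] result.
#' @param n_perm Number of permutations.
#' @param fdr Target false discovery rate.
#' @param seed Integer seed.
#' @return List: `threshold`, `D` (observed), `n_perm`, `fdr`.
#' @export
fdr_threshold <- function(table, n_perm = 1000L, fdr = 0.05, seed = 1L) {
  counts <- table$counts
  nb <- nrow(counts)
  w <- (table$bins$end - table$bins$start)
  prob <- w / sum(w)
  totals <- colSums(counts)
  if (sum(totals) == 0L) stop("no calls in the bin table")
  d_obs <- hotspot_statistic(counts)
  perm_d <- matrix(0, nb, n_perm)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      pc <- vapply(totals, function(tt) {
        as.numeric(stats::rmultinom(1L, tt, prob))
      }, numeric(nb))
      perm_d[, p] <- hotspot_statistic(pc)
    }
  })
  # smallest observed D value t with estimated FDR at or below the target,
  # counting inclusively (bins with D >= t are called): with a strict
  # inequality the largest observed D could never qualify as a threshold
  cand <- sort(unique(d_obs[d_obs > 0]))
  thr <- Inf
  if (fdr > 0) {
    for (t in cand) {
      n_obs <- sum(d_obs >= t)
      n_perm_mean <- mean(colSums(perm_d >= t))
      if (n_perm_mean / n_obs <= fdr) { thr <- t; break }
    }
  }
  list(threshold = thr, D = d_obs, n_perm = n_perm, fdr = fdr)
}

#' Hotspot detection over a bin table
#'
#' @param table A [bin_frequencies()] result.
#' @inheritParams fdr_threshold
#' @return data.frame: bins with `D`, `threshold`, `is_hotspot` and the
#'   per-species counts for flagged bins' breakdown.
#' @export
find_hotspots <- function(table, n_perm = 1000L, fdr = 0.05, seed = 1L) {
  ft <- fdr_threshold(table, n_perm = n_perm, fdr = fdr, seed = seed)
  out <- cbind(table$bins,
               data.frame(D = ft$D, threshold = ft$threshold,
                          is_hotspot = ft$D >= ft$threshold))
  cbind(out, as.data.frame(table$counts))
}
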