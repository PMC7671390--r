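# Fixed-Numt catalogue: seeded local alignment of the mtDNA against the
# nuclear contigs of a reference assembly.

#' Scan a reference genome for fixed NumtS
#'
#' Exact `word`-mer seeds from the doubled mtDNA (both strands) are
#' matched against each nuclear contig (Aho-Corasick via
#' [Biostrings::matchPDict()]), clustered by alignment diagonal, and each
#' candidate region is refined by local alignment against the doubled
#' mtDNA (match 1 / mismatch -2 / gap open 4 / gap extend 1). HSPs above
#' the identity and length floors on the same strand within `merge_gap`
#' are merged into one record with a fragment count. Output is sorted and
#' invariant to contig order.
#'
#' @param nuclear Named list/character of nuclear contig sequences, a
#'   `DNAStringSet`, or a FASTA path. Must not include the mtDNA itself.
#' @param mt_seq mtDNA sequence (character, `DNAString`, or FASTA path).
#' @param word Seed word size (bp).
#' @param min_identity Minimum percent identity of a reported HSP.
#' @param min_length Minimum HSP length (bp).
#' @param merge_gap Same-strand HSPs closer than this merge (bp).
#' @param min_seeds Minimum diagonal-cluster seeds to trigger alignment.
#' @return data.frame of class `reference_numts`: `chrom`, `start`,
#'   `end` (0-based half-open), `mt_start`, `mt_end` (circular),
#'   `strand`, `identity`, `fragments`.
#' @export
scan_reference <- function(nuclear, mt_seq, word = 11L, min_identity = 80,
                           min_length = 50L, merge_gap = 5000L,
                           min_seeds = 3L) {
  if (is.character(nuclear) && length(nuclear) == 1L &&
      file.exists(nuclear)) {
    nuclear <- Biostrings::readDNAStringSet(nuclear)
  }
  if (inherits(nuclear, "DNAStringSet")) {
    nuclear <- stats::setNames(as.character(nuclear), names(nuclear))
  }
  if (is.character(mt_seq) && length(mt_seq) == 1L && file.exists(mt_seq)) {
    mt_seq <- as.character(Biostrings::readDNAStringSet(mt_seq)[[1]])
  }
  mt_seq <- as.character(mt_seq)
  mt_len <- nchar(mt_seq)
  dbl <- paste0(mt_seq, mt_seq)
  strands <- list(`+` = dbl, `-` = revcomp(dbl))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -2,
                                                     baseOnly = TRUE)
  hsps <- list()
  for (st in names(strands)) {
    sub <- strands[[st]]
    n_words <- nchar(sub) - word + 1L
    words <- substring(sub, seq_len(n_words), seq_len(n_words) + word - 1L)
    uw <- !duplicated(words)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(words[uw]),
                            max.mismatch = 0)
    w_pos <- split(seq_len(n_words) - 1L, words)  # mt offsets per word
    u_words <- words[uw]
    for (ch in sort(names(nuclear))) {
      subj <- Biostrings::DNAString(nuclear[[ch]])
      m <- Biostrings::matchPDict(pd, subj)
      si <- Biostrings::startIndex(m)
      cnt <- lengths(si)
      hit_w <- which(cnt > 0L)
      if (!length(hit_w)) next
      n_nuc <- cnt[hit_w]
      mtl <- w_pos[u_words[hit_w]]
      n_mt <- lengths(mtl)
      seed <- data.frame(
        nuc = rep(unlist(si[hit_w], use.names = FALSE) - 1L,
                  times = rep(n_mt, times = n_nuc)),
        mt = unlist(mapply(rep, mtl, n_nuc, SIMPLIFY = FALSE),
                    use.names = FALSE))
      seed$diag <- seed$nuc - seed$mt
      # cluster seeds: same diagonal band (width 64) and nearby on the contig
      seed <- seed[order(seed$diag %/% 64L, seed$nuc), , drop = FALSE]
      grp <- cumsum(c(1L, as.integer(
        diff(seed$diag %/% 64L) != 0L | diff(seed$nuc) > 1000L)))
      big <- which(tabulate(grp) >= min_seeds)
      groups <- split(seq_len(nrow(seed)), grp)
      for (g in big) {
        x <- seed[groups[[g]], , drop = FALSE]
        # a run of overlapping word hits from one chance ~15 bp match is
        # not a candidate; demand seeds spread beyond two word lengths
        if (max(x$nuc) - min(x$nuc) < 3L * word) next
        pad <- 200L
        n_lo <- max(0L, min(x$nuc) - pad)
        n_hi <- min(nchar(nuclear[[ch]]), max(x$nuc) + word + pad)
        m_lo <- max(0L, min(x$mt) - pad)
        m_hi <- min(nchar(sub), max(x$mt) + word + pad)
        aln <- Biostrings::pairwiseAlignment(
          substr(nuclear[[ch]], n_lo + 1L, n_hi),
          substr(sub, m_lo + 1L, m_hi),
          type = "local", substitutionMatrix = submat,
          gapOpening = 4, gapExtension = 1)
        p_al <- as.character(Biostrings::alignedPattern(aln))
        s_al <- as.character(Biostrings::alignedSubject(aln))
        ncol_al <- nchar(p_al)
        if (ncol_al == 0L) next
        matches <- sum(strsplit(p_al, "")[[1]] == strsplit(s_al, "")[[1]])
        identity <- 100 * matches / ncol_al
        n_s <- n_lo + Biostrings::start(Biostrings::pattern(aln)) - 1L
        n_e <- n_lo + Biostrings::end(Biostrings::pattern(aln))
        if (n_e - n_s < min_length || identity < min_identity) next
        mt_s_dbl <- m_lo + Biostrings::start(Biostrings::subject(aln)) - 1L
        mt_e_dbl <- m_lo + Biostrings::end(Biostrings::subject(aln))
        if (st == "-") {  # map back to forward-strand mt coordinates
          tmp <- nchar(sub) - mt_e_dbl
          mt_e_dbl <- nchar(sub) - mt_s_dbl
          mt_s_dbl <- tmp
        }
        hsps[[length(hsps) + 1L]] <- data.frame(
          chrom = ch, start = n_s, end = n_e,
          mt_start = mt_s_dbl %% mt_len,
          mt_end = if (mt_e_dbl - mt_s_dbl >= mt_len) mt_s_dbl %% mt_len
                   else mt_e_dbl %% mt_len,
          strand = st, identity = identity, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hsps)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), mt_start = integer(),
                      mt_end = integer(), strand = character(),
                      identity = numeric(), fragments = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("reference_numts", "data.frame")
    return(out)
  }
  h <- do.call(rbind, hsps)
  # deduplicate overlapping HSPs from adjacent seed clusters
  h <- h[order(h$chrom, h$strand, h$start, h$end), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))[-1L]) {
    j <- max(which(keep[seq_len(i - 1L)]))
    if (h$chrom[i] == h$chrom[j] && h$strand[i] == h$strand[j] &&
        h$start[i] < h$end[j]) {
      # keep the longer of two overlapping HSPs
      if (h$end[i] - h$start[i] > h$end[j] - h$start[j]) {
        keep[j] <- FALSE
      } else {
        keep[i] <- FALSE
      }
    }
  }
  h <- h[keep, , drop = FALSE]
  # merge same-strand HSPs within merge_gap
  out <- list()
  h <- h[order(h$chrom, h$strand, h$start), , drop = FALSE]
  grp <- cumsum(c(1L, as.integer(
    h$chrom[-1L] != h$chrom[-nrow(h)] | h$strand[-1L] != h$strand[-nrow(h)] |
      (h$start[-1L] - h$end[-nrow(h)]) > merge_gap)))
  for (g in unique(grp)) {
    x <- h[grp == g, , drop = FALSE]
    w <- x$end - x$start
    out[[g]] <- data.frame(
      chrom = x$chrom[1L], start = min(x$start), end = max(x$end),
      mt_start = x$mt_start[which.max(w)], mt_end = x$mt_end[which.max(w)],
      strand = x$strand[1L],
      identity = sum(x$identity * w) / sum(w),
      fragments = nrow(x), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("reference_numts", "data.frame")
  res
}
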