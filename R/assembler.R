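# Numt insertion-sequence reconstruction: read pooling across carriers, a
# greedy overlap-consensus assembler, and annotation of contigs against
# the circular mtDNA.

#' Pool Numt-supporting reads across carrier samples
#'
#' Collects, for one call: discordant mt-side mates whose nuclear anchor
#' lies within `flank` of the breakpoint, soft-clipped nuclear reads near
#' the breakpoint, and unmapped reads placed at a mapped mate near the
#' breakpoint. Reads are pooled over all carriers with an alignment file
#' and deduplicated by (read name, mate). mt-side mates are reorientated
#' to the nuclear strand using the call's orientation so that one
#' consistent strand enters the assembler.
#'
#' @param sams Named list/vector: sample -> SAM/BAM path.
#' @param call One-row call (from [cluster_and_call()] /
#'   [merge_samples()]).
#' @param mt_contig mtDNA contig name.
#' @param flank Anchor window around the breakpoint (bp).
#' @param min_clip Minimum soft-clip length contributing a read.
#' @return Named character vector of read sequences (names unique per
#'   read/mate).
#' @export
extract_reads <- function(sams, call, mt_contig, flank = 1000L,
                          min_clip = 10L) {
  carriers <- strsplit(call$carriers, ",")[[1]]
  if (!length(carriers)) stop("call has no carriers")
  out <- character(0)
  for (sm in carriers) {
    if (!sm %in% names(sams) || !file.exists(sams[[sm]])) {
      warning("no alignment file for carrier ", sm, "; skipped")
      next
    }
    bam <- sam_as_bam(sams[[sm]])
    hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
    lo <- max(1L, call$pos - flank)
    hi <- min(hdr[[call$chrom]], call$pos + flank)
    region <- GenomicRanges::GRanges(call$chrom, IRanges::IRanges(lo, hi))
    nuc <- read_alignments(bam, region = region)
    mt_all <- read_alignments(
      bam, region = GenomicRanges::GRanges(
        mt_contig, IRanges::IRanges(1L, hdr[[mt_contig]])))
    pc <- parse_cigar_clips(nuc$cigar)
    keep_clip <- !bitwAnd(nuc$flag, 4L) &
      (pc$clip_l >= min_clip | pc$clip_r >= min_clip)
    keep_unmapped <- bitwAnd(nuc$flag, 4L) > 0L
    nuc_keep <- nuc[keep_clip | keep_unmapped, , drop = FALSE]
    mt_keep <- mt_all[!is.na(mt_all$mrnm) & mt_all$mrnm == call$chrom &
                        abs(mt_all$mpos - 1L - call$pos) <= flank, ,
                      drop = FALSE]
    if (nrow(mt_keep) && !is.null(call$orientation) &&
        call$orientation == "-") {
      mt_keep$seq <- revcomp(mt_keep$seq)
    }
    pool <- rbind(nuc_keep, mt_keep)
    if (!nrow(pool)) next
    mate <- ifelse(bitwAnd(pool$flag, 64L) > 0L, "1", "2")
    nm <- paste0(pool$qname, "/", mate)
    dup <- duplicated(nm) | nm %in% names(out)
    add <- stats::setNames(pool$seq[!dup], nm[!dup])
    out <- c(out, add)
  }
  out[sort(names(out))]
}

#' Greedy overlap-consensus assembly of a read set
#'
#' Repeatedly merges the pair of sequences with the highest-scoring
#' suffix-prefix overlap of at least `min_overlap` bp at
#' `min_overlap_identity` or better (full containment allowed), taking
#' the per-column majority as consensus. Overlap candidates are seeded
#' with exact 16-mers; ties break lexicographically on read name, so the
#' result is independent of input order. Stops when no admissible merge
#' remains.
#'
#' @param reads Named character vector of read sequences (>= 2 for any
#'   merging to happen; fewer are returned as-is).
#' @param min_overlap Minimum overlap length (bp).
#' @param min_overlap_identity Minimum overlap identity (fraction).
#' @return List of contigs, each `list(seq, members, n_reads)`, sorted by
#'   decreasing length; `members` is a data.frame (name, offset).
#' @export
assemble_reads <- function(reads, min_overlap = 16L,
                           min_overlap_identity = 0.95) {
  reads <- reads[order(names(reads))]
  contigs <- lapply(seq_along(reads), function(i) {
    list(seq = unname(reads[i]),
         members = data.frame(name = names(reads)[i], offset = 0L,
                              stringsAsFactors = FALSE))
  })
  names(contigs) <- names(reads)
  if (length(contigs) < 2L) return(unname(contigs))

  seed_w <- min(16L, min_overlap)
  best <- function(a, b) best_overlap(contigs[[a]]$seq, contigs[[b]]$seq,
                                      min_overlap, min_overlap_identity,
                                      seed_w)
  keys <- names(contigs)
  # score table: rows a -> b (suffix of a onto prefix of b, or b within a)
  scores <- list()
  for (a in keys) for (b in keys) if (a != b) {
    s <- best(a, b)
    if (!is.null(s)) scores[[paste(a, b, sep = "\r")]] <- s$score
  }
  while (length(scores)) {
    sc <- unlist(scores)
    top <- names(sc)[order(-sc, names(sc))][1L]
    ab <- strsplit(top, "\r", fixed = TRUE)[[1]]
    a <- ab[1L]; b <- ab[2L]
    ov <- best(a, b)
    if (is.null(ov)) { scores[[top]] <- NULL; next }
    merged <- merge_contigs(contigs[[a]], contigs[[b]], ov$offset, reads)
    nm <- merged$members$name[1L]
    contigs[[a]] <- NULL; contigs[[b]] <- NULL
    scores <- scores[!grepl(paste0("^", esc(a), "\r|\r", esc(a), "$|",
                                   "^", esc(b), "\r|\r", esc(b), "$"),
                            names(scores))]
    contigs[[nm]] <- merged
    for (k in names(contigs)) if (k != nm) {
      s1 <- best(nm, k)
      if (!is.null(s1)) scores[[paste(nm, k, sep = "\r")]] <- s1$score
      s2 <- best(k, nm)
      if (!is.null(s2)) scores[[paste(k, nm, sep = "\r")]] <- s2$score
    }
  }
  out <- lapply(contigs, function(x) {
    x$n_reads <- nrow(x$members); x
  })
  out <- unname(out)
  out[order(-vapply(out, function(x) nchar(x$seq), 0L),
            vapply(out, function(x) x$members$name[1L], ""))]
}

esc <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# best suffix(a)-prefix(b) overlap (or containment of b in a), seeded by
# exact seed_w-mers of b looked up in a
best_overlap <- function(a, b, min_overlap, min_id, seed_w) {
  la <- nchar(a); lb <- nchar(b)
  if (lb < min_overlap) return(NULL)
  seed <- substr(b, 1L, seed_w)
  hits <- gregexpr(seed, a, fixed = TRUE)[[1]]
  if (hits[1L] == -1L) return(NULL)
  cand <- hits - 1L                   # 0-based offset of b within a
  bestv <- NULL
  for (off in cand) {
    k <- min(la - off, lb)            # overlap length
    if (k < min_overlap) next
    mm <- str_mismatches(substr(a, off + 1L, off + k), substr(b, 1L, k))
    if (mm > (1 - min_id) * k) next
    score <- k - 4L * mm
    if (is.null(bestv) || score > bestv$score) {
      bestv <- list(offset = off, score = score)
    }
  }
  bestv
}

# consensus over all member reads (looked up by name) by per-column
# majority; ties resolve alphabetically via which.max over A,C,G,T
merge_contigs <- function(ca, cb, offset, reads) {
  mem <- rbind(ca$members,
               data.frame(name = cb$members$name,
                          offset = cb$members$offset + offset,
                          stringsAsFactors = FALSE))
  mem <- mem[order(mem$name), , drop = FALSE]
  rownames(mem) <- NULL
  seqs <- unname(reads[mem$name])
  width <- max(mem$offset + nchar(seqs))
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs),
                                    shift = mem$offset, width = width)
  cm <- cm[DNA, , drop = FALSE]
  cons <- paste(DNA[apply(cm, 2L, which.max)], collapse = "")
  list(seq = cons, members = mem)
}
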