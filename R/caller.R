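# Polymorphic Numt detection from discordant pairs and soft-clipped reads.

#' Collect Numt-informative alignment signals from a SAM/BAM
#'
#' Returns (i) discordant pairs: the nuclear-side mate of every pair with
#' exactly one mate on the mtDNA contig and nuclear mapping quality at
#' least `min_mapq`, and (ii) soft-clipped nuclear reads whose clipped
#' tail is at least `min_clip` bp and, when `mt_seq` is supplied, matches
#' the mtDNA (either strand, doubled to honour circularity, at most one
#' mismatch per 15 bp).
#'
#' @param sam Path to SAM/BAM.
#' @param mt_contig Name of the mtDNA contig; must be in the header.
#' @param min_mapq Minimum nuclear-mate mapping quality.
#' @param mt_seq Optional mtDNA sequence for clip verification.
#' @param min_clip Minimum clipped-tail length (bp).
#' @return List of class `numt_signals` with data.frames `discordant`
#'   (chrom, pos, end, strand, mapq, mt_pos, mt_strand, orientation) and
#'   `clipped` (chrom, clip_pos, side, seq, mapq). Coordinates 0-based.
#' @export
collect_signals <- function(sam, mt_contig, min_mapq = 20L, mt_seq = NULL,
                            min_clip = 10L) {
  hdr <- Rsamtools::scanBamHeader(sam_as_bam(sam))[[1]]$targets
  if (!mt_contig %in% names(hdr)) {
    stop("mt contig '", mt_contig, "' is not in the SAM header; ",
         "was the reference augmented?")
  }
  aln <- read_alignments(sam)
  aln <- aln[!bitwAnd(aln$flag, 4L), , drop = FALSE]  # mapped records only
  parsed <- parse_cigar_clips(aln$cigar)

  nuc <- aln$rname != mt_contig
  disc_i <- which(nuc & !is.na(aln$mrnm) & aln$mrnm == mt_contig &
                    !bitwAnd(aln$flag, 8L) & aln$mapq >= min_mapq)
  d <- aln[disc_i, , drop = FALSE]
  discordant <- data.frame(
    qname = d$qname,
    chrom = d$rname,
    pos = d$pos - 1L,
    end = d$pos - 1L + parsed$m_len[disc_i],
    strand = d$strand,
    mapq = d$mapq,
    mt_pos = d$mpos - 1L,
    mt_strand = ifelse(bitwAnd(d$flag, 32L) > 0L, "-", "+"),
    stringsAsFactors = FALSE
  )
  # "+" insertions look like ordinary FR pairs (anchor and mt mate on
  # opposite strands); same-strand mates indicate a "-" insertion
  discordant$orientation <- ifelse(discordant$strand != discordant$mt_strand,
                                   "+", "-")

  clip_i <- which(nuc & (parsed$clip_l >= min_clip | parsed$clip_r >= min_clip)
                  & aln$mapq >= min_mapq)
  rows <- list()
  for (j in clip_i) {
    if (parsed$clip_l[j] >= min_clip) {
      rows[[length(rows) + 1L]] <- data.frame(
        qname = aln$qname[j], chrom = aln$rname[j],
        clip_pos = aln$pos[j] - 1L, side = "left",
        seq = substr(aln$seq[j], 1L, parsed$clip_l[j]),
        mapq = aln$mapq[j], stringsAsFactors = FALSE)
    }
    if (parsed$clip_r[j] >= min_clip) {
      rows[[length(rows) + 1L]] <- data.frame(
        qname = aln$qname[j], chrom = aln$rname[j],
        clip_pos = aln$pos[j] - 1L + parsed$m_len[j], side = "right",
        seq = substr(aln$seq[j], nchar(aln$seq[j]) - parsed$clip_r[j] + 1L,
                     nchar(aln$seq[j])),
        mapq = aln$mapq[j], stringsAsFactors = FALSE)
    }
  }
  clipped <- if (length(rows)) do.call(rbind, rows) else
    data.frame(qname = character(), chrom = character(), clip_pos = integer(),
               side = character(), seq = character(), mapq = integer(),
               stringsAsFactors = FALSE)
  if (!is.null(mt_seq) && nrow(clipped)) {
    keep <- clip_matches_mt(clipped$seq, as.character(mt_seq))
    clipped <- clipped[keep, , drop = FALSE]
  }
  o <- order(discordant$chrom, discordant$pos, discordant$qname)
  discordant <- discordant[o, , drop = FALSE]
  o <- order(clipped$chrom, clipped$clip_pos, clipped$qname)
  clipped <- clipped[o, , drop = FALSE]
  rownames(discordant) <- rownames(clipped) <- NULL
  structure(list(discordant = discordant, clipped = clipped,
                 mt_contig = mt_contig),
            class = "numt_signals")
}

parse_cigar_clips <- function(cigar) {
  clip_l <- integer(length(cigar))
  clip_r <- integer(length(cigar))
  m_len <- integer(length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)        # fast path: fully aligned reads
  m_len[simple] <- as.integer(sub("M", "", cigar[simple], fixed = TRUE))
  rest <- which(!simple)
  if (length(rest)) {
    cg <- cigar[rest]
    has_l <- grepl("^[0-9]+S", cg)
    clip_l[rest[has_l]] <- as.integer(sub("S", "", regmatches(
      cg, regexpr("^[0-9]+S", cg))))
    has_r <- grepl("[0-9]+S$", cg)
    clip_r[rest[has_r]] <- as.integer(sub("S$", "", regmatches(
      cg, regexpr("[0-9]+S$", cg))))
    mm <- regmatches(cg, gregexpr("[0-9]+M", cg))
    m_len[rest] <- vapply(mm, function(x) sum(as.integer(sub("M", "", x))),
                          0L)
  }
  list(clip_l = clip_l, clip_r = clip_r, m_len = m_len)
}

# does each clipped tail match the (doubled, both-strand) mtDNA with at
# most one mismatch per 15 bp?
clip_matches_mt <- function(seqs, mt_seq) {
  dbl <- Biostrings::DNAString(paste0(mt_seq, mt_seq))
  rc <- Biostrings::reverseComplement(dbl)
  vapply(seqs, function(s) {
    mm <- nchar(s) %/% 15L
    p <- Biostrings::DNAString(s)
    length(Biostrings::matchPattern(p, dbl, max.mismatch = mm)) > 0L ||
      length(Biostrings::matchPattern(p, rc, max.mismatch = mm)) > 0L
  }, TRUE, USE.NAMES = FALSE)
}

#' Cluster signals into per-sample Numt calls
#'
#' Nuclear mates are clustered by single linkage with a link distance of
#' `insert_mean + 3 * insert_sd`; a cluster becomes a call when it holds
#' at least `min_support` discordant pairs. The breakpoint is the modal
#' soft-clip position when clipped evidence exists (ties resolve to the
#' smaller coordinate), otherwise the midpoint between the innermost
#' forward-side mate end and the innermost reverse-side mate start; the
#' confidence interval spans those two bounds. Orientation is the
#' majority pair-orientation class. Fully deterministic and independent
#' of input record order.
#'
#' @param signals A [collect_signals()] result.
#' @param insert_mean,insert_sd Insert size model of the library.
#' @param min_support Minimum discordant-pair support for a PASS call.
#' @param sample Sample ID recorded as the carrier.
#' @return data.frame of class `numt_calls`: one row per call with
#'   breakpoint (0-based), CI, mt segment estimate, support and filter.
#' @export
cluster_and_call <- function(signals, insert_mean = 400, insert_sd = 50,
                             min_support = 4L, sample = "sample") {
  d <- signals$discordant
  cl <- signals$clipped
  window <- insert_mean + 3 * insert_sd
  calls <- list()
  for (ch in sort(unique(d$chrom))) {
    dc <- d[d$chrom == ch, , drop = FALSE]
    dc <- dc[order(dc$pos, dc$qname), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(dc$pos) > window)))
    for (g in unique(grp)) {
      x <- dc[grp == g, , drop = FALSE]
      if (nrow(x) < min_support) next
      fwd <- x[x$strand == "+", , drop = FALSE]
      rev <- x[x$strand == "-", , drop = FALSE]
      lo <- if (nrow(fwd)) max(fwd$end) else min(x$pos) - as.integer(insert_mean)
      hi <- if (nrow(rev)) min(rev$pos) else max(x$end) + as.integer(insert_mean)
      if (hi < lo) { tmp <- lo; lo <- hi; hi <- tmp }
      xc <- cl[cl$chrom == ch & cl$clip_pos >= min(x$pos) - window &
                 cl$clip_pos <= max(x$end) + window, , drop = FALSE]
      if (nrow(xc)) {
        tab <- table(xc$clip_pos)
        bp <- as.integer(names(tab)[which.max(tab)])  # modal; ties -> smallest
      } else {
        bp <- as.integer((lo + hi) %/% 2)
      }
      ci_lo <- min(lo, bp); ci_hi <- max(hi, bp)
      ori_tab <- table(x$orientation)
      ori <- names(ori_tab)[which.max(ori_tab)]
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = ch, pos = bp, ci_lo = ci_lo, ci_hi = ci_hi,
        mt_start_est = min(x$mt_pos),
        mt_end_est = max(x$mt_pos) + 100L,
        orientation = ori,
        n_discordant = nrow(x), n_clipped = nrow(xc),
        sides_supported = sum(nrow(fwd) > 0L, nrow(rev) > 0L),
        carriers = sample, support = nrow(x),
        filter = if (nrow(x) >= min_support) "PASS" else "LowSupport",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else empty_calls()
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("numt_calls", "data.frame")
  attr(out, "reference") <- signals$mt_contig
  out
}

empty_calls <- function() {
  data.frame(chrom = character(), pos = integer(), ci_lo = integer(),
             ci_hi = integer(), mt_start_est = integer(),
             mt_end_est = integer(), orientation = character(),
             n_discordant = integer(), n_clipped = integer(),
             sides_supported = integer(), carriers = character(),
             support = integer(), filter = character(),
             stringsAsFactors = FALSE)
}

#' Call NumtS in one sample (signals + clustering)
#'
#' @inheritParams collect_signals
#' @inheritParams cluster_and_call
#' @return A `numt_calls` data.frame.
#' @export
call_numts <- function(sam, mt_contig, sample, min_mapq = 20L,
                       mt_seq = NULL, insert_mean = 400, insert_sd = 50,
                       min_support = 4L) {
  sig <- collect_signals(sam, mt_contig, min_mapq = min_mapq, mt_seq = mt_seq)
  cluster_and_call(sig, insert_mean = insert_mean, insert_sd = insert_sd,
                   min_support = min_support, sample = sample)
}

#' Merge per-sample calls into a species call set
#'
#' Calls whose breakpoints fall within `window` bp of each other (single
#' linkage per chromosome) are merged into one species-level call at the
#' support-weighted median breakpoint, with carriers unioned and support
#' summed.
#'
#' @param call_list Named list (sample -> `numt_calls`); all against the
#'   same species reference.
#' @param window Merge window in bp (breakpoint distance).
#' @return data.frame: merged calls with `carriers` (comma-separated) and
#'   `n_samples`.
#' @export
merge_samples <- function(call_list, window = 500L) {
  if (!length(call_list)) return(empty_calls())
  refsets <- unique(lapply(call_list, function(x) sort(unique(x$chrom))))
  nonempty <- Filter(nrow, call_list)
  if (length(nonempty) > 1L) {
    mtc <- unique(unlist(lapply(nonempty, function(x) attr(x, "reference"))))
    if (length(mtc) > 1L) stop("calls come from different references: ",
                               paste(mtc, collapse = ", "))
  }
  all <- do.call(rbind, lapply(names(call_list), function(sm) {
    x <- call_list[[sm]]
    if (nrow(x)) x$carriers <- sm
    x
  }))
  if (nrow(all) == 0L) return(empty_calls())
  out <- list()
  for (ch in sort(unique(all$chrom))) {
    x <- all[all$chrom == ch, , drop = FALSE]
    x <- x[order(x$pos, x$carriers), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(diff(x$pos) > window)))
    for (g in unique(grp)) {
      y <- x[grp == g, , drop = FALSE]
      bp <- weighted_median(y$pos, y$support)
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, pos = bp,
        ci_lo = min(y$ci_lo), ci_hi = max(y$ci_hi),
        mt_start_est = min(y$mt_start_est),
        mt_end_est = max(y$mt_end_est),
        orientation = names(sort(table(y$orientation),
                                 decreasing = TRUE))[1L],
        n_discordant = sum(y$n_discordant),
        n_clipped = sum(y$n_clipped),
        sides_supported = max(y$sides_supported),
        carriers = paste(sort(unique(y$carriers)), collapse = ","),
        support = sum(y$support),
        filter = "PASS", n_samples = length(unique(y$carriers)),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write calls as BED6+ and a minimal VCF
#'
#' @param calls A calls data.frame.
#' @param bed,vcf Output paths (either may be `NULL` to skip).
#' @param species Species/reference label for the VCF header.
#' @return Invisibly, the paths written.
#' @export
write_calls <- function(calls, bed = NULL, vcf = NULL, species = "species") {
  if (!is.null(bed)) {
    utils::write.table(
      data.frame(calls$chrom, calls$pos, calls$pos + 1L,
                 sprintf("NUMT_%s_%d", calls$chrom, calls$pos), calls$support,
                 calls$orientation, calls$ci_lo, calls$ci_hi,
                 calls$n_discordant, calls$n_clipped, calls$carriers),
      bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(vcf)) {
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##source=numtforge"),
             sprintf("##reference=%s", species),
             "##INFO=<ID=MTSTART,Number=1,Type=Integer,Description=\"mtDNA segment start (0-based)\">",
             "##INFO=<ID=MTEND,Number=1,Type=Integer,Description=\"mtDNA segment end estimate\">",
             "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Discordant pair support\">",
             "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Breakpoint confidence interval\">",
             "##ALT=<ID=INS:MT,Description=\"Nuclear mitochondrial insertion\">",
             paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                                 "FILTER", "INFO"), collapse = "\t")))
    body <- sprintf(
      "%s\t%d\tNUMT%03d\tN\t<INS:MT>\t.\t%s\tMTSTART=%d;MTEND=%d;SUPPORT=%d;CIPOS=%d,%d",
      calls$chrom, calls$pos + 1L, seq_len(nrow(calls)), calls$filter,
      calls$mt_start_est, calls$mt_end_est, calls$support,
      calls$ci_lo - calls$pos, calls$ci_hi - calls$pos)
    writeLines(c(hdr, body), vcf)
  }
  invisible(c(bed = bed, vcf = vcf))
}
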