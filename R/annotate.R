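# Contig annotation against the circular mtDNA and the nuclear flanks.

# local alignment of a contig against the doubled mtDNA (both strands).
# Returns NULL or list(mt_start, mt_end (circular, half-open), strand,
# identity (percent), score, aligned pattern/subject + offsets for
# per-position work.
align_to_mt <- function(contig, mt_seq, min_len = 50L, min_identity = 80) {
  mt_len <- nchar(mt_seq)
  dbl <- paste0(mt_seq, mt_seq)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -2,
                                                     baseOnly = TRUE)
  best <- NULL
  for (st in c("+", "-")) {
    qry <- if (st == "+") contig else revcomp(contig)
    aln <- Biostrings::pairwiseAlignment(qry, dbl, type = "local",
                                         substitutionMatrix = submat,
                                         gapOpening = 4, gapExtension = 1)
    if (is.null(best) || Biostrings::score(aln) > best$score) {
      best <- list(aln = aln, strand = st, score = Biostrings::score(aln))
    }
    # a near-perfect forward hit cannot be beaten by the reverse strand
    if (st == "+" && best$score >= 0.9 * nchar(contig)) break
  }
  aln <- best$aln
  s0 <- Biostrings::start(Biostrings::subject(aln)) - 1L
  e0 <- Biostrings::end(Biostrings::subject(aln))
  span <- e0 - s0
  p_al <- as.character(Biostrings::alignedPattern(aln))
  s_al <- as.character(Biostrings::alignedSubject(aln))
  ncol_al <- nchar(p_al)
  matches <- sum(strsplit(p_al, "")[[1]] == strsplit(s_al, "")[[1]])
  identity <- 100 * matches / ncol_al
  if (span < min_len || identity < min_identity) return(NULL)
  list(
    mt_start = s0 %% mt_len,
    mt_end = if (span >= mt_len) s0 %% mt_len else e0 %% mt_len,
    strand = best$strand, identity = identity, score = best$score,
    span = span,
    q_start = Biostrings::start(Biostrings::pattern(aln)) - 1L,
    q_end = Biostrings::end(Biostrings::pattern(aln)),
    p_al = p_al, s_al = s_al, s0 = s0, mt_len = mt_len
  )
}

# does the contig carry the nuclear sequence immediately left/right of the
# breakpoint? (30 bp junction-adjacent probe, <= 2 mismatches)
flank_presence <- function(contig, ref, pos, probe = 30L, max_mm = 2L) {
  L <- nchar(ref)
  left <- substr(ref, max(1L, pos - probe + 1L), pos)
  right <- substr(ref, pos + 1L, min(L, pos + probe))
  has <- function(p) {
    nchar(p) >= probe &&
      length(Biostrings::matchPattern(Biostrings::DNAString(p),
                                      Biostrings::DNAString(contig),
                                      max.mismatch = max_mm)) > 0L
  }
  c(left = has(left), right = has(right))
}

#' Annotate one contig against the mtDNA and the nuclear breakpoint
#'
#' Aligns the contig locally against the doubled mtDNA (both strands) to
#' resolve circular segments, and probes for the nuclear flank sequence
#' on either side of the call breakpoint to establish which junctions the
#' contig spans.
#'
#' @param contig Contig sequence (character).
#' @param mt_seq mtDNA sequence.
#' @param ref_seq Nuclear reference sequence of the call chromosome.
#' @param call One-row call (needs `pos`).
#' @param min_len,min_identity mtDNA alignment acceptance floor.
#' @return One-row data.frame (`mt_start`, `mt_end`, `strand`,
#'   `identity`, `span`, `has_left`, `has_right`, `is_mt`), or an
#'   all-`NA` row with `is_mt = FALSE` when no acceptable mtDNA alignment
#'   exists.
#' @export
annotate_contig <- function(contig, mt_seq, ref_seq, call, min_len = 50L,
                            min_identity = 80) {
  hit <- align_to_mt(contig, mt_seq, min_len, min_identity)
  fl <- flank_presence(contig, ref_seq, call$pos)
  if (is.null(hit)) {
    return(data.frame(mt_start = NA_integer_, mt_end = NA_integer_,
                      strand = NA_character_, identity = NA_real_,
                      span = NA_integer_, has_left = fl["left"],
                      has_right = fl["right"], is_mt = FALSE,
                      row.names = NULL))
  }
  data.frame(mt_start = hit$mt_start, mt_end = hit$mt_end,
             strand = hit$strand, identity = hit$identity, span = hit$span,
             has_left = unname(fl["left"]), has_right = unname(fl["right"]),
             is_mt = TRUE, row.names = NULL)
}

#' Annotate a call from its assembled contigs
#'
#' Classifies completeness: `full` when one mtDNA-matching contig carries
#' both nuclear flanks; `partial-two-side` when separate contigs carry
#' the left and right junctions (the insertion length is then estimated
#' as the circular distance between the two junction mtDNA coordinates);
#' `partial-one-side` when only one junction is recovered; `unanchored`
#' when contigs match the mtDNA but no junction; `non-mt` otherwise.
#'
#' @param contigs List of contigs from [assemble_reads()] (or character
#'   vector of sequences).
#' @param mt_seq mtDNA sequence.
#' @param ref_seq Nuclear reference sequence of the call chromosome.
#' @param call One-row call.
#' @param min_len,min_identity mtDNA alignment acceptance floor.
#' @return One-row data.frame: `mt_start`, `mt_end`, `strand`,
#'   `identity`, `completeness`, `est_length`, `n_contigs`, `best_contig`
#'   (sequence of the contig the segment was read from).
#' @export
annotate_call <- function(contigs, mt_seq, ref_seq, call, min_len = 50L,
                          min_identity = 80) {
  seqs <- if (is.character(contigs)) contigs else
    vapply(contigs, function(x) x$seq, "")
  if (!length(seqs)) stop("no contigs to annotate")
  ann <- do.call(rbind, lapply(seqs, annotate_contig, mt_seq = mt_seq,
                               ref_seq = ref_seq, call = call,
                               min_len = min_len,
                               min_identity = min_identity))
  ann$len <- nchar(seqs)
  mt_len <- nchar(mt_seq)
  ok <- which(ann$is_mt)
  empty <- data.frame(mt_start = NA_integer_, mt_end = NA_integer_,
                      strand = NA_character_, identity = NA_real_,
                      completeness = "non-mt", est_length = NA_integer_,
                      n_contigs = length(seqs), best_contig = NA_character_,
                      stringsAsFactors = FALSE)
  if (!length(ok)) return(empty)
  score <- ann$identity * ann$span
  full <- ok[ann$has_left[ok] & ann$has_right[ok]]
  if (length(full)) {
    i <- full[which.max(score[full])]
    return(data.frame(mt_start = ann$mt_start[i], mt_end = ann$mt_end[i],
                      strand = ann$strand[i], identity = ann$identity[i],
                      completeness = "full",
                      est_length = circ_length(ann$mt_start[i],
                                               ann$mt_end[i], mt_len),
                      n_contigs = length(seqs), best_contig = seqs[i],
                      stringsAsFactors = FALSE))
  }
  lefts <- ok[ann$has_left[ok]]
  rights <- ok[ann$has_right[ok]]
  if (length(lefts) && length(rights)) {
    li <- lefts[which.max(score[lefts])]
    ri <- rights[which.max(score[rights])]
    st <- ann$strand[li]
    # the left junction exposes the segment 5' end on "+" insertions and
    # the segment 3' end on "-" insertions
    if (st == "+") {
      ms <- ann$mt_start[li]; me <- ann$mt_end[ri]
    } else {
      ms <- ann$mt_start[ri]; me <- ann$mt_end[li]
    }
    i <- if (score[li] >= score[ri]) li else ri
    return(data.frame(mt_start = ms, mt_end = me, strand = st,
                      identity = stats::weighted.mean(
                        ann$identity[c(li, ri)], ann$span[c(li, ri)]),
                      completeness = "partial-two-side",
                      est_length = circ_length(ms, me, mt_len),
                      n_contigs = length(seqs), best_contig = seqs[i],
                      stringsAsFactors = FALSE))
  }
  one <- c(lefts, rights)
  comp <- if (length(one)) "partial-one-side" else "unanchored"
  pool <- if (length(one)) one else ok
  i <- pool[which.max(score[pool])]
  data.frame(mt_start = ann$mt_start[i], mt_end = ann$mt_end[i],
             strand = ann$strand[i], identity = ann$identity[i],
             completeness = comp,
             est_length = NA_integer_,
             n_contigs = length(seqs), best_contig = seqs[i],
             stringsAsFactors = FALSE)
}

#' Assemble and annotate every call of a species
#'
#' @param calls Species-level calls ([merge_samples()]).
#' @param sams Named list sample -> SAM/BAM.
#' @param mt_seq mtDNA sequence (species consensus).
#' @param mt_contig mtDNA contig name.
#' @param ref_seqs Named list chrom -> nuclear reference sequence.
#' @param flank Read-pooling window (bp).
#' @param min_overlap,min_overlap_identity Assembler parameters.
#' @return data.frame: one row per call (call columns + annotation).
#' @export
assemble_calls <- function(calls, sams, mt_seq, mt_contig, ref_seqs,
                           flank = 1000L, min_overlap = 16L,
                           min_overlap_identity = 0.95) {
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    call <- calls[i, ]
    reads <- extract_reads(sams, call, mt_contig, flank = flank)
    ann <- if (length(reads) >= 2L) {
      ctg <- assemble_reads(reads, min_overlap, min_overlap_identity)
      annotate_call(ctg, mt_seq, ref_seqs[[call$chrom]], call)
    } else {
      data.frame(mt_start = NA_integer_, mt_end = NA_integer_,
                 strand = NA_character_, identity = NA_real_,
                 completeness = "no-reads", est_length = NA_integer_,
                 n_contigs = 0L, best_contig = NA_character_,
                 stringsAsFactors = FALSE)
    }
    rows[[i]] <- cbind(call[, c("chrom", "pos", "carriers", "support")],
                       ann, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
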