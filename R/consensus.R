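# Per-sample mtDNA consensus by iterative majority pileup.

# internal: read a SAM via Rsamtools, returning a data.frame of the fields
# the pipeline consumes. SAM is converted to (sorted) BAM once and cached
# alongside the input.
read_alignments <- function(sam, fields = c("qname", "flag", "rname",
                                            "strand", "pos", "mapq", "cigar",
                                            "mrnm", "mpos", "seq"),
                            region = NULL) {
  bam <- sam_as_bam(sam)
  param <- if (is.null(region)) {
    Rsamtools::ScanBamParam(what = fields)
  } else {
    Rsamtools::ScanBamParam(what = fields, which = region)
  }
  res <- Rsamtools::scanBam(bam, param = param)
  res <- lapply(res, function(x) {
    x$seq <- as.character(x$seq)
    x$rname <- as.character(x$rname)
    x$mrnm <- as.character(x$mrnm)
    x$strand <- as.character(x$strand)
    as.data.frame(x, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

sam_as_bam <- function(sam) {
  if (grepl("\\.bam$", sam)) return(sam)
  bam <- paste0(tools::file_path_sans_ext(sam), ".bam")
  if (!file.exists(bam) ||
      file.mtime(bam) < file.mtime(sam)) {
    Rsamtools::asBam(sam, tools::file_path_sans_ext(sam), overwrite = TRUE,
                     indexDestination = TRUE)
  }
  bam
}

#' Build a per-sample mtDNA consensus by iterative pileup
#'
#' Each position takes the majority base among covering reads (minimum
#' depth 2, strict majority, ties keep the previous base), otherwise the
#' reference base. After each consensus update, reads with mismatches are
#' re-placed by searching a small exact-match shift against the current
#' consensus; iteration stops when no position changes or after
#' `max_iter` rounds. Substitution-only by design: the consensus keeps
#' the reference length, so every downstream module shares one mtDNA
#' coordinate system.
#'
#' @param sam Path to a SAM/BAM with reads on the mtDNA contig.
#' @param ref_mt Reference mtDNA (character string or `DNAString`).
#' @param mt_contig Name of the mtDNA contig in the SAM (default: the
#'   single contig whose length equals `nchar(ref_mt)`).
#' @param min_depth Minimum depth for a position to be updated.
#' @param max_iter Iteration cap.
#' @return Object of class `consensus_mt`: `sequence`, `depth`,
#'   `majority_fraction`, `n_iterations`, `low_confidence`.
#' @export
build_consensus_mt <- function(sam, ref_mt, mt_contig = NULL,
                               min_depth = 2L, max_iter = 5L) {
  ref_mt <- as.character(ref_mt)
  L <- nchar(ref_mt)
  aln <- read_alignments(sam)
  if (is.null(mt_contig)) {
    hdr <- Rsamtools::scanBamHeader(sam_as_bam(sam))[[1]]$targets
    cand <- names(hdr)[hdr == L]
    if (length(cand) != 1L) stop("cannot infer the mt contig; pass mt_contig")
    mt_contig <- cand
  }
  aln <- aln[!is.na(aln$rname) & aln$rname == mt_contig &
               !bitwAnd(aln$flag, 4L), , drop = FALSE]
  if (nrow(aln) == 0L) stop("no aligned reads on contig ", mt_contig)

  # trim soft clips so reads contribute only their aligned M run
  parsed <- parse_simple_cigar(aln$cigar)
  aseq <- substr(aln$seq, parsed$clip_l + 1L, parsed$clip_l + parsed$m_len)
  pos0 <- aln$pos - 1L
  keep <- parsed$m_len > 0L & pos0 + parsed$m_len <= L
  aseq <- aseq[keep]; pos0 <- pos0[keep]

  cons <- ref_mt
  n_iter <- 0L
  prev_changed <- Inf
  repeat {
    n_iter <- n_iter + 1L
    cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(aseq),
                                      shift = pos0, width = L)[DNA, ,
                                                               drop = FALSE]
    depth <- colSums(cm)
    top <- apply(cm, 2L, which.max)
    top_n <- cm[cbind(top, seq_len(L))]
    frac <- ifelse(depth > 0, top_n / depth, 0)
    cur <- strsplit(cons, "")[[1]]
    upd <- depth >= min_depth & top_n > depth / 2  # strict majority
    new <- cur
    new[upd] <- DNA[top[upd]]
    changed <- sum(new != cur)
    cons <- paste(new, collapse = "")
    if (changed == 0L || n_iter >= max_iter) break
    prev_changed <- changed
    # re-place mismatching reads by exact-match shift against the consensus
    shifted <- replace_by_shift(aseq, pos0, cons)
    pos0 <- shifted
  }

  low_conf <- mean(depth == 0) > 0.5
  if (low_conf) {
    warning("more than half of the mtDNA has zero coverage; ",
            "consensus is reference-dominated")
  }
  structure(list(sequence = cons, depth = as.integer(depth),
                 majority_fraction = frac, n_iterations = n_iter,
                 contig = mt_contig, low_confidence = low_conf),
            class = "consensus_mt")
}

#' @export
print.consensus_mt <- function(x, ...) {
  cat("consensus_mt:", nchar(x$sequence), "bp,", x$n_iterations,
      "iteration(s), mean depth", round(mean(x$depth), 1),
      if (x$low_confidence) "(LOW CONFIDENCE)" else "", "\n")
  invisible(x)
}

# parse cigars of the form [pS] nM [qS]: left clip and aligned length
parse_simple_cigar <- function(cigar) {
  p <- parse_cigar_clips(cigar)
  list(clip_l = p$clip_l, m_len = p$m_len)
}

# try shifts -3..3 for reads that mismatch the current consensus; keep the
# original placement unless a shift gives an exact match
replace_by_shift <- function(aseq, pos0, cons) {
  L <- nchar(cons)
  tgt <- substring(cons, pos0 + 1L, pos0 + nchar(aseq))
  bad <- which(tgt != aseq)
  for (j in bad) {
    for (sh in c(-1L, 1L, -2L, 2L, -3L, 3L)) {
      p <- pos0[j] + sh
      if (p < 0L || p + nchar(aseq[j]) > L) next
      if (substr(cons, p + 1L, p + nchar(aseq[j])) == aseq[j]) {
        pos0[j] <- p
        break
      }
    }
  }
  pos0
}

#' Append an mtDNA consensus contig to a reference FASTA
#'
#' The input contigs are copied byte-identically; the consensus is added
#' as a final contig under `contig_name`. Stripping the last contig
#' recovers the input exactly.
#'
#' @param ref_fasta Path to the species reference FASTA.
#' @param consensus A [build_consensus_mt()] result, character string, or
#'   `DNAString`.
#' @param contig_name Name for the added mtDNA contig.
#' @param out Output FASTA path.
#' @return Invisibly, `out`.
#' @export
augment_reference <- function(ref_fasta, consensus, contig_name, out) {
  refs <- Biostrings::readDNAStringSet(ref_fasta)
  if (contig_name %in% names(refs)) {
    stop("contig name already present in reference: ", contig_name)
  }
  seq <- if (inherits(consensus, "consensus_mt")) consensus$sequence
         else as.character(consensus)
  add <- Biostrings::DNAStringSet(seq)
  names(add) <- contig_name
  Biostrings::writeXStringSet(c(refs, add), out)
  invisible(out)
}
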