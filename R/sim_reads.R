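# Idealized paired-end alignment simulator.
#
# Reads are drawn from the sample genome (species reference + that
# sample's polymorphic Numt insertions) and from the sample's circular
# mtDNA, then *placed* rather than aligned: a read wholly inside reference
# sequence maps concordantly; a read wholly inside an insertion maps onto
# the mtDNA contig at the segment offset the insertion was copied from; a
# read crossing an insertion junction is soft-clipped at the exact
# breakpoint. This removes the aligner as a dependency while producing the
# discordant-pair / soft-clip signal structure the caller consumes, with
# analytically predictable support counts.

#' Deterministic per-sample mtDNA (species consensus + private SNPs)
#'
#' @param cohort A [plant_numts()] cohort.
#' @param sample Sample ID.
#' @return Character string: the sample's mtDNA sequence.
#' @export
sample_mt_sequence <- function(cohort, sample) {
  sp <- sample_species(cohort, sample)
  cons <- cohort$lineage$sequences[[sp]]
  k <- cohort$config$mt_snps_per_sample
  if (k == 0L) return(cons)
  idx <- match(sample, sort(unlist(cohort$samples, use.names = FALSE)))
  with_seed(sub_seed(cohort$config$seed, 300L + idx), {
    s <- strsplit(cons, "")[[1]]
    pos <- sample.int(length(s), k)
    for (p in pos) s[p] <- sample(setdiff(DNA, s[p]), 1L)
    paste(s, collapse = "")
  })
}

#' mtDNA contig name used in a species' augmented reference
#' @param species Species name.
#' @return Character scalar, `"<species>_MT"`.
#' @export
mt_contig_name <- function(species) paste0(species, "_MT")

#' Simulate idealized paired-end alignments for one sample
#'
#' Emits a valid SAM file (with `@SQ` lines for the nuclear chromosomes
#' and the species mtDNA contig) containing nuclear fragments at
#' `config$coverage`, mtDNA fragments at `config$mt_coverage`, and the
#' junction signals of every polymorphic Numt carried by the sample.
#' Fully seeded: the same cohort + sample gives a byte-identical file.
#'
#' @param cohort A [plant_numts()] cohort.
#' @param sample Sample ID.
#' @param out_sam Output SAM path.
#' @param config Simulation config (defaults to the cohort's).
#' @return Invisibly, `out_sam`.
#' @export
simulate_alignments <- function(cohort, sample, out_sam,
                                config = cohort$config) {
  sp <- sample_species(cohort, sample)
  mt_name <- mt_contig_name(sp)
  mt_seq <- cohort$lineage$sequences[[sp]]
  mt_len <- nchar(mt_seq)
  smt <- sample_mt_sequence(cohort, sample)
  ins_all <- sample_insertions(cohort, sample)
  rl <- config$read_length

  idx <- match(sample, sort(unlist(cohort$samples, use.names = FALSE)))
  recs <- list()
  with_seed(sub_seed(config$seed, 400L + idx), {
    for (ch in cohort$genomes$chroms) {
      recs[[ch]] <- sim_chrom_fragments(
        ref = cohort$ref_seq[[sp]][[ch]], chrom = ch,
        ins = ins_all[ins_all$chrom == ch, , drop = FALSE],
        mt_name = mt_name, mt_len = mt_len, config = config, sample = sample)
    }
    recs[["MT"]] <- sim_mt_fragments(smt, mt_name, config, sample)
  })
  rec <- do.call(rbind, recs)

  sq <- c(vapply(cohort$genomes$chroms, function(ch) {
    sprintf("@SQ\tSN:%s\tLN:%d", ch, nchar(cohort$ref_seq[[sp]][[ch]]))
  }, ""), sprintf("@SQ\tSN:%s\tLN:%d", mt_name, mt_len))
  header <- c("@HD\tVN:1.6\tSO:unsorted", sq,
              sprintf("@RG\tID:%s\tSM:%s", sample, sample))
  lines <- do.call(paste, c(list(rec$qname, rec$flag, rec$rname, rec$pos,
                                 rec$mapq, rec$cigar, rec$rnext, rec$pnext,
                                 rec$tlen, rec$seq, strrep("I", rl)),
                            sep = "\t"))
  writeLines(c(header, lines), out_sam)
  invisible(out_sam)
}

# ---- nuclear fragments for one chromosome -----------------------------

sim_chrom_fragments <- function(ref, chrom, ins, mt_name, mt_len, config,
                                sample) {
  rl <- config$read_length
  ref_len <- nchar(ref)
  m <- nrow(ins)
  # sample-genome sequence and segment map (alternating ref runs/insertions)
  if (m > 0L) {
    cum_ins <- cumsum(c(0L, ins$length))[seq_len(m)]
    ins_s <- ins$ref_pos + cum_ins            # sample coord of insertion start
    pieces <- character(0); cur <- 0L
    for (k in seq_len(m)) {
      pieces <- c(pieces, substr(ref, cur + 1L, ins$ref_pos[k]), ins$seq[k])
      cur <- ins$ref_pos[k]
    }
    pieces <- c(pieces, substr(ref, cur + 1L, ref_len))
    sample_seq <- paste(pieces, collapse = "")
    seg_start <- c(0L, as.integer(rbind(ins_s, ins_s + ins$length)))
    seg_kind <- c(0L, as.integer(rbind(seq_len(m), rep(0L, m))))
    ref_off <- c(0L, as.integer(cumsum(ins$length)))  # one per ref run
  } else {
    sample_seq <- ref
    seg_start <- 0L; seg_kind <- 0L
  }
  sample_len <- nchar(sample_seq)

  n_frag <- ceiling(config$coverage * sample_len / (2 * rl))
  fl <- pmax(as.integer(round(stats::rnorm(n_frag, config$insert_mean,
                                           config$insert_sd))),
             2L * rl + 10L)
  s <- as.integer(floor(stats::runif(n_frag, 0, sample_len - fl)))
  a <- c(s, s + fl - rl)                      # read starts (R1 then R2)
  is_r2 <- rep(c(FALSE, TRUE), each = n_frag)
  frag <- rep(seq_len(n_frag), 2L)
  b <- a + rl

  i1 <- findInterval(a, seg_start)
  i2 <- findInterval(b - 1L, seg_start)
  kind1 <- seg_kind[i1]

  out <- data.frame(
    qname = paste0(sample, ":", chrom, ":", frag),
    rname = chrom, pos0 = NA_integer_, rev = is_r2,
    cigar = NA_character_, seq = NA_character_, mapped_mt = FALSE,
    stringsAsFactors = FALSE
  )
  rseq <- substring(sample_seq, a + 1L, b)

  # case A: wholly inside a reference run
  ca <- which(i1 == i2 & kind1 == 0L)
  if (m > 0L) {
    off <- integer(2L * m + 1L)
    off[seg_kind == 0L] <- ref_off
    out$pos0[ca] <- a[ca] - off[i1[ca]]
  } else {
    out$pos0[ca] <- a[ca]
  }
  out$cigar[ca] <- paste0(rl, "M")
  out$seq[ca] <- rseq[ca]

  # case B: wholly inside one insertion -> maps onto the mtDNA contig
  cb <- which(i1 == i2 & kind1 > 0L)
  for (j in cb) {
    k <- kind1[j]
    o1 <- a[j] - seg_start[i1[j]]
    r <- place_on_mt(rseq[j], o1, o1 + rl, 0L, 0L, ins$mt_start[k],
                     ins$length[k], ins$strand[k], mt_len, is_r2[j])
    out$pos0[j] <- r$pos0; out$cigar[j] <- r$cigar; out$seq[j] <- r$seq
    out$rname[j] <- mt_name; out$rev[j] <- r$rev; out$mapped_mt[j] <- TRUE
  }

  # case C: junction-spanning reads, soft-clipped at the exact breakpoint
  cc <- which(i1 != i2)
  for (j in cc) {
    cut <- seg_start[i2[j]]
    left_len <- cut - a[j]
    right_len <- b[j] - cut
    left_kind <- seg_kind[i1[j]]
    right_kind <- seg_kind[i2[j]]
    if (left_kind == 0L) {          # ref -> insertion (left junction)
      k <- right_kind
      if (left_len >= config$min_anchor) {
        off <- if (m > 0L) off_lookup(seg_kind, ref_off, i1[j]) else 0L
        out$pos0[j] <- a[j] - off
        out$cigar[j] <- paste0(left_len, "M", right_len, "S")
        out$seq[j] <- rseq[j]
      } else {                      # anchor too short: place on mt side
        r <- place_on_mt(rseq[j], 0L, right_len, left_len, 0L,
                         ins$mt_start[k], ins$length[k], ins$strand[k],
                         mt_len, is_r2[j])
        out$pos0[j] <- r$pos0; out$cigar[j] <- r$cigar; out$seq[j] <- r$seq
        out$rname[j] <- mt_name; out$rev[j] <- r$rev; out$mapped_mt[j] <- TRUE
      }
    } else {                        # insertion -> ref (right junction)
      k <- left_kind
      if (right_len >= config$min_anchor) {
        off <- if (m > 0L) off_lookup(seg_kind, ref_off, i2[j]) else 0L
        out$pos0[j] <- cut - off
        out$cigar[j] <- paste0(left_len, "S", right_len, "M")
        out$seq[j] <- rseq[j]
      } else {
        o1 <- a[j] - seg_start[i1[j]]
        r <- place_on_mt(rseq[j], o1, o1 + left_len, 0L, right_len,
                         ins$mt_start[k], ins$length[k], ins$strand[k],
                         mt_len, is_r2[j])
        out$pos0[j] <- r$pos0; out$cigar[j] <- r$cigar; out$seq[j] <- r$seq
        out$rname[j] <- mt_name; out$rev[j] <- r$rev; out$mapped_mt[j] <- TRUE
      }
    }
  }
  finalize_pairs(out, n_frag, rl, config)
}

# offsets of the ref-run containing segment i (sample - reference coords)
off_lookup <- function(seg_kind, ref_off, i) {
  ref_segs <- which(seg_kind == 0L)
  ref_off[match(i, ref_segs)]
}

# Place (part of) a read onto the linear mtDNA contig.
# rseq: full read in sample-forward orientation; [o1, o2) the insertion
# offsets covered by its aligned portion; pre/post: sample-forward clipped
# bases before/after that portion (nuclear overhangs at junctions).
place_on_mt <- function(rseq, o1, o2, pre, post, mt_start, ins_len, strand,
                        mt_len, is_r2) {
  span <- o2 - o1
  if (strand == "+") {
    u <- (mt_start + o1) %% mt_len
    seq <- rseq
    clip_l <- pre; clip_r <- post
    rev <- is_r2
  } else {
    u <- (mt_start + ins_len - o2) %% mt_len
    seq <- revcomp(rseq)
    clip_l <- post; clip_r <- pre   # revcomp swaps the clipped ends
    rev <- !is_r2
  }
  if (u + span > mt_len) {          # origin wrap: clip at the contig end
    extra <- u + span - mt_len
    span <- mt_len - u
    clip_r <- clip_r + extra
  }
  cigar <- paste0(if (clip_l > 0L) paste0(clip_l, "S") else "",
                  span, "M",
                  if (clip_r > 0L) paste0(clip_r, "S") else "")
  list(pos0 = as.integer(u), cigar = cigar, seq = seq, rev = rev)
}

# ---- mtDNA (organelle) fragments --------------------------------------

sim_mt_fragments <- function(smt, mt_name, config, sample) {
  rl <- config$read_length
  L <- nchar(smt)
  n_frag <- ceiling(config$mt_coverage * L / (2 * rl))
  fl <- pmax(as.integer(round(stats::rnorm(n_frag, config$insert_mean,
                                           config$insert_sd))),
             2L * rl + 10L)
  s <- as.integer(floor(stats::runif(n_frag, 0, L)))
  a <- c(s, s + fl - rl) %% L
  is_r2 <- rep(c(FALSE, TRUE), each = n_frag)
  frag <- rep(seq_len(n_frag), 2L)

  out <- data.frame(
    qname = paste0(sample, ":MT:", frag),
    rname = mt_name, pos0 = a, rev = is_r2,
    cigar = paste0(rl, "M"), seq = NA_character_, mapped_mt = TRUE,
    stringsAsFactors = FALSE
  )
  wraps <- a + rl > L
  out$seq[!wraps] <- substring(smt, a[!wraps] + 1L, a[!wraps] + rl)
  for (j in which(wraps)) {
    sp1 <- L - a[j]
    out$seq[j] <- paste0(substr(smt, a[j] + 1L, L), substr(smt, 1L, rl - sp1))
    out$cigar[j] <- paste0(sp1, "M", rl - sp1, "S")
  }
  finalize_pairs(out, n_frag, rl, config)
}

# ---- shared record finishing -----------------------------------------

finalize_pairs <- function(out, n_frag, rl, config) {
  r1 <- seq_len(n_frag); r2 <- n_frag + r1
  if (config$error_rate > 0) {
    n_err <- stats::rbinom(nrow(out), rl, config$error_rate)
    r <- 1L
    while (any(n_err >= r)) {  # one vectorized pass per error rank
      idx <- which(n_err >= r)
      p <- sample.int(rl, length(idx), replace = TRUE)
      cur <- substring(out$seq[idx], p, p)
      new <- DNA[(match(cur, DNA) - 1L +
                    sample.int(3L, length(idx), replace = TRUE)) %% 4L + 1L]
      seqs <- out$seq[idx]
      substr(seqs, p, p) <- new
      out$seq[idx] <- seqs
      r <- r + 1L
    }
  }
  same <- out$rname[r1] == out$rname[r2]
  span1 <- ifelse(same, pmax(out$pos0[r1], out$pos0[r2]) + rl -
                    pmin(out$pos0[r1], out$pos0[r2]), 0L)
  proper <- same & xor(out$rev[r1], out$rev[r2]) &
    span1 <= config$insert_mean + 5 * config$insert_sd
  tl1 <- ifelse(same, ifelse(out$pos0[r1] <= out$pos0[r2], span1, -span1), 0L)
  flag1 <- 1L + 64L + 16L * out$rev[r1] + 32L * out$rev[r2] + 2L * proper
  flag2 <- 1L + 128L + 16L * out$rev[r2] + 32L * out$rev[r1] + 2L * proper
  data.frame(
    qname = out$qname[c(r1, r2)],
    flag = c(flag1, flag2),
    rname = out$rname[c(r1, r2)],
    pos = out$pos0[c(r1, r2)] + 1L,
    mapq = 60L,
    cigar = out$cigar[c(r1, r2)],
    rnext = c(ifelse(same, "=", out$rname[r2]),
              ifelse(same, "=", out$rname[r1])),
    pnext = c(out$pos0[r2], out$pos0[r1]) + 1L,
    tlen = c(tl1, -tl1),
    seq = out$seq[c(r1, r2)],
    stringsAsFactors = FALSE
  )
}
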