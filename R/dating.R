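# Insertion dating from diagnostic sites between ancestral and consensus
# mtDNA, plus GC/length characterization.

#' Diagnostic-site profile between ancestral and consensus mtDNA
#'
#' Lists every position where the ancestral mtDNA (sequence at the
#' species' divergence node, `T` MY ago) differs from the present-day
#' species consensus. A Numt frozen `a` MY ago carries the derived
#' (consensus) allele at a diagnostic site exactly when the substitution
#' predates the insertion, which is what makes these sites informative
#' about insertion age.
#'
#' @param ancestral,consensus Equal-length mtDNA sequences (character).
#' @param T_div Divergence time of the ancestral sequence (MY).
#' @param species Label carried through to results.
#' @return Object of class `diagnostic_profile`: data.frame `pos`
#'   (0-based), `ancestral`, `derived`, plus attributes `T_div`,
#'   `species`, `mt_len`.
#' @export
build_profile <- function(ancestral, consensus, T_div, species = "species") {
  ancestral <- toupper(as.character(ancestral))
  consensus <- toupper(as.character(consensus))
  if (nchar(ancestral) != nchar(consensus)) {
    stop("ancestral and consensus mtDNA lengths differ (",
         nchar(ancestral), " vs ", nchar(consensus),
         "); the no-indel convention is required")
  }
  a <- strsplit(ancestral, "")[[1]]
  c_ <- strsplit(consensus, "")[[1]]
  d <- which(a != c_)
  prof <- data.frame(pos = d - 1L, ancestral = a[d], derived = c_[d],
                     stringsAsFactors = FALSE)
  structure(prof, T_div = T_div, species = species,
            mt_len = nchar(ancestral),
            class = c("diagnostic_profile", "data.frame"))
}

# per-mt-position contig alleles from a contig's mtDNA alignment
# (align_to_mt() result); returns named character vector keyed by mt pos
contig_mt_alleles <- function(hit) {
  p <- strsplit(hit$p_al, "")[[1]]
  s <- strsplit(hit$s_al, "")[[1]]
  s_pos <- cumsum(s != "-") - 1L + hit$s0   # doubled-mt coordinate
  keep <- s != "-" & p != "-"
  stats::setNames(p[keep], s_pos[keep] %% hit$mt_len)
}

#' Date one Numt from its contig and a diagnostic profile
#'
#' Aligns the contig to the doubled consensus mtDNA, reads the contig
#' allele at every diagnostic position the aligned segment covers, and
#' classifies each as derived (consensus), ancestral, or other. Sites
#' matching neither allele ("post-correction" of mismatches: private
#' nuclear mutations or assembly error) are excluded from the allele
#' ratio by default (`other_rule = "exclude"`) or counted as ancestral
#' with `other_rule = "ancestral"`. The age is
#' `(1 - f_derived) * T_div`: under uniform substitution timing a Numt
#' inserted `a` MY ago carries derived alleles for the fraction
#' `(T - a)/T` of diagnostic sites that predate it.
#'
#' @param contig Contig (or planted segment) sequence, nuclear
#'   orientation.
#' @param consensus_mt Species consensus mtDNA (character).
#' @param profile A [build_profile()] for the same species.
#' @param min_sites QC floor on covered diagnostic sites.
#' @param other_rule `"exclude"` (default) or `"ancestral"`.
#' @return One-row data.frame: `n_covered`, `n_derived`, `n_ancestral`,
#'   `n_other`, `allele_ratio`, `age`, `qc_pass`.
#' @export
date_numt <- function(contig, consensus_mt, profile, min_sites = 5L,
                      other_rule = c("exclude", "ancestral")) {
  other_rule <- match.arg(other_rule)
  T_div <- attr(profile, "T_div")
  undated <- data.frame(n_covered = 0L, n_derived = 0L, n_ancestral = 0L,
                        n_other = 0L, allele_ratio = NA_real_,
                        age = NA_real_, qc_pass = FALSE)
  hit <- align_to_mt(contig, consensus_mt)
  if (is.null(hit)) return(undated)
  alleles <- contig_mt_alleles(hit)
  at <- alleles[as.character(profile$pos)]
  cov <- !is.na(at)
  if (!sum(cov)) return(undated)
  der <- cov & at == profile$derived
  anc <- cov & at == profile$ancestral
  oth <- cov & !der & !anc
  n_der <- sum(der); n_anc <- sum(anc); n_oth <- sum(oth)
  if (other_rule == "ancestral") {
    n_anc <- n_anc + n_oth
    n_oth2 <- 0L
  } else n_oth2 <- n_oth
  denom <- n_der + n_anc
  ratio <- if (denom > 0L) n_der / denom else NA_real_
  age <- if (is.na(ratio)) NA_real_ else (1 - ratio) * T_div
  data.frame(n_covered = sum(cov), n_derived = n_der, n_ancestral = n_anc,
             n_other = n_oth2, allele_ratio = ratio, age = age,
             qc_pass = sum(cov) >= min_sites && denom > 0L)
}

#' Insertion-rate histogram (counts per 1-MY age bin)
#'
#' @param ages data.frame with `species` and `age` (MY); rows with `NA`
#'   age (undated) are excluded and reported.
#' @param bin Bin width in MY.
#' @return List: `histogram` (data.frame species, bin_lo, bin_hi,
#'   count), `n_undated`.
#' @export
insertion_rate_histogram <- function(ages, bin = 1) {
  if (!nrow(ages)) stop("no dated NumtS to bin")
  undated <- sum(is.na(ages$age))
  x <- ages[!is.na(ages$age), , drop = FALSE]
  if (!nrow(x)) stop("no dated NumtS to bin")
  x$bin_lo <- floor(x$age / bin) * bin
  agg <- stats::aggregate(list(count = x$age),
                          by = list(species = x$species, bin_lo = x$bin_lo),
                          FUN = length)
  agg$bin_hi <- agg$bin_lo + bin
  agg <- agg[order(agg$species, agg$bin_lo),
             c("species", "bin_lo", "bin_hi", "count")]
  rownames(agg) <- NULL
  list(histogram = agg, n_undated = undated)
}

#' GC and length characterization of Numt sequences
#'
#' @param seqs Named character vector of Numt sequences.
#' @param class Parallel class labels (e.g. "polymorphic"/"reference").
#' @param mt_seq Parent mtDNA for the GC baseline.
#' @return List: `table` (per-Numt GC%, length, class), `summary`
#'   (per-class mean/median GC and length), `mt_gc`.
#' @export
characterize_numts <- function(seqs, class = rep("polymorphic",
                                                 length(seqs)),
                               mt_seq = NULL) {
  tab <- data.frame(name = names(seqs), class = class,
                    length = nchar(seqs), gc = gc_percent(seqs),
                    row.names = NULL, stringsAsFactors = FALSE)
  sm <- do.call(rbind, lapply(split(tab, tab$class), function(x) {
    data.frame(class = x$class[1L], n = nrow(x),
               mean_gc = mean(x$gc), median_gc = stats::median(x$gc),
               mean_length = mean(x$length),
               median_length = stats::median(x$length))
  }))
  rownames(sm) <- NULL
  list(table = tab, summary = sm,
       mt_gc = if (is.null(mt_seq)) NA_real_ else gc_percent(mt_seq))
}

#' GC content of the nuclear flanks of breakpoints
#'
#' @param ref_seq Chromosome sequence.
#' @param pos Breakpoint positions (0-based).
#' @param flank Flank width on either side (bp).
#' @return Numeric vector: GC% of the joined 2 x `flank` bp flanks.
#' @export
flank_gc <- function(ref_seq, pos, flank = 100L) {
  L <- nchar(ref_seq)
  vapply(pos, function(p) {
    left <- substr(ref_seq, max(1L, p - flank + 1L), p)
    right <- substr(ref_seq, p + 1L, min(L, p + flank))
    gc_percent(paste0(left, right))
  }, 0)
}
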