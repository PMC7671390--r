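# Internal helpers: circular-coordinate arithmetic, seeded RNG, sequence utils.
# All internal coordinates are 0-based half-open; mtDNA segments use
# (start, end) with end <= start meaning the segment wraps the origin.

DNA <- c("A", "C", "G", "T")

#' Length of a circular mtDNA segment
#'
#' Segments are 0-based half-open `(start, end)` on a circle of length
#' `len`; `end <= start` denotes a segment wrapping the replication origin
#' (as D-loop-spanning fragments do).
#'
#' @param start,end Integer vectors, 0-based half-open circular interval.
#' @param len Circle (mtDNA) length in bp.
#' @return Integer vector of segment lengths in `[1, len]`.
#' @export
circ_length <- function(start, end, len) {
  ifelse(end > start, end - start, len - start + end)
}

#' Extract a circular segment from a sequence
#'
#' @param seq A single character string (the circular sequence).
#' @param start,end 0-based half-open circular interval (`end <= start`
#'   wraps the origin).
#' @return Character string of length `circ_length(start, end, nchar(seq))`.
#' @export
circ_extract <- function(seq, start, end) {
  len <- nchar(seq)
  stopifnot(start >= 0, start < len, end >= 0, end <= len)
  if (end > start) {
    substr(seq, start + 1L, end)
  } else {
    paste0(substr(seq, start + 1L, len), substr(seq, 1L, end))
  }
}

# circular containment: does segment (s,e) fully contain gene (gs,ge)?
# Both 0-based half-open on a circle of length len.
circ_contains <- function(s, e, gs, ge, len) {
  seg_len <- circ_length(s, e, len)
  gene_len <- circ_length(gs, ge, len)
  offset <- (gs - s) %% len
  # a full-circle segment contains every gene regardless of phase
  offset + gene_len <= seg_len | seg_len == len
}

#' Reverse complement of a DNA string
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded package operations do not
#' perturb the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a sub-seed deterministically, kept well below .Machine$integer.max
sub_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + (offset %% 1000L)
}

# random DNA string(s)
random_dna <- function(n) {
  paste(sample(DNA, n, replace = TRUE), collapse = "")
}

# count mismatches between two equal-length strings (fast, byte-wise)
str_mismatches <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# GC percent of a character string; ambiguity codes ignored in the denominator
#' GC content of sequences
#' @param x Character vector of DNA sequences.
#' @return Numeric vector, GC percent = (G+C)/(A+C+G+T) * 100.
#' @export
gc_percent <- function(x) {
  ss <- Biostrings::DNAStringSet(x)
  f <- Biostrings::letterFrequency(ss, letters = c("A", "C", "G", "T"))
  unname(100 * (f[, "G"] + f[, "C"]) / pmax(rowSums(f), 1L))
}

# weighted median (lower of the two central values on ties) -- deterministic
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}
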