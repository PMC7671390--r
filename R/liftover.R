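# Cross-species coordinate unification through UCSC chain files.

#' Validate and import a UCSC chain file
#'
#' Runs a light structural validation (field counts, numeric fields,
#' block-sum consistency) that reports the offending line number, then
#' imports through [rtracklayer::import.chain()].
#'
#' @param path Chain file path.
#' @return An [rtracklayer::Chain] object.
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (grepl("^\\s*$", lines[i])) { i <- i + 1L; next }
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (f[1L] != "chain" || !(length(f) %in% c(12L, 13L))) {
      stop("malformed chain header at line ", i, " of ", path)
    }
    tlen <- as.numeric(f[7L]) - as.numeric(f[6L])
    qlen <- as.numeric(f[12L]) - as.numeric(f[11L])
    tsum <- 0; qsum <- 0
    repeat {
      i <- i + 1L
      if (i > n) stop("truncated chain block at line ", i, " of ", path)
      b <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (any(is.na(suppressWarnings(as.numeric(b))))) {
        stop("malformed chain data at line ", i, " of ", path)
      }
      if (length(b) == 1L) {
        tsum <- tsum + as.numeric(b[1L]); qsum <- qsum + as.numeric(b[1L])
        break
      }
      if (length(b) != 3L) stop("malformed chain data at line ", i,
                                " of ", path)
      tsum <- tsum + as.numeric(b[1L]) + as.numeric(b[2L])
      qsum <- qsum + as.numeric(b[1L]) + as.numeric(b[3L])
    }
    if (tsum != tlen || qsum != qlen) {
      stop("chain block sums do not match the header span ending at line ",
           i, " of ", path)
    }
    i <- i + 1L
  }
  rtracklayer::import.chain(path)
}

#' Lift intervals to the frame genome through a chain
#'
#' Block-arithmetic interval mapping with explicit UCSC-liftOver-style
#' semantics: an interval maps when at least `min_map_ratio` of its bases
#' land on one frame chromosome and strand; the result interval spans the
#' outermost mapped bases. Intervals whose mapped bases straddle several
#' chromosomes/strands fail as `"split"`; those with insufficient mapped
#' bases fail as `"unmapped"`.
#'
#' @param x data.frame with `chrom`, `start`, `end` (0-based half-open;
#'   an `end` equal to `start + 1` is a breakpoint).
#' @param chain An [read_chain()] result (or path).
#' @param min_map_ratio Minimum fraction of mapped bases.
#' @return `x` plus columns `status` (`mapped|split|unmapped`),
#'   `h_chrom`, `h_start`, `h_end`, `h_strand`.
#' @export
liftover_intervals <- function(x, chain, min_map_ratio = 0.95) {
  if (is.character(chain)) chain <- read_chain(chain)
  gr <- GenomicRanges::GRanges(x$chrom,
                               IRanges::IRanges(x$start + 1L, x$end))
  lifted <- rtracklayer::liftOver(gr, chain)
  out <- x
  out$status <- "unmapped"
  out$h_chrom <- NA_character_
  out$h_start <- NA_integer_
  out$h_end <- NA_integer_
  out$h_strand <- NA_character_
  for (i in seq_along(lifted)) {
    p <- lifted[[i]]
    if (!length(p)) next
    covered <- sum(GenomicRanges::width(p))
    if (covered < min_map_ratio * (x$end[i] - x$start[i])) next
    chroms <- unique(as.character(GenomicRanges::seqnames(p)))
    strands <- unique(as.character(GenomicRanges::strand(p)))
    if (length(chroms) > 1L || length(strands) > 1L) {
      out$status[i] <- "split"
      next
    }
    out$status[i] <- "mapped"
    out$h_chrom[i] <- chroms
    out$h_start[i] <- min(GenomicRanges::start(p)) - 1L
    out$h_end[i] <- max(GenomicRanges::end(p))
    out$h_strand[i] <- strands
  }
  out
}

#' Unify species calls into the frame coordinate system
#'
#' Lifts call breakpoints through the species chain and returns the
#' frame-coordinate call table; calls failing liftover are retained with
#' their failure status so sharing denominators can exclude them
#' explicitly.
#'
#' @param calls Calls data.frame with `chrom` and `pos` (breakpoints).
#' @param chain Chain (or path) mapping species (target) to frame
#'   (query).
#' @param species Origin species label.
#' @param class Call class label (`"polymorphic"` or `"fixed"`).
#' @return data.frame of unified calls: origin columns plus `status`,
#'   `h_chrom`, `h_pos`.
#' @export
unify_calls <- function(calls, chain, species, class = "polymorphic") {
  if (nrow(calls) == 0L) {
    return(data.frame(species = character(), class = character(),
                      chrom = character(), pos = integer(),
                      status = character(), h_chrom = character(),
                      h_pos = integer(), stringsAsFactors = FALSE))
  }
  x <- data.frame(chrom = calls$chrom, start = calls$pos,
                  end = calls$pos + 1L, stringsAsFactors = FALSE)
  lifted <- liftover_intervals(x, chain, min_map_ratio = 1)
  data.frame(species = species, class = class, chrom = calls$chrom,
             pos = calls$pos, status = lifted$status,
             h_chrom = lifted$h_chrom, h_pos = lifted$h_start,
             stringsAsFactors = FALSE)
}
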