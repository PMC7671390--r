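# Per-species genome construction over a shared "base" coordinate frame.
#
# Every genome (the frame species and each other species) is expressed as
# the base genome plus an ordered table of events in base coordinates:
#   - small indels private to a species (ins_len / del_len, no id)
#   - planted Numt insertions (ins_len, id shared across all genomes that
#     inherit the insertion)
# A deletion at p removes base interval [p, p+del_len); an insertion at p
# sits immediately before base p. This bookkeeping gives exact coordinate
# maps between any species and the frame genome, from which UCSC chains
# are emitted.

#' Build per-species genomes and the base coordinate frame
#'
#' Generates a random base genome and, for every non-frame species, a set
#' of seeded small indels that distinguish its genome from the frame
#' (emulating the inter-species alignment gaps that give chain files their
#' block structure). Numt insertions are added later by [plant_numts()].
#'
#' @param tree A [species_tree()].
#' @param config A [sim_config()].
#' @param frame Frame (coordinate-reference) species; must be a tip.
#' @param seed Integer seed (defaults to `config$seed`).
#' @return Object of class `numt_genomes`.
#' @export
build_genomes <- function(tree, config, frame = "human", seed = config$seed) {
  stopifnot(inherits(tree, "numt_tree"), inherits(config, "sim_config"))
  if (!frame %in% tree_species(tree)) stop("frame species not in tree: ", frame)
  chrom_len <- floor(config$genome_length / config$n_chroms)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  base_len <- stats::setNames(rep(chrom_len, config$n_chroms), chroms)

  species <- tree_species(tree)
  base_seq <- list()
  indels <- stats::setNames(vector("list", length(species)), species)

  with_seed(sub_seed(seed, 11L), {
    for (ch in chroms) base_seq[[ch]] <- random_dna(chrom_len)
    for (sp in species) {
      if (sp == frame) {
        indels[[sp]] <- empty_events()
        next
      }
      evs <- list()
      for (ch in chroms) {
        n <- stats::rpois(1L, config$nuclear_indel_rate * chrom_len)
        if (n == 0L) next
        pos <- sort(sample.int(chrom_len - 2000L, n) + 1000L)
        # keep events well separated so bookkeeping stays unambiguous
        keep <- c(TRUE, diff(pos) > 200L)
        pos <- pos[keep]; n <- length(pos)
        sizes <- sample(1:50, n, replace = TRUE)
        is_ins <- stats::runif(n) < 0.5
        evs[[ch]] <- data.frame(
          chrom = ch, base_pos = pos,
          ins_len = ifelse(is_ins, sizes, 0L),
          del_len = ifelse(is_ins, 0L, sizes),
          seq = ifelse(is_ins, vapply(sizes, random_dna, ""), ""),
          id = NA_character_, stringsAsFactors = FALSE
        )
      }
      indels[[sp]] <- if (length(evs)) do.call(rbind, evs) else empty_events()
    }
  })

  structure(list(tree = tree, config = config, frame = frame,
                 chroms = chroms, base_len = base_len,
                 base_seq = base_seq, indels = indels),
            class = "numt_genomes")
}

empty_events <- function() {
  data.frame(chrom = character(), base_pos = integer(), ins_len = integer(),
             del_len = integer(), seq = character(), id = character(),
             stringsAsFactors = FALSE)
}

# ---- coordinate maps --------------------------------------------------

# map base coordinates -> genome coordinates for one chromosome's events.
# Returns NA for bases removed by a deletion.
map_base_to_genome <- function(pos, events) {
  if (nrow(events) == 0L) return(pos)
  ev <- events[order(events$base_pos), , drop = FALSE]
  shift <- cumsum(ev$ins_len - ev$del_len)
  idx <- findInterval(pos, ev$base_pos)
  out <- pos + ifelse(idx == 0L, 0L, shift[idx])
  dels <- ev[ev$del_len > 0L, , drop = FALSE]
  if (nrow(dels)) {
    j <- findInterval(pos, dels$base_pos)
    bad <- j > 0L & pos < dels$base_pos[pmax(j, 1L)] + dels$del_len[pmax(j, 1L)]
    out[bad] <- NA_integer_
  }
  out
}

# genome length after applying events
genome_length_after <- function(base_len, events) {
  base_len + sum(events$ins_len) - sum(events$del_len)
}

# materialize a genome sequence for one chromosome
apply_events <- function(base, events) {
  if (nrow(events) == 0L) return(base)
  ev <- events[order(events$base_pos), , drop = FALSE]
  pieces <- character(0)
  cur <- 0L
  for (k in seq_len(nrow(ev))) {
    p <- ev$base_pos[k]
    if (p > cur) pieces <- c(pieces, substr(base, cur + 1L, p))
    if (ev$ins_len[k] > 0L) {
      pieces <- c(pieces, ev$seq[k])
      cur <- p
    } else {
      cur <- p + ev$del_len[k]
    }
  }
  if (cur < nchar(base)) pieces <- c(pieces, substr(base, cur + 1L, nchar(base)))
  paste(pieces, collapse = "")
}

# ---- chain construction ----------------------------------------------

# aligned blocks between a species genome (target) and the frame genome
# (query) for one chromosome, from the two event tables.
# Returns data.frame(size, t_start, q_start) in 0-based coordinates.
chain_blocks <- function(events_s, events_f, base_len) {
  key <- function(e) paste(e$base_pos, ifelse(is.na(e$id), "", e$id))
  all_pos <- sort(unique(c(events_s$base_pos, events_f$base_pos)))
  blocks <- list()
  cur_base <- 0L; t_pos <- 0L; q_pos <- 0L
  emit <- function(size) {
    if (size > 0L) blocks[[length(blocks) + 1L]] <<-
        c(size = size, t_start = t_pos, q_start = q_pos)
  }
  for (p in all_pos) {
    run <- p - cur_base
    emit(run); t_pos <- t_pos + run; q_pos <- q_pos + run
    es <- events_s[events_s$base_pos == p, , drop = FALSE]
    ef <- events_f[events_f$base_pos == p, , drop = FALSE]
    # shared Numt insertion -> aligned block over the inserted sequence
    shared <- intersect(es$id[!is.na(es$id)], ef$id[!is.na(ef$id)])
    adv_base <- 0L
    for (i in seq_len(nrow(es))) {
      if (!is.na(es$id[i]) && es$id[i] %in% shared) next
      if (es$ins_len[i] > 0L) t_pos <- t_pos + es$ins_len[i]
      if (es$del_len[i] > 0L) {
        q_pos <- q_pos + es$del_len[i]
        adv_base <- adv_base + es$del_len[i]
      }
    }
    for (i in seq_len(nrow(ef))) {
      if (!is.na(ef$id[i]) && ef$id[i] %in% shared) next
      if (ef$ins_len[i] > 0L) q_pos <- q_pos + ef$ins_len[i]
      if (ef$del_len[i] > 0L) {
        t_pos <- t_pos + ef$del_len[i]
        adv_base <- adv_base + ef$del_len[i]
      }
    }
    if (length(shared)) {
      len <- es$ins_len[match(shared[1L], es$id)]
      emit(len); t_pos <- t_pos + len; q_pos <- q_pos + len
    }
    cur_base <- p + adv_base
  }
  emit(base_len - cur_base)
  if (!length(blocks)) return(data.frame(size = integer(), t_start = integer(),
                                         q_start = integer()))
  bl <- as.data.frame(do.call(rbind, blocks))
  # merge blocks contiguous on both genomes
  if (nrow(bl) > 1L) {
    keep <- rep(TRUE, nrow(bl))
    for (k in 2:nrow(bl)) {
      prev <- max(which(keep[1:(k - 1L)]))
      if (bl$t_start[k] == bl$t_start[prev] + bl$size[prev] &&
          bl$q_start[k] == bl$q_start[prev] + bl$size[prev]) {
        bl$size[prev] <- bl$size[prev] + bl$size[k]
        keep[k] <- FALSE
      }
    }
    bl <- bl[keep, , drop = FALSE]
  }
  rownames(bl) <- NULL
  bl
}

# serialize blocks for all chromosomes of one species into UCSC chain text
chain_text <- function(blocks_by_chrom, t_sizes, q_sizes) {
  out <- character(0)
  id <- 0L
  for (ch in names(blocks_by_chrom)) {
    bl <- blocks_by_chrom[[ch]]
    if (nrow(bl) == 0L) next
    id <- id + 1L
    fmt <- function(x) formatC(x, format = "d")
    t_end <- bl$t_start[nrow(bl)] + bl$size[nrow(bl)]
    q_end <- bl$q_start[nrow(bl)] + bl$size[nrow(bl)]
    header <- paste("chain", fmt(sum(bl$size)), ch, fmt(t_sizes[[ch]]),
                    "+", fmt(bl$t_start[1L]), fmt(t_end), ch,
                    fmt(q_sizes[[ch]]), "+", fmt(bl$q_start[1L]),
                    fmt(q_end), id)
    lines <- character(nrow(bl))
    for (k in seq_len(nrow(bl))) {
      if (k < nrow(bl)) {
        dt <- bl$t_start[k + 1L] - (bl$t_start[k] + bl$size[k])
        dq <- bl$q_start[k + 1L] - (bl$q_start[k] + bl$size[k])
        lines[k] <- paste(fmt(bl$size[k]), fmt(dt), fmt(dq))
      } else {
        lines[k] <- fmt(bl$size[k])
      }
    }
    out <- c(out, header, lines, "")
  }
  out
}
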