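#' Evolve an mtDNA lineage along a species tree
#'
#' Simulates circular mtDNA evolution from a root sequence down every
#' branch of the tree under a Jukes-Cantor model (uniform substitution
#' rates, no indels, so all node sequences share one coordinate system).
#' Substitution counts per branch are Poisson with mean
#' `rate * branch_length_MY * sequence_length`; event times are uniform on
#' the branch. Every event is recorded, so the sequence at any historical
#' time point on any lineage can be reconstructed exactly (the substrate
#' both of Numt planting and of diagnostic-site dating).
#'
#' @param tree A [species_tree()].
#' @param root_seq Character string, the mtDNA at the root (ACGT only,
#'   >= 1 kb).
#' @param rate Substitutions per site per MY (> 0 allowed to be 0 for the
#'   degenerate identity case).
#' @param seed Integer seed; identical inputs give identical lineages.
#' @return An object of class `mt_lineage`: `sequences` (named character
#'   vector, one per tree node), `events` (data.frame with `node` = child
#'   node of the branch, `pos` 0-based, `from`, `to`, `time_my` before
#'   present), `length`, and the `tree`.
#' @export
evolve_mt <- function(tree, root_seq, rate, seed = 1L) {
  stopifnot(inherits(tree, "numt_tree"), rate >= 0)
  root_seq <- toupper(root_seq)
  if (nchar(root_seq) < 1000L) stop("root mtDNA must be >= 1 kb")
  if (grepl("[^ACGT]", root_seq)) stop("root mtDNA must contain only ACGT")
  len <- nchar(root_seq)
  phy <- tree$phylo
  root_lab <- node_label(tree, length(phy$tip.label) + 1L)

  seqs <- character(0)
  seqs[root_lab] <- root_seq
  events <- list()

  with_seed(seed, {
    # walk edges parent-before-child (ape's default cladewise order)
    for (i in seq_len(nrow(phy$edge))) {
      par <- node_label(tree, phy$edge[i, 1])
      chl <- node_label(tree, phy$edge[i, 2])
      t_old <- divergence_time(tree, par)
      t_young <- divergence_time(tree, chl)
      n_sub <- stats::rpois(1L, rate * (t_old - t_young) * len)
      s <- strsplit(seqs[[par]], "")[[1]]
      if (n_sub > 0L) {
        pos <- sample.int(len, n_sub, replace = TRUE) - 1L
        times <- stats::runif(n_sub, t_young, t_old)
        o <- order(times, decreasing = TRUE)  # oldest applied first
        pos <- pos[o]; times <- times[o]
        from <- character(n_sub); to <- character(n_sub)
        for (k in seq_len(n_sub)) {
          from[k] <- s[pos[k] + 1L]
          to[k] <- sample(setdiff(DNA, from[k]), 1L)
          s[pos[k] + 1L] <- to[k]
        }
        events[[chl]] <- data.frame(
          node = chl, pos = pos, from = from, to = to, time_my = times,
          stringsAsFactors = FALSE
        )
      }
      seqs[chl] <- paste(s, collapse = "")
    }
  })

  ev <- if (length(events)) do.call(rbind, events) else {
    data.frame(node = character(), pos = integer(), from = character(),
               to = character(), time_my = numeric())
  }
  rownames(ev) <- NULL
  structure(list(sequences = seqs, events = ev, length = len, tree = tree),
            class = "mt_lineage")
}

#' @export
print.mt_lineage <- function(x, ...) {
  cat("mt_lineage:", x$length, "bp,", nrow(x$events), "substitution events,",
      length(x$sequences), "node sequences\n")
  invisible(x)
}

#' Reconstruct the mtDNA of a lineage at a historical time point
#'
#' Starting from the present-day (or node) sequence of `node`, undoes all
#' recorded substitutions younger than `age` along the path from the root,
#' yielding the mtDNA exactly as it existed `age` MY before the present.
#' `age` may exceed the node's own depth, in which case ancestors' branches
#' are unwound too (up to the root).
#'
#' @param lineage An [evolve_mt()] result.
#' @param node Node label (tip or internal).
#' @param age MY before present; must not exceed the root depth.
#' @return Character string of length `lineage$length`.
#' @export
mt_sequence_at <- function(lineage, node, age) {
  tree <- lineage$tree
  stopifnot(age >= 0)
  if (age > max(tree$depth)) stop("age predates the tree root")
  node_depth <- divergence_time(tree, node)
  if (age < node_depth) {
    stop("age ", age, " is younger than node ", node, " (", node_depth, " MY)")
  }
  path <- root_path(tree, node)
  ev <- lineage$events[lineage$events$node %in% path, , drop = FALSE]
  ev <- ev[ev$time_my < age, , drop = FALSE]
  s <- strsplit(lineage$sequences[[node]], "")[[1]]
  if (nrow(ev)) {
    # undo youngest first so positions hit repeatedly resolve correctly
    ev <- ev[order(ev$time_my), , drop = FALSE]
    for (k in seq_len(nrow(ev))) s[ev$pos[k] + 1L] <- ev$from[k]
  }
  paste(s, collapse = "")
}
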