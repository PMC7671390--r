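# Cross-species sharing of unified insertion sites and ancestral-node
# assignment.

#' Shared events between two unified call lists
#'
#' Greedy nearest-neighbour matching of frame-coordinate breakpoints
#' within `window` bp; each call matches at most once; candidate pairs
#' are taken in order of increasing distance (ties resolve to the smaller
#' coordinates), so the result is deterministic.
#'
#' @param a,b data.frames with `h_chrom` and `h_pos` (only rows with
#'   non-`NA` positions are considered).
#' @param window Maximum breakpoint distance (bp).
#' @return List: `shared` (count) and `pairs` (data.frame of matched row
#'   indices `i` in `a`, `j` in `b`, and `dist`).
#' @export
pairwise_shared <- function(a, b, window = 500L) {
  ai <- which(!is.na(a$h_pos))
  bi <- which(!is.na(b$h_pos))
  cand <- list()
  for (i in ai) {
    js <- bi[b$h_chrom[bi] == a$h_chrom[i] &
               abs(b$h_pos[bi] - a$h_pos[i]) <= window]
    if (length(js)) {
      cand[[length(cand) + 1L]] <- data.frame(
        i = i, j = js, dist = abs(b$h_pos[js] - a$h_pos[i]))
    }
  }
  if (!length(cand)) {
    return(list(shared = 0L,
                pairs = data.frame(i = integer(), j = integer(),
                                   dist = integer())))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$dist, a$h_pos[cand$i], b$h_pos[cand$j]), ,
               drop = FALSE]
  used_i <- logical(nrow(a)); used_j <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_i[cand$i[k]] && !used_j[cand$j[k]]) {
      keep[k] <- TRUE
      used_i[cand$i[k]] <- TRUE
      used_j[cand$j[k]] <- TRUE
    }
  }
  pairs <- cand[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  list(shared = nrow(pairs), pairs = pairs)
}

#' Pairwise sharing matrix across species
#'
#' @param call_lists Named list: species -> unified call data.frame.
#' @param window Matching window (bp).
#' @return Symmetric integer matrix; the diagonal holds each species'
#'   mapped call count.
#' @export
sharing_matrix <- function(call_lists, window = 500L) {
  sp <- names(call_lists)
  m <- matrix(0L, length(sp), length(sp), dimnames = list(sp, sp))
  for (i in seq_along(sp)) {
    m[i, i] <- sum(!is.na(call_lists[[i]]$h_pos))
    if (i < length(sp)) for (j in (i + 1L):length(sp)) {
      s <- pairwise_shared(call_lists[[i]], call_lists[[j]], window)$shared
      m[i, j] <- m[j, i] <- s
    }
  }
  m
}

#' Ancestral events at each divergence node of the frame lineage
#'
#' Walking the frame species' lineage from the shallowest divergence node
#' toward the root, an event is ancestral at a node when it is present in
#' the frame species and, for every node up to and including that one,
#' matched (within `window`) in at least one species of the clade that
#' diverged there. This cumulative definition makes the node sets nested:
#' deeper nodes can only lose events.
#'
#' @param call_lists Named list: species -> unified calls (must include
#'   the frame species).
#' @param tree A [species_tree()].
#' @param frame Frame species name.
#' @param window Matching window (bp).
#' @return List per node (shallowest first): `node`, `time`, `clade`,
#'   `count`, `events` (frame-call rows ancestral at that node).
#' @export
ancestral_nodes <- function(call_lists, tree, frame = "human",
                            window = 500L) {
  if (!frame %in% names(call_lists)) {
    stop("frame species '", frame, "' missing from call lists")
  }
  fr <- call_lists[[frame]]
  nodes <- frame_lineage_nodes(tree, frame)
  matched <- matrix(FALSE, nrow(fr), length(call_lists),
                    dimnames = list(NULL, names(call_lists)))
  for (sp in setdiff(names(call_lists), frame)) {
    pr <- pairwise_shared(fr, call_lists[[sp]], window)$pairs
    matched[pr$i, sp] <- TRUE
  }
  ok <- !is.na(fr$h_pos)
  out <- list()
  for (nd in nodes) {
    clade <- intersect(nd$clade, colnames(matched))
    hit <- if (length(clade)) {
      rowSums(matched[, clade, drop = FALSE]) > 0L
    } else rep(FALSE, nrow(fr))
    ok <- ok & hit
    out[[nd$node]] <- list(node = nd$node, time = nd$time, clade = nd$clade,
                           count = sum(ok),
                           events = fr[ok, , drop = FALSE])
  }
  out
}
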