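#' Species tree with divergence times
#'
#' Wraps an [ape::phylo] tree into the container the simulator and the
#' comparative analyses consume. The tree must be ultrametric (all tips at
#' the present, branch lengths in million years, MY) with at least two
#' tips. Internal nodes are labelled; unlabelled nodes receive generated
#' labels `n<k>`.
#'
#' @param x A newick string, a path to a newick file, or an [ape::phylo].
#' @return An object of class `numt_tree`: the `phylo` plus cached node
#'   depths (divergence times, MY before present).
#' @examples
#' tr <- species_tree("((human:6,chimp:6)hominini:19,macaque:25)root;")
#' divergence_time(tr, "hominini")
#' @export
species_tree <- function(x) {
  phy <- if (inherits(x, "phylo")) {
    x
  } else if (is.character(x) && length(x) == 1L && grepl(";", x)) {
    ape::read.tree(text = x)
  } else {
    ape::read.tree(x)
  }
  if (is.null(phy)) stop("could not parse tree")
  if (length(phy$tip.label) < 2L) stop("species tree needs >= 2 tips")
  if (is.null(phy$edge.length)) stop("species tree needs branch lengths (MY)")
  if (!ape::is.ultrametric(phy, tol = 1e-6)) {
    stop("species tree must be ultrametric (all tips at the present)")
  }
  n_int <- phy$Nnode
  if (is.null(phy$node.label) || any(phy$node.label == "")) {
    lab <- phy$node.label
    if (is.null(lab)) lab <- rep("", n_int)
    lab[lab == ""] <- paste0("n", which(lab == ""))
    phy$node.label <- lab
  }
  # depth = time before present of each node (tips ~ 0)
  from_root <- ape::node.depth.edgelength(phy)
  depth <- max(from_root) - from_root
  depth[depth < 1e-9] <- 0
  names(depth) <- c(phy$tip.label, phy$node.label)
  structure(list(phylo = phy, depth = depth), class = "numt_tree")
}

#' @export
print.numt_tree <- function(x, ...) {
  cat("numt_tree:", length(x$phylo$tip.label), "species;",
      "root at", max(x$depth), "MY\n")
  cat("  tips:", paste(x$phylo$tip.label, collapse = ", "), "\n")
  invisible(x)
}

#' Tree species (tip labels)
#' @param tree A [species_tree()].
#' @return Character vector of species names.
#' @export
tree_species <- function(tree) tree$phylo$tip.label

#' Divergence time of a node
#' @param tree A [species_tree()].
#' @param node Node label (tip or internal).
#' @return Time before present in MY (0 for tips).
#' @export
divergence_time <- function(tree, node) {
  if (!node %in% names(tree$depth)) stop("unknown node: ", node)
  unname(tree$depth[node])
}

# internal: node id from label
node_id <- function(tree, label) {
  phy <- tree$phylo
  all <- c(phy$tip.label, phy$node.label)
  i <- match(label, all)
  if (is.na(i)) stop("unknown node: ", label)
  i
}

node_label <- function(tree, id) {
  c(tree$phylo$tip.label, tree$phylo$node.label)[id]
}

# internal: parent node label, NA for root
node_parent <- function(tree, label) {
  phy <- tree$phylo
  id <- node_id(tree, label)
  e <- phy$edge[phy$edge[, 2] == id, 1]
  if (length(e) == 0L) return(NA_character_)
  node_label(tree, e)
}

# internal: labels on the path from the root to `label` (inclusive)
root_path <- function(tree, label) {
  path <- label
  p <- node_parent(tree, label)
  while (!is.na(p)) {
    path <- c(p, path)
    p <- node_parent(tree, p)
  }
  path
}

# internal: tip labels descending from node `label`
node_tips <- function(tree, label) {
  phy <- tree$phylo
  id <- node_id(tree, label)
  if (id <= length(phy$tip.label)) return(label)
  kids <- phy$edge[phy$edge[, 1] == id, 2]
  unlist(lapply(kids, function(k) node_tips(tree, node_label(tree, k))))
}

# internal: time span (young, old) of the branch above `label`
branch_span <- function(tree, label) {
  p <- node_parent(tree, label)
  if (is.na(p)) stop("node ", label, " is the root; it has no branch above")
  c(young = divergence_time(tree, label), old = divergence_time(tree, p))
}

# internal: internal nodes on the lineage of `frame` tip, shallowest first,
# each with its sister clade (the species that diverged at that node)
frame_lineage_nodes <- function(tree, frame) {
  path <- root_path(tree, frame)        # root ... frame
  ints <- rev(path[-length(path)])      # shallowest internal node first
  lapply(ints, function(nd) {
    kids <- tree$phylo$edge[tree$phylo$edge[, 1] == node_id(tree, nd), 2]
    kid_labs <- node_label(tree, kids)
    on_path <- kid_labs %in% path | kid_labs == frame
    sister <- unlist(lapply(kid_labs[!on_path], node_tips, tree = tree))
    list(node = nd, time = divergence_time(tree, nd), clade = sister)
  })
}
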