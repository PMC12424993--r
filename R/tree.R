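#' Read a rooted subline phylogeny from a Newick file
#'
#' Leaves are the subline names. The tree may be multifurcating; internal
#' nodes without labels are given stable labels (`N1`, `N2`, ...) in
#' preorder so that placements can be referenced across sessions.
#'
#' @param path Path to a Newick file.
#' @return An object of class `phylo` (from \pkg{ape}), validated and with
#'   internal node labels filled in.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(path)),
    error = function(e) stop("Newick parse failure in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) {
    stop("Newick parse failure in '", path, "': no tree found", call. = FALSE)
  }
  validate_tree(tree)
}

#' Write a phylogeny to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Validate a subline phylogeny
#'
#' Checks that the tree is rooted, that leaf labels are unique and
#' non-empty, and fills in missing internal-node labels.
#'
#' @param tree A `phylo` object.
#' @return The validated (possibly relabelled) tree.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  labs <- tree$tip.label
  if (any(is.na(labs)) || any(!nzchar(labs))) {
    stop("all leaves must be labelled with non-empty subline names",
         call. = FALSE)
  }
  if (anyDuplicated(labs)) {
    stop("duplicate leaf labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  }
  nint <- tree$Nnode
  if (is.null(tree$node.label) || length(tree$node.label) != nint ||
      any(is.na(tree$node.label)) || any(!nzchar(tree$node.label))) {
    lab <- if (is.null(tree$node.label)) character(nint) else tree$node.label
    lab[is.na(lab) | !nzchar(lab)] <-
      paste0("N", which(is.na(lab) | !nzchar(lab)))
    tree$node.label <- lab
  }
  tree
}

root_node <- function(tree) length(tree$tip.label) + 1L

#' Node label for an internal or tip node id
#'
#' @param tree A `phylo` object.
#' @param node Integer node id(s) in ape numbering (tips `1..n`, internal
#'   nodes `n+1..`).
#' @return Character label(s): the subline name for tips, the internal node
#'   label otherwise.
#' @export
node_label <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- character(length(node))
  tip <- node <= ntip
  out[tip] <- tree$tip.label[node[tip]]
  out[!tip] <- tree$node.label[node[!tip] - ntip]
  out
}

#' Node id for a node label
#' @param tree A `phylo` object.
#' @param label Character label(s) (tip or internal).
#' @return Integer node id(s).
#' @export
node_id <- function(tree, label) {
  ntip <- length(tree$tip.label)
  idx <- match(label, c(tree$tip.label, tree$node.label))
  if (anyNA(idx)) {
    stop("unknown node label(s): ",
         paste(label[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' Most recent common ancestor of a set of sublines
#'
#' Returns the deepest node whose subtree leaf set contains all the given
#' sublines. A single subline maps to its own leaf.
#'
#' @param tree A `phylo` object.
#' @param leaves Character vector of subline names (non-empty).
#' @return Integer node id.
#' @export
mrca_node <- function(tree, leaves) {
  if (length(leaves) == 0) stop("'leaves' must be non-empty", call. = FALSE)
  idx <- match(unique(leaves), tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown subline label(s): ",
         paste(unique(leaves)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

#' Subline names below a node
#'
#' @param tree A `phylo` object.
#' @param node Integer node id.
#' @return Character vector of subline names in the node's subtree (the
#'   node itself if it is a leaf).
#' @export
leaves_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tips <- phangorn::Descendants(tree, node, type = "tips")[[1]]
  tree$tip.label[tips]
}

#' Classify the branch above a node as truncal, internal or terminal
#'
#' The trunk (the conceptual branch entering the root) is modelled as the
#' root node itself: variants shared by every subline are "placed at the
#' trunk". A leaf's incoming branch is terminal; everything else is
#' internal.
#'
#' @param tree A `phylo` object.
#' @param node Integer node id.
#' @return One of `"truncal"`, `"internal"`, `"terminal"`.
#' @export
classify_branch <- function(tree, node) {
  ntip <- length(tree$tip.label)
  vapply(node, function(v) {
    if (v == ntip + 1L) "truncal"
    else if (v <= ntip) "terminal"
    else "internal"
  }, character(1))
}

#' Map branch class to the clonality vocabulary
#' @param class Branch class from [classify_branch()].
#' @return `"clonal"`, `"subclonal"` or `"private"`.
#' @export
clonality_of <- function(class) {
  c(truncal = "clonal", internal = "subclonal", terminal = "private")[class]
}

#' Nodes in level order (root first)
#'
#' @param tree A `phylo` object.
#' @param reverse If `TRUE`, deepest level first (children always precede
#'   their parents).
#' @return Integer vector of node ids covering tips and internal nodes.
#' @export
level_order <- function(tree, reverse = FALSE) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  parent <- integer(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  depth <- integer(nn)
  root <- ntip + 1L
  ord <- integer(0)
  frontier <- root
  d <- 0L
  while (length(frontier)) {
    depth[frontier] <- d
    ord <- c(ord, frontier)
    frontier <- tree$edge[tree$edge[, 1] %in% frontier, 2]
    d <- d + 1L
  }
  if (reverse) rev(ord) else ord
}

#' Children of a node
#' @param tree A `phylo` object.
#' @param node Integer node id.
#' @return Integer vector of child node ids (empty for tips).
#' @export
tree_children <- function(tree, node) {
  tree$edge[tree$edge[, 1] == node, 2]
}

#' Ancestors of a node, from its parent up to the root
#' @param tree A `phylo` object.
#' @param node Integer node id.
#' @return Integer vector of ancestor node ids (possibly empty for root).
#' @export
tree_ancestors <- function(tree, node) {
  parent <- integer(length(tree$tip.label) + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  out <- integer(0)
  v <- node
  while (parent[v] != 0L) {
    v <- parent[v]
    out <- c(out, v)
  }
  out
}
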