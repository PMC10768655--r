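#' Parse a rooted newick tree
#'
#' Wraps [ape::read.tree()] and validates the result for use as a character
#' phylogeny: unique leaf labels, no unbranched internal nodes. Unlabeled
#' internal nodes are auto-named `n2`, `n3`, ... positionally in preorder
#' (the root is the first internal node visited, hence `n2` when unlabeled,
#' matching the node numbering convention of ancestral-state software).
#'
#' @param s newick string, terminating in `;`.
#' @return an [ape::read.tree()] `phylo` object with complete `node.label`.
#' @examples
#' parse_newick("((A:1,B:1),C:2);")
#' @export
parse_newick <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (!nzchar(trimws(s))) stop("empty newick string")
  phy <- tryCatch(ape::read.tree(text = s),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("malformed newick string: ", s)
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  phy <- ape::collapse.singles(phy)
  autolabel_nodes(phy)
}

#' Serialize a phylogeny to newick
#'
#' Deterministic inverse of [parse_newick()] (up to whitespace); labels and
#' branch lengths are preserved.
#'
#' @param phy a `phylo` object.
#' @return newick string.
#' @export
write_newick <- function(phy) {
  ape::write.tree(phy)
}

# Fill empty internal-node labels with n2, n3, ... by preorder position.
autolabel_nodes <- function(phy) {
  nnode <- phy$Nnode
  lab <- phy$node.label
  if (is.null(lab)) lab <- rep("", nnode)
  lab[is.na(lab)] <- ""
  pre <- preorder_internal(phy)            # node ids, root first
  pos <- match(pre, ape::Ntip(phy) + seq_len(nnode))
  for (k in seq_along(pre)) {
    if (!nzchar(lab[pos[k]])) lab[pos[k]] <- paste0("n", k + 1L)
  }
  if (anyDuplicated(lab))
    stop("duplicate internal node labels after auto-naming: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  phy$node.label <- lab
  phy
}

# Internal node ids in preorder (root first), via cladewise edge order.
preorder_internal <- function(phy) {
  edge <- ape::reorder.phylo(phy, "cladewise")$edge
  unique(edge[, 1L])
}

# All node labels indexed by ape node id: tips 1..Ntip then internals.
node_labels <- function(phy) {
  if (is.null(phy$node.label))
    stop("tree has no internal node labels; use parse_newick() or autolabel")
  c(phy$tip.label, phy$node.label)
}

# id of the root node
root_node <- function(phy) {
  ape::Ntip(phy) + 1L
}

# edges as a two-column matrix of (parent label, child label), preorder
branch_table <- function(phy) {
  labs <- node_labels(phy)
  edge <- ape::reorder.phylo(phy, "cladewise")$edge
  data.frame(parent = labs[edge[, 1L]], child = labs[edge[, 2L]],
             stringsAsFactors = FALSE)
}
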