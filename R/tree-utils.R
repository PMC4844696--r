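## Internal traversal helpers over ape "phylo" trees. All modules address
## nodes by label (tips by tip.label, internal nodes by node.label); a branch
## is identified by the label of its child node.

## Decompose a rooted phylo into labels, parent pointers and traversal orders.
tree_index <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree <- label_internal_nodes(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  labels <- c(tree$tip.label, tree$node.label)
  if (anyDuplicated(labels)) stop("duplicate node labels in tree")
  parent <- rep(NA_integer_, nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  ## preorder: root first, then cladewise edge order
  pre <- c(root, ape::reorder.phylo(tree, "cladewise")$edge[, 2])
  children <- vector("list", nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    children[[p]] <- c(children[[p]], tree$edge[i, 2])
  }
  list(tree = tree, ntip = ntip, nnode = nnode, labels = labels,
       parent = parent, children = children, root = root,
       preorder = pre, postorder = rev(pre),
       is_tip = seq_len(nnode) <= ntip)
}

## Nodes on the path from `node` up to (and including) `ancestor`.
path_to_ancestor <- function(idx, node, ancestor) {
  path <- node
  while (node != ancestor) {
    node <- idx$parent[node]
    if (is.na(node)) stop("ancestor not on path to root")
    path <- c(path, node)
  }
  path
}

## Most recent common ancestor of a set of node indices.
mrca_nodes <- function(idx, nodes) {
  if (length(nodes) == 1) return(nodes)
  anc <- path_to_ancestor(idx, nodes[1], idx$root)
  for (n in nodes[-1]) {
    anc2 <- path_to_ancestor(idx, n, idx$root)
    anc <- anc[anc %in% anc2]
  }
  anc[1]
}
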