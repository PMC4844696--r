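## Ancestral gene-family content on a rooted species tree.
##
## Wagner parsimony: minimum-cost integer ancestral copy numbers under
## linear branch costs c(s -> t) = gain_cost*max(t-s,0) + loss_cost*max(s-t,0),
## solved exactly by Sankoff-style dynamic programming over states
## 0..max_state (bottom-up cost tables, top-down traceback). Symmetric mode
## has equal penalties; asymmetric mode penalises a gain twice as much as a
## loss (gain:loss = 2:1). Multifurcations are handled natively (the DP sums
## over children). Among equal-cost tracebacks the smallest ancestral state
## is chosen (fewest retained copies), deterministically.
##
## Dollo parsimony over presence/absence: one origin per family at the most
## recent common ancestor of the leaves carrying it, presence on the minimal
## spanning subtree, losses elsewhere. A family whose spanning ancestor is
## the root is reported as gained on a root pseudo-branch (branch id = root
## label), so every present family has exactly one gain branch.

#' Linear gain/loss cost model for Wagner parsimony
#'
#' @param gain_cost cost per copy gained (> 0).
#' @param loss_cost cost per copy lost (> 0).
#' @return a `cost_model` object.
#' @export
cost_model <- function(gain_cost = 1, loss_cost = 1) {
  stopifnot(gain_cost > 0, loss_cost > 0)
  structure(list(gain_cost = gain_cost, loss_cost = loss_cost),
            class = "cost_model")
}

#' Add singleton genes to a family matrix
#'
#' Genes not assigned to any family are given their own single-gene family
#' (count 1 in their species, 0 elsewhere), so per-species totals are not
#' biased by cluster membership.
#'
#' @param mat families x species integer matrix.
#' @param singletons data frame with columns `gene_id` and `species`
#'   (species must match matrix columns), or `NULL`/zero rows for none.
#' @return the augmented matrix.
#' @export
prepare_matrix <- function(mat, singletons = NULL) {
  if (is.null(singletons) || nrow(singletons) == 0) return(mat)
  stopifnot(all(c("gene_id", "species") %in% names(singletons)),
            all(singletons$species %in% colnames(mat)))
  if (any(singletons$gene_id %in% rownames(mat))) {
    stop("singleton id(s) clash with existing family ids")
  }
  add <- matrix(0L, nrow = nrow(singletons), ncol = ncol(mat),
                dimnames = list(singletons$gene_id, colnames(mat)))
  add[cbind(seq_len(nrow(singletons)),
            match(singletons$species, colnames(mat)))] <- 1L
  rbind(mat, add)
}

## Per-family Sankoff DP. counts: named leaf counts; returns states for all
## nodes plus the minimal cost.
.wagner_one <- function(idx, counts, costs, max_state) {
  S <- max_state
  if (any(counts > S)) stop("max_state smaller than an observed leaf count")
  states <- 0:S
  ## branch cost matrix C[s+1, t+1] = c(s -> t)
  d <- outer(states, states, `-`)        # s - t
  C <- costs$gain_cost * pmax(-d, 0) + costs$loss_cost * pmax(d, 0)
  M <- matrix(NA_real_, nrow = idx$nnode, ncol = S + 1)
  for (node in idx$postorder) {
    if (idx$is_tip[node]) {
      v <- rep(Inf, S + 1)
      v[counts[[idx$labels[node]]] + 1] <- 0
      M[node, ] <- v
    } else {
      tot <- rep(0, S + 1)
      for (ch in idx$children[[node]]) {
        ## for each parent state s: min over child states t
        trans <- apply(C + rep(M[ch, ], each = S + 1), 1, min)
        tot <- tot + trans
      }
      M[node, ] <- tot
    }
  }
  assign <- integer(idx$nnode)
  root_costs <- M[idx$root, ]
  total <- min(root_costs)
  assign[idx$root] <- which(root_costs == total)[1] - 1L  # smallest state on tie
  for (node in idx$preorder) {
    if (node == idx$root || idx$is_tip[node]) next
    s <- assign[idx$parent[node]]
    v <- C[s + 1, ] + M[node, ]
    assign[node] <- which(v == min(v))[1] - 1L
  }
  for (node in which(idx$is_tip)) {
    assign[node] <- counts[[idx$labels[node]]]
  }
  list(states = assign, cost = total)
}

#' Wagner parsimony reconstruction of ancestral copy numbers
#'
#' @param tree rooted [ape::phylo] species tree whose leaves match the
#'   matrix species.
#' @param mat families x species integer matrix.
#' @param costs a [cost_model()]; `cost_model(2, 1)` is the asymmetric mode.
#' @param max_state upper bound of the DP state space per family; default is
#'   that family's maximum leaf count + 2 (under linear costs higher
#'   ancestral states are never optimal; the margin covers multifurcations).
#' @return a `reconstruction` object: `node_states` (nodes x families matrix,
#'   rownames = node labels), `total_cost`, `events` (per-branch data frame:
#'   `branch`, `family`, `from`, `to`, `type` in
#'   gain/loss/expansion/contraction), `mode`, and the tree.
#' @export
wagner_reconstruct <- function(tree, mat, costs = cost_model(), max_state = NULL) {
  stopifnot(inherits(costs, "cost_model"))
  idx <- tree_index(tree)
  tips <- idx$labels[idx$is_tip]
  if (!setequal(tips, colnames(mat))) {
    stop("tree leaves and matrix species differ: tree-only {",
         paste(setdiff(tips, colnames(mat)), collapse = ","),
         "}, matrix-only {",
         paste(setdiff(colnames(mat), tips), collapse = ","), "}")
  }
  node_states <- matrix(0L, nrow = idx$nnode, ncol = nrow(mat),
                        dimnames = list(idx$labels, rownames(mat)))
  total <- 0
  for (f in seq_len(nrow(mat))) {
    counts <- setNames(as.integer(mat[f, tips]), tips)
    S <- if (is.null(max_state)) max(counts) + 2L else as.integer(max_state)
    r <- .wagner_one(idx, counts, costs, max(S, 1L))
    node_states[, f] <- r$states
    total <- total + r$cost
  }
  structure(list(node_states = node_states, total_cost = total,
                 events = .branch_events(idx, node_states),
                 mode = sprintf("wagner(gain=%g,loss=%g)",
                                costs$gain_cost, costs$loss_cost),
                 tree = idx$tree),
            class = "reconstruction")
}

## Per-branch change events from node states. parent 0 -> child >0: gain;
## parent >0 -> child 0: loss; child > parent > 0: expansion; contraction
## symmetric.
.branch_events <- function(idx, node_states, root_gains = FALSE) {
  ev <- list()
  for (node in idx$preorder) {
    if (node == idx$root) {
      if (root_gains) {
        present <- which(node_states[idx$root, ] > 0)
        if (length(present) > 0) {
          ev[[length(ev) + 1]] <- data.frame(
            branch = idx$labels[idx$root],
            family = colnames(node_states)[present],
            from = 0L, to = node_states[idx$root, present],
            type = "gain", stringsAsFactors = FALSE)
        }
      }
      next
    }
    p <- node_states[idx$parent[node], ]
    ch <- node_states[node, ]
    changed <- which(p != ch)
    if (length(changed) == 0) next
    type <- ifelse(p[changed] == 0, "gain",
                   ifelse(ch[changed] == 0, "loss",
                          ifelse(ch[changed] > p[changed],
                                 "expansion", "contraction")))
    ev[[length(ev) + 1]] <- data.frame(
      branch = idx$labels[node], family = colnames(node_states)[changed],
      from = unname(p[changed]), to = unname(ch[changed]), type = type,
      stringsAsFactors = FALSE)
  }
  if (length(ev) == 0) {
    return(data.frame(branch = character(0), family = character(0),
                      from = integer(0), to = integer(0),
                      type = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

#' Dollo parsimony reconstruction of gene-family presence
#'
#' Each family originates exactly once, on the branch into the most recent
#' common ancestor of the leaves that carry it (the root pseudo-branch when
#' that ancestor is the root); it is present on the minimal subtree spanning
#' those leaves and lost on branches leaving that subtree.
#'
#' @param tree rooted [ape::phylo] species tree.
#' @param mat families x species matrix; any positive entry is presence.
#' @return a `reconstruction` object as in [wagner_reconstruct()] (0/1 node
#'   states), plus `origin`: named character vector, family -> label of the
#'   origin node (`NA` for all-absent families).
#' @export
dollo_reconstruct <- function(tree, mat) {
  idx <- tree_index(tree)
  tips <- idx$labels[idx$is_tip]
  if (!setequal(tips, colnames(mat))) {
    stop("tree leaves and matrix species differ: tree-only {",
         paste(setdiff(tips, colnames(mat)), collapse = ","),
         "}, matrix-only {",
         paste(setdiff(colnames(mat), tips), collapse = ","), "}")
  }
  presence <- mat[, tips, drop = FALSE] > 0
  node_states <- matrix(0L, nrow = idx$nnode, ncol = nrow(mat),
                        dimnames = list(idx$labels, rownames(mat)))
  origin <- setNames(rep(NA_character_, nrow(mat)), rownames(mat))
  total <- 0
  for (f in seq_len(nrow(mat))) {
    leaves <- match(tips[presence[f, ]], idx$labels)
    if (length(leaves) == 0) next
    anc <- mrca_nodes(idx, leaves)
    present_nodes <- unique(unlist(lapply(leaves, path_to_ancestor,
                                          idx = idx, ancestor = anc)))
    node_states[present_nodes, f] <- 1L
    origin[f] <- idx$labels[anc]
    ## cost bookkeeping: one gain + losses (branches leaving the subtree)
    sub <- .subtree_nodes(idx, anc)
    losses <- sum(!(sub %in% present_nodes) &
                    (idx$parent[sub] %in% present_nodes))
    total <- total + 1 + losses
  }
  ev <- .branch_events(idx, node_states)
  ## re-tag origins: the absent->present branch (or root pseudo-branch)
  root_present <- which(node_states[idx$root, ] > 0)
  if (length(root_present) > 0) {
    ev <- rbind(ev, data.frame(
      branch = idx$labels[idx$root],
      family = colnames(node_states)[root_present],
      from = 0L, to = 1L, type = "gain", stringsAsFactors = FALSE))
  }
  structure(list(node_states = node_states, total_cost = total,
                 events = ev, origin = origin, mode = "dollo",
                 tree = idx$tree),
            class = "reconstruction")
}

.subtree_nodes <- function(idx, node) {
  out <- node
  stack <- idx$children[[node]]
  while (length(stack) > 0) {
    n <- stack[1]; stack <- stack[-1]
    out <- c(out, n)
    stack <- c(stack, idx$children[[n]])
  }
  out
}

#' Per-branch gain/loss/expansion summary
#'
#' One row per branch (identified by the label of its child node; for Dollo
#' reconstructions the root row carries families originating at the root).
#'
#' @param recon a `reconstruction` object.
#' @return data frame with columns `branch`, `n_gained`, `n_lost`,
#'   `n_expanded`, `n_contracted`, `net` (= gained - lost).
#' @export
branch_summary <- function(recon) {
  stopifnot(inherits(recon, "reconstruction"))
  idx <- tree_index(recon$tree)
  branches <- idx$labels[idx$preorder]
  ev <- recon$events
  count_type <- function(b, ty) sum(ev$branch == b & ev$type == ty)
  out <- data.frame(
    branch = branches,
    n_gained = vapply(branches, count_type, integer(1), ty = "gain"),
    n_lost = vapply(branches, count_type, integer(1), ty = "loss"),
    n_expanded = vapply(branches, count_type, integer(1), ty = "expansion"),
    n_contracted = vapply(branches, count_type, integer(1), ty = "contraction"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$net <- out$n_gained - out$n_lost
  out
}
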