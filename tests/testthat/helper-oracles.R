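# Independent oracles and fixture builders used across the suite.
# The oracles enumerate exhaustively and share no code with the package's
# dynamic-programming / spanning-subtree implementations.

# Exhaustive Wagner parsimony: enumerate every assignment of integer states
# 0..S to the internal nodes and take the minimum total linear branch cost.
brute_wagner_cost <- function(tree, counts, gain, loss, S) {
  tree <- label_internal_nodes(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  edge <- tree$edge
  grid <- as.matrix(expand.grid(rep(list(0:S), tree$Nnode)))
  state <- matrix(NA_integer_, nrow(grid), nnode)
  state[, ntip + seq_len(tree$Nnode)] <- grid
  for (i in seq_len(ntip)) state[, i] <- counts[[tree$tip.label[i]]]
  cost <- rep(0, nrow(grid))
  for (e in seq_len(nrow(edge))) {
    d <- state[, edge[e, 2]] - state[, edge[e, 1]]
    cost <- cost + gain * pmax(d, 0) + loss * pmax(-d, 0)
  }
  min(cost)
}

# Exhaustive Dollo: enumerate every 0/1 assignment to internal nodes that
# (with the fixed leaves) has exactly one absent->present transition,
# counting the root as an origin when present there; return the minimum
# number of losses and the presence pattern achieving it.
brute_dollo <- function(tree, presence) {
  tree <- label_internal_nodes(tree)
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  grid <- as.matrix(expand.grid(rep(list(0:1), tree$Nnode)))
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    state <- c(presence[tree$tip.label], grid[r, ])
    gains <- grid[r, 1]  # root (node ntip+1) present counts as the origin
    losses <- 0
    for (e in seq_len(nrow(edge))) {
      p <- state[edge[e, 1]]; ch <- state[edge[e, 2]]
      if (p == 0 && ch == 1) gains <- gains + 1
      if (p == 1 && ch == 0) losses <- losses + 1
    }
    if (gains != 1) next
    if (is.null(best) || losses < best$losses) {
      best <- list(losses = losses, state = state)
    }
  }
  best
}

# Random rooted tree with deterministic tip labels t1..tn.
random_tree <- function(n) {
  tr <- ape::rtree(n, rooted = TRUE)
  tr$tip.label <- paste0("t", seq_len(n))
  tr$node.label <- NULL
  tr
}

demo_rules <- function() {
  list(
    tap_rule("bZIP", mandatory = "PF00170", ga = c(PF00170 = 25)),
    tap_rule("MYB", mandatory = "PF00249", forbidden = "PF01388",
             ga = c(PF00249 = 20)),
    tap_rule("E2F_DP", mandatory = "PF02319", forbidden = "PF00249",
             ga = c(PF02319 = 30))
  )
}

domain_hits <- function(protein_id, domains, scores) {
  data.frame(protein_id = protein_id, domain_id = domains,
             bitscore = scores, evalue = 1e-10, stringsAsFactors = FALSE)
}

demo_ladder <- function() {
  build_ladder(c("cellular organisms", "Eukaryota", "Viridiplantae",
                 "Chlorophyta", "Chlorophyceae", "Chlamydomonadales",
                 "Goniaceae", "Gonium", "Gonium pectorale"))
}

homology_row <- function(gene, subject, evalue, lineage) {
  data.frame(query_id = gene, subject_id = subject, evalue = evalue,
             bitscore = 100, lineage = lineage, stringsAsFactors = FALSE)
}
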