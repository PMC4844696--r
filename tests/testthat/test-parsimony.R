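test_that("singletons become single-gene families, preserving column sums", {
  mat <- matrix(c(2L, 1L, 0L, 3L), nrow = 2,
                dimnames = list(c("f1", "f2"), c("A", "B")))
  singles <- data.frame(gene_id = c("s1", "s2", "s3"),
                        species = c("A", "A", "B"))
  out <- prepare_matrix(mat, singles)
  expect_equal(nrow(out), 5)
  expect_equal(unname(colSums(out)), unname(colSums(mat)) + c(2, 1))
  expect_equal(unname(out["s1", ]), c(1L, 0L))
  expect_identical(prepare_matrix(mat, NULL), mat)
  expect_error(prepare_matrix(mat, data.frame(gene_id = "f1", species = "A")),
               "clash")
})

test_that("a concordant cherry reconstructs with zero cost", {
  tr <- read_newick(text = "(A,B);")
  mat <- matrix(c(1L, 1L), 1, dimnames = list("f1", c("A", "B")))
  r <- wagner_reconstruct(tr, mat)
  expect_equal(r$total_cost, 0)
  expect_equal(unname(r$node_states["N1", "f1"]), 1L)
  expect_equal(nrow(r$events), 0)
})

test_that("asymmetric costs prefer a loss over a gain where symmetric ties", {
  tr <- read_newick(text = "((A,B),C);")
  mat <- matrix(c(1L, 1L, 0L), 1, dimnames = list("f1", c("A", "B", "C")))

  sym <- wagner_reconstruct(tr, mat, cost_model(1, 1))
  expect_equal(sym$total_cost, 1)  # one gain OR one loss

  asym <- wagner_reconstruct(tr, mat, cost_model(2, 1))
  expect_equal(asym$total_cost, 1)
  expect_equal(unname(asym$node_states["N1", "f1"]), 1L)  # root has it
  expect_equal(asym$events$branch, "C")
  expect_equal(asym$events$type, "loss")

  # exhaustive enumeration over all ancestral assignments agrees
  counts <- c(A = 1, B = 1, C = 0)
  expect_equal(sym$total_cost, brute_wagner_cost(tr, counts, 1, 1, 3))
  expect_equal(asym$total_cost, brute_wagner_cost(tr, counts, 2, 1, 3))
})

test_that("leaf/species mismatches are reported with the offenders", {
  tr <- read_newick(text = "((A,B),C);")
  mat <- matrix(1L, 1, 3, dimnames = list("f1", c("A", "B", "D")))
  expect_error(wagner_reconstruct(tr, mat), "C")
  expect_error(dollo_reconstruct(tr, mat), "D")
})

test_that("DP cost equals the exhaustive minimum on random instances", {
  withr::with_seed(101L, {
    for (i in 1:60) {
      n <- sample(3:6, 1)
      tr <- random_tree(n)
      counts <- setNames(sample(0:4, n, replace = TRUE), tr$tip.label)
      costs <- if (i %% 2 == 0) cost_model(1, 1) else cost_model(2, 1)
      mat <- matrix(as.integer(counts), 1,
                    dimnames = list("f1", names(counts)))
      dp <- wagner_reconstruct(tr, mat, costs)$total_cost
      bf <- brute_wagner_cost(tr, counts, costs$gain_cost, costs$loss_cost,
                              max(counts) + 2)
      expect_equal(dp, bf, label = paste("instance", i))
    }
  })
})

test_that("reconstruction cost decomposes over branches under the cost model", {
  withr::with_seed(113L, {
    tr <- random_tree(5)
    mat <- matrix(sample(0:3, 20, replace = TRUE), nrow = 4,
                  dimnames = list(paste0("f", 1:4), tr$tip.label))
    costs <- cost_model(2, 1)
    r <- wagner_reconstruct(tr, mat, costs)
    idx <- volvocomp:::tree_index(r$tree)
    total <- 0
    for (e in seq_len(nrow(idx$tree$edge))) {
      p <- r$node_states[idx$tree$edge[e, 1], ]
      ch <- r$node_states[idx$tree$edge[e, 2], ]
      d <- ch - p
      total <- total + sum(costs$gain_cost * pmax(d, 0) +
                             costs$loss_cost * pmax(-d, 0))
    }
    expect_equal(r$total_cost, total)
  })
})

test_that("increasing the gain cost never infers more gains", {
  withr::with_seed(127L, {
    for (i in 1:20) {
      tr <- random_tree(sample(4:6, 1))
      mat <- matrix(sample(0:2, 3 * length(tr$tip.label), replace = TRUE),
                    nrow = 3, dimnames = list(paste0("f", 1:3), tr$tip.label))
      cheap <- wagner_reconstruct(tr, mat, cost_model(1, 1))
      dear <- wagner_reconstruct(tr, mat, cost_model(3, 1))
      n_gains <- function(r) sum(r$events$type == "gain")
      expect_lte(n_gains(dear), n_gains(cheap))
    }
  })
})

test_that("Dollo places one origin at the spanning ancestor", {
  tr <- read_newick(text = "((A,B),C);")
  all3 <- matrix(c(1L, 1L, 1L), 1, dimnames = list("f1", c("A", "B", "C")))
  r1 <- dollo_reconstruct(tr, all3)
  expect_equal(unname(r1$origin["f1"]), "N1")       # root origin
  expect_equal(sum(r1$events$type == "loss"), 0)

  ac <- matrix(c(1L, 0L, 1L), 1, dimnames = list("f1", c("A", "B", "C")))
  r2 <- dollo_reconstruct(tr, ac)
  expect_equal(unname(r2$origin["f1"]), "N1")
  losses <- r2$events[r2$events$type == "loss", ]
  expect_equal(losses$branch, "B")                  # one loss on B
  expect_equal(r2$total_cost, 2)                    # origin + one loss

  one <- matrix(c(0L, 1L, 0L), 1, dimnames = list("f1", c("A", "B", "C")))
  r3 <- dollo_reconstruct(tr, one)
  expect_equal(unname(r3$origin["f1"]), "B")        # pendant-branch origin
})

test_that("Dollo losses are minimal among single-origin scenarios", {
  withr::with_seed(131L, {
    for (i in 1:25) {
      tr <- random_tree(sample(3:6, 1))
      pres <- setNames(sample(0:1, length(tr$tip.label), replace = TRUE),
                       tr$tip.label)
      if (sum(pres) == 0) next
      mat <- matrix(as.integer(pres), 1, dimnames = list("f1", names(pres)))
      r <- dollo_reconstruct(tr, mat)
      oracle <- brute_dollo(tr, pres)
      expect_equal(sum(r$events$type == "loss"), oracle$losses)
      expect_equal(r$total_cost, 1 + oracle$losses)
    }
  })
})

test_that("branch summaries are consistent and conserve Dollo gains/losses", {
  tr <- read_newick(text = "((A,B),(C,D));")
  flat <- matrix(1L, 2, 4, dimnames = list(c("f1", "f2"), c("A", "B", "C", "D")))
  bs0 <- branch_summary(wagner_reconstruct(tr, flat))
  expect_true(all(bs0[, -1] == 0))

  withr::with_seed(139L, {
    mat <- matrix(sample(0:1, 24, replace = TRUE), nrow = 6,
                  dimnames = list(paste0("f", 1:6), c("A", "B", "C", "D")))
    r <- dollo_reconstruct(tr, mat)
    bs <- branch_summary(r)
    present_somewhere <- sum(rowSums(mat) > 0)
    at_root <- sum(r$node_states["N1", ] > 0)
    # single origin per present family: total gains (root row included)
    # equal the families present at the leaves' union
    expect_equal(sum(bs$n_gained), present_somewhere)
    expect_equal(bs$n_gained[bs$branch == "N1"], at_root)
    # the summary is a faithful tally of the event table
    expect_equal(sum(bs$n_lost), sum(r$events$type == "loss"))
    expect_equal(sum(bs$n_gained), sum(r$events$type == "gain"))
  })
})

test_that("gain-only simulated histories are recovered branch-by-branch", {
  tr <- read_newick(text = "((A,B),(C,D));")
  sim <- simulate_family_evolution(
    tr, evolution_params(gain_rate = 0.7, root_families = 4, seed = 57))
  keep <- rowSums(sim$matrix) > 0
  r <- dollo_reconstruct(tr, sim$matrix[keep, , drop = FALSE])
  bs <- branch_summary(r)
  planted <- table(sim$truth$events$branch[sim$truth$events$type == "gain"])
  for (b in bs$branch) {
    want <- if (b %in% names(planted)) planted[[b]] else
      if (b == "N1") sum(keep) - sum(sim$truth$events$type == "gain") else 0
    expect_equal(bs$n_gained[bs$branch == b], unname(want),
                 label = paste("gains on branch", b))
  }
})

test_that("mixed-rate histories are bounded below by parsimony", {
  tr <- read_newick(text = "((A,B),(C,D));")
  sim <- simulate_family_evolution(
    tr, evolution_params(gain_rate = 0.5, loss_rate = 0.3, root_families = 10,
                         seed = 61))
  r <- wagner_reconstruct(tr, sim$matrix, cost_model(1, 1))
  # without duplication every event moves one copy, so the planted history
  # costs exactly its event count and parsimony can only do better
  expect_lte(r$total_cost, sum(abs(sim$truth$events$to -
                                     sim$truth$events$from)))
  expect_lte(nrow(r$events), nrow(sim$truth$events))
})
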