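## Synthetic-data generators with planted ground truth. Every pipeline input
## (copy-number matrices, domain-hit tables, homology-hit tables, a toy
## genome) can be generated with a known answer, so each analysis stage is
## testable end-to-end without external databases.
##
## Event counts per branch are Poisson in the *rate per branch* (branch
## lengths are optional in inputs, so per-branch rates are the contract);
## loss hits a uniformly chosen present family; duplication is per-copy
## Bernoulli. All randomness flows from one integer seed; global RNG state is
## restored afterwards.

#' Parameters for gene-family evolution simulation
#'
#' @param gain_rate expected number of family gains per branch (Poisson).
#' @param loss_rate expected number of family losses per branch (Poisson).
#' @param dup_rate per-copy duplication probability per branch.
#' @param root_families number of families present (copy number 1) at the root.
#' @param seed integer seed.
#' @return an `evolution_params` list.
#' @export
evolution_params <- function(gain_rate = 0, loss_rate = 0, dup_rate = 0,
                             root_families = 0, seed = 1) {
  stopifnot(gain_rate >= 0, loss_rate >= 0, dup_rate >= 0, dup_rate <= 1,
            is_count(root_families))
  structure(list(gain_rate = gain_rate, loss_rate = loss_rate,
                 dup_rate = dup_rate, root_families = as.integer(root_families),
                 seed = as.integer(seed)),
            class = "evolution_params")
}

#' Simulate gene-family evolution along a rooted species tree
#'
#' The root starts with `root_families` families at copy number 1. Along each
#' branch, `Poisson(gain_rate)` new families appear at count 1,
#' `Poisson(loss_rate)` currently-present families drop to 0 (chosen
#' uniformly, without replacement), and every existing copy duplicates
#' independently with probability `dup_rate`. Leaf counts form the returned
#' matrix; every event is recorded in the planted truth.
#'
#' @param tree rooted [ape::phylo] species tree.
#' @param params an [evolution_params()] object.
#' @return list with `matrix` (families x species integer matrix), and
#'   `truth`: `events` (data frame `branch`, `type` in gain/loss/expansion,
#'   `family`, `from`, `to`) and `node_states` (nodes x families matrix of
#'   copy numbers, rownames = node labels).
#' @export
simulate_family_evolution <- function(tree, params) {
  stopifnot(inherits(params, "evolution_params"))
  idx <- tree_index(tree)
  local_seed(params$seed, {
    fam_ids <- if (params$root_families > 0) {
      sprintf("FAM%04d", seq_len(params$root_families))
    } else character(0)
    n_fam <- length(fam_ids)
    states <- matrix(0L, nrow = idx$nnode, ncol = n_fam)
    if (n_fam > 0) states[idx$root, ] <- 1L
    events <- list()
    next_fam <- n_fam

    for (node in idx$preorder) {
      if (node == idx$root) next
      branch <- idx$labels[node]
      st <- states[node, ] <- states[idx$parent[node], ]
      st <- states[node, ]

      ## gains: new families at count 1
      n_gain <- rpois(1, params$gain_rate)
      if (n_gain > 0) {
        new_ids <- sprintf("FAM%04d", next_fam + seq_len(n_gain))
        next_fam <- next_fam + n_gain
        fam_ids <- c(fam_ids, new_ids)
        states <- cbind(states, matrix(0L, idx$nnode, n_gain))
        states[node, ncol(states) - n_gain + seq_len(n_gain)] <- 1L
        events[[length(events) + 1]] <- data.frame(
          branch = branch, type = "gain", family = new_ids,
          from = 0L, to = 1L, stringsAsFactors = FALSE)
      }
      st <- states[node, ]

      ## losses: uniformly chosen present families drop to 0
      n_loss <- min(rpois(1, params$loss_rate), sum(st > 0))
      if (n_loss > 0) {
        present <- which(st > 0)
        victims <- if (length(present) == 1) present else
          sample(present, n_loss)
        events[[length(events) + 1]] <- data.frame(
          branch = branch, type = "loss", family = fam_ids[victims],
          from = st[victims], to = 0L, stringsAsFactors = FALSE)
        st[victims] <- 0L
      }

      ## duplication: each copy duplicates with prob dup_rate
      if (params$dup_rate > 0) {
        present <- which(st > 0)
        if (length(present) > 0) {
          extra <- rbinom(length(present), st[present], params$dup_rate)
          grew <- extra > 0
          if (any(grew)) {
            events[[length(events) + 1]] <- data.frame(
              branch = branch, type = "expansion",
              family = fam_ids[present[grew]],
              from = st[present[grew]],
              to = st[present[grew]] + extra[grew], stringsAsFactors = FALSE)
            st[present[grew]] <- st[present[grew]] + extra[grew]
          }
        }
      }
      states[node, ] <- st
    }

    rownames(states) <- idx$labels
    colnames(states) <- fam_ids
    mat <- t(states[seq_len(idx$ntip), , drop = FALSE])
    ev <- if (length(events) > 0) {
      do.call(rbind, events)
    } else {
      data.frame(branch = character(0), type = character(0),
                 family = character(0), from = integer(0), to = integer(0),
                 stringsAsFactors = FALSE)
    }
    list(matrix = mat, truth = list(events = ev, node_states = t(states)))
  })
}

#' Simulate a proteome of domain hits with planted TAP families
#'
#' Each planted family member receives hits on all of its family's mandatory
#' domains with bit scores at or above that family's gathering threshold.
#' Background proteins receive decoy domains (never a rule domain at a
#' passing score; occasionally a mandatory domain *below* its threshold).
#' With probability `noise`, a planted member additionally receives one of
#' its family's forbidden domains, so a correct classifier must reject it.
#'
#' @param rules list of [tap_rule()] objects.
#' @param n_members_per_family planted members per family.
#' @param n_background number of background proteins.
#' @param noise probability that a planted member carries a forbidden domain.
#' @param seed integer seed.
#' @return list with `hits` (domain-hit data frame) and `truth` (data frame
#'   `protein_id`, `family` (`NA` for background), `noisy`).
#' @export
simulate_tap_proteome <- function(rules, n_members_per_family, n_background,
                                  noise = 0, seed = 1) {
  if (length(rules) == 0) stop("rules must be non-empty")
  stopifnot(all(vapply(rules, inherits, logical(1), "tap_rule")),
            is_count(n_members_per_family), is_count(n_background),
            noise >= 0, noise <= 1)
  rule_domains <- unique(unlist(lapply(rules, function(r)
    c(r$mandatory, r$forbidden))))
  local_seed(seed, {
    hits <- list()
    truth <- list()
    p <- 0L
    for (r in rules) {
      for (i in seq_len(n_members_per_family)) {
        p <- p + 1L
        pid <- sprintf("prot%04d", p)
        sc <- unname(r$ga[r$mandatory]) + runif(length(r$mandatory), 0, 25)
        hits[[length(hits) + 1]] <- data.frame(
          protein_id = pid, domain_id = r$mandatory, bitscore = sc,
          evalue = 10^-runif(length(r$mandatory), 5, 30),
          stringsAsFactors = FALSE)
        noisy <- length(r$forbidden) > 0 && runif(1) < noise
        if (noisy) {
          fd <- if (length(r$forbidden) == 1) r$forbidden else
            sample(r$forbidden, 1)
          hits[[length(hits) + 1]] <- data.frame(
            protein_id = pid, domain_id = fd, bitscore = runif(1, 5, 50),
            evalue = 10^-runif(1, 3, 20), stringsAsFactors = FALSE)
        }
        truth[[length(truth) + 1]] <- data.frame(
          protein_id = pid, family = r$family, noisy = noisy,
          stringsAsFactors = FALSE)
      }
    }
    for (i in seq_len(n_background)) {
      p <- p + 1L
      pid <- sprintf("prot%04d", p)
      nd <- sample(1:3, 1)
      doms <- sprintf("DECOY_%02d", sample(1:20, nd))
      hits[[length(hits) + 1]] <- data.frame(
        protein_id = pid, domain_id = doms, bitscore = runif(nd, 10, 80),
        evalue = 10^-runif(nd, 3, 20), stringsAsFactors = FALSE)
      if (runif(1) < 0.3) {
        ## sub-threshold hit on a real mandatory domain: must not classify
        r <- rules[[sample(length(rules), 1)]]
        d <- if (length(r$mandatory) == 1) r$mandatory else
          sample(r$mandatory, 1)
        hits[[length(hits) + 1]] <- data.frame(
          protein_id = pid, domain_id = d,
          bitscore = max(0.1, unname(r$ga[d]) - runif(1, 5, 15)),
          evalue = 10^-runif(1, 3, 20), stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1]] <- data.frame(
        protein_id = pid, family = NA_character_, noisy = FALSE,
        stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, hits)
    rownames(hits) <- NULL
    list(hits = hits, truth = do.call(rbind, truth))
  })
}

#' Simulate homology hits with planted phylostrata
#'
#' For each gene with planted stratum s < k, at least one hit is generated
#' whose subject lineage shares exactly the first s ladder taxa with the
#' focal lineage (E-value well below the filter threshold), plus optional
#' nearer hits and decoy hits whose E-values exceed the threshold. Genes
#' planted species-specific (stratum k) get only decoy hits.
#'
#' @param genes character vector of gene ids.
#' @param ladder a [build_ladder()] object.
#' @param stratum_assignment named integer vector, gene id -> planted stratum
#'   in `1..k`.
#' @param seed integer seed.
#' @param evalue_max filter threshold the decoys must fail (default 0.001).
#' @return homology-hit data frame (`query_id`, `subject_id`, `evalue`,
#'   `bitscore`, `lineage`).
#' @export
simulate_homology_hits <- function(genes, ladder, stratum_assignment, seed = 1,
                                   evalue_max = 0.001) {
  stopifnot(inherits(ladder, "phylo_ladder"),
            all(genes %in% names(stratum_assignment)))
  k <- ladder$k
  s_all <- stratum_assignment[genes]
  stopifnot(all(s_all >= 1), all(s_all <= k))
  local_seed(seed, {
    rows <- list()
    for (g in genes) {
      s <- s_all[[g]]
      nhit <- 0L
      mk_lineage <- function(depth) {
        ## shares exactly ladder taxa 1..depth, then diverges
        paste(c(ladder$taxa[seq_len(depth)],
                sprintf("OtherClade_%d_%d", depth, sample(1:999, 1))),
              collapse = ";")
      }
      add <- function(depth, evalue) {
        nhit <<- nhit + 1L
        rows[[length(rows) + 1]] <<- data.frame(
          query_id = g, subject_id = sprintf("db|%s_h%d", g, nhit),
          evalue = evalue, bitscore = runif(1, 50, 500),
          lineage = mk_lineage(depth), stringsAsFactors = FALSE)
      }
      if (s < k) {
        add(s, 10^-runif(1, 5, 50))                 # anchor at planted stratum
        for (j in seq_len(sample(0:2, 1))) {        # nearer (younger) hits
          add(resample(s:(k - 1)), 10^-runif(1, 4, 40))
        }
      }
      ## decoys above the E-value threshold, at old strata: must be filtered
      for (j in seq_len(sample(if (s < k) 0:1 else 1:2, 1))) {
        add(1, evalue_max * 10^runif(1, 0.5, 3))
      }
      ## species-specific genes may also have no hits at all
      if (s == k && runif(1) < 0.3) {
        rows <- rows[seq_len(length(rows) - nhit)]
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Construct a toy genome with exactly known summary statistics
#'
#' Gene structures (exon/intron layout) are generated first; the chromosome
#' sequence is then *constructed* with an exact G+C count (`round(gc * L)`
#' bases are G or C, positions shuffled), so GC content is known exactly
#' rather than sampled. The returned `stats` element records the planted
#' truth for every summary the stats module computes.
#'
#' @param n_genes number of genes.
#' @param intron_len_mean mean intron length (intron lengths are sampled
#'   uniformly in `[intron_len_mean/2, 3*intron_len_mean/2]`).
#' @param gc target GC fraction in `[0,1]`.
#' @param seed integer seed.
#' @param max_exons maximum exons per gene (exon count uniform in 1..max).
#' @return list with `genome` (named character, one chromosome), `models`
#'   (`gene_models` data frame) and `stats` (list: `gc`, `genome_size_mb`,
#'   `n_genes`, `introns_per_gene`, `mean_intron_len_bp`,
#'   `pct_genes_with_introns`).
#' @export
simulate_toy_genome <- function(n_genes, intron_len_mean = 200, gc = 0.5,
                                seed = 1, max_exons = 4) {
  stopifnot(is_count(n_genes), n_genes > 0, gc >= 0, gc <= 1,
            intron_len_mean >= 2, max_exons >= 1)
  local_seed(seed, {
    pos <- 1L
    rows <- list()
    intron_lens <- integer(0)
    n_with_introns <- 0L
    introns_per_gene <- integer(n_genes)
    for (i in seq_len(n_genes)) {
      gid <- sprintf("g%03d", i)
      tid <- sprintf("%s.t1", gid)
      n_ex <- if (max_exons == 1) 1L else sample(seq_len(max_exons), 1)
      ex_len <- sample(50:200, n_ex, replace = TRUE)
      il <- if (n_ex > 1) {
        lo <- max(1, floor(intron_len_mean / 2))
        hi <- max(lo, ceiling(3 * intron_len_mean / 2))
        sample(lo:hi, n_ex - 1, replace = TRUE)
      } else integer(0)
      starts <- integer(n_ex); ends <- integer(n_ex)
      cur <- pos
      for (e in seq_len(n_ex)) {
        starts[e] <- cur
        ends[e] <- cur + ex_len[e] - 1L
        cur <- ends[e] + (if (e < n_ex) il[e] else 0L) + 1L
      }
      rows[[i]] <- data.frame(gene_id = gid, transcript_id = tid,
                              strand = "+", start = starts, end = ends,
                              stringsAsFactors = FALSE)
      intron_lens <- c(intron_lens, il)
      introns_per_gene[i] <- n_ex - 1L
      if (n_ex > 1) n_with_introns <- n_with_introns + 1L
      pos <- cur + sample(100:300, 1)   # intergenic spacer
    }
    models <- do.call(rbind, rows)
    class(models) <- c("gene_models", "data.frame")
    L <- max(models$end) + 200L
    n_gc <- round(gc * L)
    bases <- c(sample(c("G", "C"), n_gc, replace = TRUE),
               sample(c("A", "T"), L - n_gc, replace = TRUE))
    genome <- paste(bases[sample.int(L)], collapse = "")
    names(genome) <- "chr1"
    stats <- list(
      gc = n_gc / L,
      genome_size_mb = L / 1e6,
      n_genes = n_genes,
      introns_per_gene = mean(introns_per_gene),
      mean_intron_len_bp = if (length(intron_lens) > 0) mean(intron_lens) else 0,
      pct_genes_with_introns = 100 * n_with_introns / n_genes
    )
    list(genome = genome, models = models, stats = stats)
  })
}
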