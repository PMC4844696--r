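## Protein-domain enrichment between species groups. Domain hit counts are
## pooled within each group and each domain is tested against all other
## domains in a 2x2 contingency table with a G-test of independence
## (likelihood-ratio chi-square, 1 df). Raw alpha = 0.05 by default, no
## multiple-testing correction (a Benjamini-Hochberg option is provided and
## recommended for genome-scale scans).

#' Domain diversity and abundance matrices
#'
#' @param hits_by_species named list of domain-hit data frames, one per
#'   species.
#' @return list with `abundance` (integer matrix, domains x species; entry =
#'   number of hits of that domain in that species) and `diversity` (the
#'   0/1 presence indicator of abundance). Domains absent everywhere do not
#'   appear as rows.
#' @export
domain_matrix <- function(hits_by_species) {
  stopifnot(!is.null(names(hits_by_species)))
  domains <- sort(unique(unlist(lapply(hits_by_species,
                                       function(h) h$domain_id))))
  ab <- matrix(0L, nrow = length(domains), ncol = length(hits_by_species),
               dimnames = list(domains, names(hits_by_species)))
  for (sp in names(hits_by_species)) {
    tab <- table(hits_by_species[[sp]]$domain_id)
    ab[names(tab), sp] <- as.integer(tab)
  }
  list(abundance = ab, diversity = (ab > 0) + 0L)
}

#' G-test of independence on a 2x2 table
#'
#' G = 2 * sum(O * ln(O / E)) over cells with O > 0 (the x*ln(x) -> 0 limit
#' gives zero cells zero contribution); E from row/column margins; p from
#' the chi-square distribution with 1 df. No correction by default; Williams
#' and Yates corrections are available behind flags.
#'
#' @param table 2x2 matrix of non-negative counts with at least one positive
#'   row sum and column sum.
#' @param correction `"none"` (default), `"williams"` or `"yates"`.
#' @return list with `g_stat` and `p_value`.
#' @export
#' @examples
#' g_test_2x2(matrix(c(10, 10, 90, 90), 2))  # G = 0, p = 1
g_test_2x2 <- function(table, correction = c("none", "williams", "yates")) {
  correction <- match.arg(correction)
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)))
  if (any(table < 0)) stop("negative entries in contingency table")
  O <- table
  n <- sum(O)
  rs <- rowSums(O)
  cs <- colSums(O)
  if (any(rs == 0) || any(cs == 0) || n == 0) {
    stop("table must have positive row and column sums")
  }
  E <- outer(rs, cs) / n
  if (correction == "yates") {
    O <- O + sign(E - O) * pmin(abs(E - O), 0.5)  # move toward E, at most 0.5
  }
  pos <- O > 0
  g <- 2 * sum(O[pos] * log(O[pos] / E[pos]))
  g <- max(g, 0)   # guard tiny negative rounding for near-independent tables
  if (correction == "williams") {
    q <- 1 + (n / rs[1] + n / rs[2] - 1) * (n / cs[1] + n / cs[2] - 1) /
      (6 * n)
    g <- g / q
  }
  list(g_stat = unname(g), p_value = unname(pchisq(g, df = 1,
                                                   lower.tail = FALSE)))
}

#' Scan domains for over/under-representation between two species groups
#'
#' Hit counts are pooled within each group. For each domain the 2x2 table is
#' (hits of this domain, hits of all other domains) x (group A, group B).
#' `sign` is +1 when the domain is significant at `alpha` and
#' over-represented in group A (its observed group-A proportion exceeds the
#' expectation under independence), -1 when significant and
#' under-represented, 0 otherwise.
#'
#' @param abundance domains x species count matrix ([domain_matrix()]).
#' @param group_a,group_b character vectors of species (disjoint subsets of
#'   the matrix columns).
#' @param alpha significance level (default 0.05).
#' @param mode `"abundance"` (pooled hit counts, G-test; default) or
#'   `"diversity"` (per-species presence counts, Fisher's exact test).
#' @param adjust p-value adjustment passed to [stats::p.adjust()]
#'   (`"none"` default; `"BH"` recommended for genome-scale scans).
#' @return data frame with one row per domain: `domain_id`, `g_stat` (`NA`
#'   in diversity mode), `p_value`, `sign`, and the table cells `a1`, `a2`,
#'   `b1`, `b2`.
#' @export
enrichment_scan <- function(abundance, group_a, group_b, alpha = 0.05,
                            mode = c("abundance", "diversity"),
                            adjust = "none") {
  mode <- match.arg(mode)
  stopifnot(all(group_a %in% colnames(abundance)),
            all(group_b %in% colnames(abundance)),
            length(intersect(group_a, group_b)) == 0)
  if (mode == "diversity") abundance <- (abundance > 0) + 0L
  ca <- rowSums(abundance[, group_a, drop = FALSE])
  cb <- rowSums(abundance[, group_b, drop = FALSE])
  if (mode == "abundance") {
    ta <- sum(ca); tb <- sum(cb)
    a2 <- ta - ca; b2 <- tb - cb
  } else {
    a2 <- length(group_a) - ca; b2 <- length(group_b) - cb
  }
  res <- lapply(seq_len(nrow(abundance)), function(i) {
    tab <- matrix(c(ca[i], cb[i], a2[i], b2[i]), 2,
                  dimnames = list(c("A", "B"), c("domain", "other")))
    if (mode == "abundance") {
      gt <- g_test_2x2(tab)
      c(g = gt$g_stat, p = gt$p_value)
    } else {
      c(g = NA_real_, p = fisher.test(tab)$p.value)
    }
  })
  g <- vapply(res, `[[`, numeric(1), "g")
  p <- vapply(res, `[[`, numeric(1), "p")
  padj <- p.adjust(p, method = adjust)
  prop_a <- ca / (ca + a2)
  prop_b <- cb / (cb + b2)
  sign <- ifelse(padj <= alpha & prop_a != prop_b,
                 ifelse(prop_a > prop_b, 1L, -1L), 0L)
  data.frame(domain_id = rownames(abundance), g_stat = g, p_value = p,
             sign = sign, a1 = as.integer(ca), a2 = as.integer(a2),
             b1 = as.integer(cb), b2 = as.integer(b2),
             stringsAsFactors = FALSE, row.names = NULL)
}
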