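## Phylostratigraphy: assign each focal-species gene an age class (its
## phylostratum) from the taxonomic lineages of its homology hits. The most
## distant hit wins, following Dollo's reasoning: a gene detected in a
## distant clade was present in the common ancestor, so its origin is placed
## at the oldest node with evidence. Genes with no surviving hit are
## species-specific (stratum k).

#' Build a phylostratum ladder from the focal lineage
#'
#' One stratum per supplied taxon; index 1 is the most inclusive (oldest)
#' taxon and index k the focal species itself.
#'
#' @param focal_lineage character vector of taxon names, root to species;
#'   the last element is the focal species.
#' @return a `phylo_ladder` list with `focal_species`, `taxa`, `k`.
#' @export
#' @examples
#' build_ladder(c("cellular organisms", "Eukaryota", "Gonium pectorale"))
build_ladder <- function(focal_lineage) {
  stopifnot(is.character(focal_lineage), length(focal_lineage) >= 2)
  if (anyDuplicated(focal_lineage)) {
    stop("duplicate taxa in focal lineage: ",
         paste(unique(focal_lineage[duplicated(focal_lineage)]), collapse = ", "))
  }
  structure(list(focal_species = focal_lineage[length(focal_lineage)],
                 taxa = focal_lineage, k = length(focal_lineage)),
            class = "phylo_ladder")
}

## Deepest ladder index whose taxon appears in the subject lineage: the
## divergence point of the subject from the focal lineage.
hit_stratum <- function(lineage, ladder) {
  taxa <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
  shared <- which(ladder$taxa %in% taxa)
  if (length(shared) == 0) {
    warning("hit lineage shares no taxon with the ladder; assigned stratum 1")
    return(1L)
  }
  max(shared)
}

#' Assign one gene to a phylostratum from its homology hits
#'
#' Hits with E-value above `evalue_max` are discarded, as are self-hits
#' (subjects listed in `focal_proteins`). Each surviving hit maps to the
#' deepest ladder index whose taxon appears in its subject lineage; the gene
#' is assigned the *minimum* such index (most distant hit wins). No
#' surviving hits: stratum k, species-specific.
#'
#' @param gene_id gene identifier (all `hits` must be for this gene).
#' @param hits homology-hit data frame ([read_hit_table()] layout) for this
#'   gene; may have zero rows.
#' @param ladder a [build_ladder()] object.
#' @param evalue_max E-value inclusion threshold (default 0.001).
#' @param focal_proteins optional character vector of focal-proteome subject
#'   ids to exclude as self-hits.
#' @return list with `gene_id`, `stratum`, `supporting_hit` (subject id of
#'   the winning hit, `NA` for species-specific genes).
#' @export
assign_phylostratum <- function(gene_id, hits, ladder, evalue_max = 0.001,
                                focal_proteins = NULL) {
  stopifnot(inherits(ladder, "phylo_ladder"))
  if (nrow(hits) > 0) {
    stopifnot(all(hits$query_id == gene_id))
    keep <- hits$evalue <= evalue_max
    if (!is.null(focal_proteins)) {
      keep <- keep & !(hits$subject_id %in% focal_proteins)
    }
    hits <- hits[keep, , drop = FALSE]
  }
  if (nrow(hits) == 0) {
    return(list(gene_id = gene_id, stratum = ladder$k,
                supporting_hit = NA_character_))
  }
  strata <- vapply(hits$lineage, hit_stratum, integer(1), ladder = ladder,
                   USE.NAMES = FALSE)
  s <- min(strata)
  cand <- hits[strata == s, , drop = FALSE]
  cand <- cand[order(cand$evalue, cand$subject_id), , drop = FALSE]
  list(gene_id = gene_id, stratum = s, supporting_hit = cand$subject_id[1])
}

#' Assign phylostrata for all genes in a hit table
#'
#' @param genes character vector of gene ids to assign (genes absent from
#'   `hits` are species-specific by default).
#' @param hits homology-hit data frame for all genes.
#' @inheritParams assign_phylostratum
#' @return data frame with columns `gene_id`, `stratum`, `supporting_hit`.
#' @export
assign_phylostrata <- function(genes, hits, ladder, evalue_max = 0.001,
                               focal_proteins = NULL) {
  out <- lapply(genes, function(g) {
    a <- assign_phylostratum(g, hits[hits$query_id == g, , drop = FALSE],
                             ladder, evalue_max, focal_proteins)
    data.frame(gene_id = a$gene_id, stratum = a$stratum,
               supporting_hit = a$supporting_hit, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Count genes per phylostratum
#'
#' @param assignments data frame from [assign_phylostrata()] (or any frame
#'   with a `stratum` column).
#' @param ladder a [build_ladder()] object.
#' @return named integer vector of length k (`PS1..PSk`), zero-filled,
#'   summing to the number of genes.
#' @export
stratum_counts <- function(assignments, ladder) {
  stopifnot(inherits(ladder, "phylo_ladder"))
  counts <- tabulate(assignments$stratum, nbins = ladder$k)
  names(counts) <- paste0("PS", seq_len(ladder$k))
  counts
}
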