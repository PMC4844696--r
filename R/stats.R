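## Genome summary statistics: GC content, gene density, intron statistics.
##
## Report rounding is half-away-from-zero to the precision used in the
## summary table (1 dp for density and GC percent, 2 dp for introns/gene);
## full precision is retained internally.

#' GC content of nucleotide sequences
#'
#' (G+C) / (A+C+G+T), pooled over all records. Ambiguity codes and N are
#' excluded from both numerator and denominator.
#'
#' @param records named character vector of nucleotide sequences.
#' @return GC fraction in `[0, 1]`.
#' @export
#' @examples
#' gc_content(c(x = "ATGCN"))  # 0.5
gc_content <- function(records) {
  s <- toupper(paste(records, collapse = ""))
  tab <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
  denom <- sum(tab)
  if (denom == 0) stop("no unambiguous A/C/G/T bases in input")
  unname((tab[["G"]] + tab[["C"]]) / denom)
}

#' Genome size in megabases
#'
#' Total residues (including N) divided by 1e6.
#'
#' @param records named character vector of sequences.
#' @return size in Mb.
#' @export
genome_size_mb <- function(records) {
  sum(nchar(records)) / 1e6
}

#' Gene density in genes per megabase
#'
#' @param n_loci number of protein-coding loci.
#' @param genome_size_mb assembly size in Mb (must be positive).
#' @return genes per Mb (full precision; summary tables round to 1 dp).
#' @export
#' @examples
#' round(gene_density(17737, 111.1), 1)  # 159.6
gene_density <- function(n_loci, genome_size_mb) {
  stopifnot(is_count(n_loci))
  if (!is.numeric(genome_size_mb) || genome_size_mb <= 0) {
    stop("genome_size_mb must be positive")
  }
  n_loci / genome_size_mb
}

## Representative transcript per gene: greatest summed exon length, ties
## broken toward the lexicographically smallest transcript_id. How
## multi-transcript genes are counted is a reporting choice; this one is
## deterministic and documented.
representative_transcripts <- function(models) {
  exlen <- models$end - models$start + 1
  agg <- stats::aggregate(exlen,
                          by = list(gene = models$gene_id,
                                    tx = models$transcript_id), FUN = sum)
  agg <- agg[order(agg$gene, -agg$x, agg$tx), , drop = FALSE]
  agg$tx[!duplicated(agg$gene)]
}

#' Intron statistics from gene models
#'
#' Introns are the gaps between consecutive exons of each gene's
#' representative transcript; intron length = next start - previous end - 1.
#' Adjacent exons (gap 0) produce no intron.
#'
#' @param models a `gene_models` data frame ([read_gff3_genes()]).
#' @return list with `introns_per_gene` (mean over genes),
#'   `mean_intron_len_bp` (mean over all introns; 0 with `no_introns = TRUE`
#'   when there are none) and `pct_genes_with_introns` in `[0, 100]`.
#' @export
intron_stats <- function(models) {
  if (nrow(models) == 0) {
    warning("no gene models; returning zeros")
    return(list(introns_per_gene = 0, mean_intron_len_bp = 0,
                pct_genes_with_introns = 0, no_introns = TRUE))
  }
  reps <- representative_transcripts(models)
  m <- models[models$transcript_id %in% reps, , drop = FALSE]
  m <- m[order(m$gene_id, m$start), , drop = FALSE]
  genes <- unique(m$gene_id)
  n_introns <- integer(length(genes))
  lens <- integer(0)
  for (i in seq_along(genes)) {
    e <- m[m$gene_id == genes[i], , drop = FALSE]
    if (nrow(e) > 1) {
      gl <- e$start[-1] - e$end[-nrow(e)] - 1L
      if (any(gl < 0)) stop("overlapping exons in gene ", genes[i])
      gl <- gl[gl > 0]
      n_introns[i] <- length(gl)
      lens <- c(lens, gl)
    }
  }
  list(
    introns_per_gene = mean(n_introns),
    mean_intron_len_bp = if (length(lens) > 0) mean(lens) else 0,
    pct_genes_with_introns = 100 * mean(n_introns > 0),
    no_introns = length(lens) == 0
  )
}

#' Genome summary from sequences and gene models
#'
#' Assembles the per-genome summary row: size, GC percent, locus count, gene
#' density, intron statistics.
#'
#' @param records named character vector of genome sequences.
#' @param models a `gene_models` data frame.
#' @return one-row data frame with columns `genome_size_mb`, `gc_percent`,
#'   `n_loci`, `gene_density`, `introns_per_gene`, `mean_intron_len_bp`,
#'   `pct_genes_with_introns` (full precision).
#' @export
genome_summary <- function(records, models) {
  mb <- genome_size_mb(records)
  n_loci <- length(unique(models$gene_id))
  istats <- intron_stats(models)
  data.frame(
    genome_size_mb = mb,
    gc_percent = 100 * gc_content(records),
    n_loci = n_loci,
    gene_density = gene_density(n_loci, mb),
    introns_per_gene = istats$introns_per_gene,
    mean_intron_len_bp = istats$mean_intron_len_bp,
    pct_genes_with_introns = istats$pct_genes_with_introns
  )
}

#' Format a genome summary at report precision
#'
#' Rounds half-away-from-zero: 1 dp for size, GC percent and density, 2 dp
#' for introns/gene and intron length, 1 dp for percent of genes with
#' introns.
#'
#' @param summary a one-row data frame from [genome_summary()].
#' @return the rounded data frame.
#' @export
format_genome_summary <- function(summary) {
  data.frame(
    genome_size_mb = round_half_up(summary$genome_size_mb, 1),
    gc_percent = round_half_up(summary$gc_percent, 1),
    n_loci = summary$n_loci,
    gene_density = round_half_up(summary$gene_density, 1),
    introns_per_gene = round_half_up(summary$introns_per_gene, 2),
    mean_intron_len_bp = round_half_up(summary$mean_intron_len_bp, 2),
    pct_genes_with_introns = round_half_up(summary$pct_genes_with_introns, 1)
  )
}
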