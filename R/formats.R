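## File formats: FASTA, GFF3, Newick, tab-separated hit tables and
## family-by-species copy-number matrices.
##
## Coordinate convention: GFF3-native 1-based inclusive coordinates are kept
## internally everywhere (exon (1,100) covers residues 1..100). Introns are
## never read from file; they are derived from exon gaps by the stats module.

#' Read sequences from a FASTA file
#'
#' Sequences are returned as a named character vector (names are the first
#' whitespace-delimited token of each header). Sequences are upper-cased on
#' read; wrapped lines are concatenated. In nucleotide context `rna_to_dna`
#' maps U to T.
#'
#' @param path path to a FASTA file.
#' @param rna_to_dna logical; if `TRUE`, map U to T (nucleotide context only).
#' @return named character vector of sequences, in file order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "AC", "GT", ">b", "GG"), tf)
#' read_fasta(tf)
read_fasta <- function(path, rna_to_dna = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (rna_to_dna) seqs <- chartr("U", "T", seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Builds one gene model per mRNA (or transcript) feature, linking exons to
#' their transcript through the `Parent` attribute and transcripts to genes
#' through theirs. Features of unknown type are ignored. Exons are sorted
#' ascending by start.
#'
#' @param path path to a GFF3 file.
#' @return a `data.frame` of class `gene_models` with one row per exon and
#'   columns `gene_id`, `transcript_id`, `strand`, `start`, `end`.
#' @export
read_gff3_genes <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  id <- as.character(gr$ID)
  parent <- vapply(as.list(gr$Parent), function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[1])
  }, character(1))

  is_tx <- type %in% c("mRNA", "transcript")
  is_exon <- type == "exon"
  if (!any(is_tx)) stop("no mRNA/transcript features in ", path)

  tx_id <- id[is_tx]
  tx_gene <- ifelse(is.na(parent[is_tx]), tx_id, parent[is_tx])
  tx_strand <- as.character(BiocGenerics::strand(gr))[is_tx]
  names(tx_gene) <- tx_id
  names(tx_strand) <- tx_id

  ep <- parent[is_exon]
  if (anyNA(ep)) stop("exon without a Parent attribute in ", path)
  orphan <- setdiff(unique(ep), tx_id)
  if (length(orphan) > 0) {
    stop("exon Parent references no mRNA: ", paste(orphan, collapse = ", "))
  }
  models <- data.frame(
    gene_id = unname(tx_gene[ep]),
    transcript_id = ep,
    strand = unname(tx_strand[ep]),
    start = BiocGenerics::start(gr)[is_exon],
    end = BiocGenerics::end(gr)[is_exon],
    stringsAsFactors = FALSE
  )
  if (any(models$end < models$start)) stop("exon with end < start in ", path)
  models <- models[order(models$transcript_id, models$start), , drop = FALSE]
  rownames(models) <- NULL
  ## enforce non-overlap within each transcript
  for (tx in unique(models$transcript_id)) {
    m <- models[models$transcript_id == tx, , drop = FALSE]
    if (nrow(m) > 1 && any(m$start[-1] <= m$end[-nrow(m)])) {
      stop("overlapping exons in transcript ", tx)
    }
  }
  class(models) <- c("gene_models", "data.frame")
  models
}

#' Write gene models to a GFF3 file
#'
#' Inverse of [read_gff3_genes()]: emits gene, mRNA and exon features with
#' ID/Parent attributes. Used by the synthetic-genome generator.
#'
#' @param models a `gene_models` data frame.
#' @param path output path.
#' @param seqid chromosome/scaffold name for all features.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path, seqid = "chr1") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in unique(models$gene_id)) {
    mg <- models[models$gene_id == g, , drop = FALSE]
    writeLines(sprintf("%s\tvolvocomp\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       seqid, min(mg$start), max(mg$end), mg$strand[1], g), con)
    for (tx in unique(mg$transcript_id)) {
      mt <- mg[mg$transcript_id == tx, , drop = FALSE]
      writeLines(sprintf("%s\tvolvocomp\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         seqid, min(mt$start), max(mt$end), mt$strand[1], tx, g), con)
      for (i in seq_len(nrow(mt))) {
        writeLines(sprintf("%s\tvolvocomp\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                           seqid, mt$start[i], mt$end[i], mt$strand[i], tx, i, tx), con)
      }
    }
  }
  invisible(path)
}

#' Read a rooted species tree from a Newick file or string
#'
#' Unlabeled internal nodes receive deterministic labels `N1..Nk` assigned in
#' preorder (root first). Branch lengths and existing labels are preserved;
#' multifurcations are kept as-is.
#'
#' @param path path to a Newick file, or `NULL` if `text` is given.
#' @param text a Newick string (alternative to `path`).
#' @return an [ape::phylo] tree with all internal nodes labelled.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (!file.exists(path)) stop("Newick file not found: ", path)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  .check_parens(text)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("failed to parse Newick string")
  label_internal_nodes(tr)
}

## Balanced-parenthesis pre-check so parse errors carry a character offset.
.check_parens <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop("unbalanced ')' in Newick string at character ", i)
    }
  }
  if (depth != 0L) {
    stop("unbalanced '(' in Newick string: ", depth,
         " unclosed at character ", length(chars))
  }
  invisible(TRUE)
}

#' Assign deterministic labels to unlabeled internal nodes
#'
#' @param tree an [ape::phylo] tree.
#' @return the tree with every internal node labelled; unlabeled nodes get
#'   `N1..Nk` in preorder.
#' @export
label_internal_nodes <- function(tree) {
  n_int <- tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", n_int)
  lab[is.na(lab)] <- ""
  ntip <- length(tree$tip.label)
  ## preorder over internal nodes: root, then order of first appearance as a
  ## parent in the cladewise edge list
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  pre <- unique(c(ntip + 1L, edge[edge[, 2] > ntip, 2]))
  k <- 0L
  for (node in pre) {
    i <- node - ntip
    if (!nzchar(lab[i])) {
      k <- k + 1L
      newlab <- paste0("N", k)
      if (newlab %in% c(tree$tip.label, lab)) {
        stop("auto-label ", newlab, " clashes with an existing node label")
      }
      lab[i] <- newlab
    }
  }
  if (anyDuplicated(c(tree$tip.label, lab))) {
    stop("duplicate node labels after labelling")
  }
  tree$node.label <- lab
  tree
}

#' Write a tree to a Newick file or string
#'
#' @param tree an [ape::phylo] tree.
#' @param path output path; if `NULL` the Newick string is returned.
#' @return `path` invisibly, or the Newick string when `path` is `NULL`.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

#' Read a homology or domain hit table
#'
#' Tab-separated, one hit per row, comment lines starting `#` skipped.
#' Homology rows have 5 columns: query id, subject id, E-value, bit score and
#' the subject taxonomic lineage, root to leaf, `;`-separated (surrounding
#' spaces are stripped). Domain rows have 4 columns: protein id, domain id,
#' bit score, E-value.
#'
#' @param path path to the table.
#' @param kind `"homology"` or `"domain"`.
#' @return data frame of hits in file order. Homology: `query_id`,
#'   `subject_id`, `evalue`, `bitscore`, `lineage` (the `;`-joined string).
#'   Domain: `protein_id`, `domain_id`, `bitscore`, `evalue`.
#' @export
read_hit_table <- function(path, kind = c("homology", "domain")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  ncol_expect <- if (kind == "homology") 5L else 4L
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != ncol_expect)
  if (length(bad) > 0) {
    stop("line ", lineno[bad[1]], ": expected ", ncol_expect,
         " tab-separated columns, found ", lengths(fields)[bad[1]])
  }
  m <- do.call(rbind, fields)
  parse_num <- function(x, what, col) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      stop("line ", lineno[which(is.na(v))[1]], ": unparseable ", what)
    }
    v
  }
  if (kind == "homology") {
    ev <- parse_num(m[, 3], "E-value")
    if (any(ev < 0)) stop("negative E-value at line ", lineno[which(ev < 0)[1]])
    lineage <- vapply(strsplit(m[, 5], ";", fixed = TRUE),
                      function(x) paste(trimws(x), collapse = ";"), character(1))
    data.frame(query_id = m[, 1], subject_id = m[, 2], evalue = ev,
               bitscore = parse_num(m[, 4], "bit score"),
               lineage = lineage, stringsAsFactors = FALSE)
  } else {
    ev <- parse_num(m[, 4], "E-value")
    if (any(ev < 0)) stop("negative E-value at line ", lineno[which(ev < 0)[1]])
    data.frame(protein_id = m[, 1], domain_id = m[, 2],
               bitscore = parse_num(m[, 3], "bit score"),
               evalue = ev, stringsAsFactors = FALSE)
  }
}

#' Write a homology or domain hit table
#'
#' @param hits data frame in the layout produced by [read_hit_table()].
#' @param path output path.
#' @param kind `"homology"` or `"domain"`.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path, kind = c("homology", "domain")) {
  kind <- match.arg(kind)
  cols <- if (kind == "homology") {
    c("query_id", "subject_id", "evalue", "bitscore", "lineage")
  } else {
    c("protein_id", "domain_id", "bitscore", "evalue")
  }
  stopifnot(all(cols %in% names(hits)))
  write.table(hits[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-family copy-number matrix
#'
#' TSV layout: header row of species ids, first column family ids, entries
#' non-negative integer copy numbers.
#'
#' @param path path to the matrix TSV.
#' @return integer matrix, `rownames` = family ids, `colnames` = species ids.
#' @export
read_family_matrix <- function(path) {
  if (!file.exists(path)) stop("family matrix not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  fam <- as.character(df[[1]])
  if (anyDuplicated(fam)) {
    stop("duplicate family id(s): ",
         paste(unique(fam[duplicated(fam)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("duplicate species id(s)")
  storage.mode(m) <- "double"
  if (anyNA(m) || any(m < 0) || any(m != floor(m))) {
    stop("family matrix entries must be non-negative integers")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- fam
  m
}

#' Write a gene-family copy-number matrix
#'
#' @param mat integer matrix with family rownames and species colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_family_matrix <- function(mat, path) {
  stopifnot(!is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(family = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
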