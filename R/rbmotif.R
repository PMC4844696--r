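## CDK phosphorylation-site motifs in retinoblastoma (RB/MAT3) family
## proteins. Cyclin-CDK dimers phosphorylate RB on serine/threonine
## residues; the standard CDK substrate consensus is the minimal [S/T]P
## dipeptide and the full [S/T]PxK/R site. Both classes are reported so
## cross-species comparisons are robust to the consensus choice. Region
## annotations (N, RB-A, linker L1, RB-B, C) are inputs; sites falling
## between annotated regions are binned explicitly, because the loss of
## sites between the E2F/DP pocket and the C-terminal domain is the key
## cross-species contrast.

.AA20 <- "ACDEFGHIKLMNPQRSTVWY"

#' Scan a protein sequence for putative CDK phosphorylation sites
#'
#' Minimal sites are `[ST]P` dipeptides; full sites additionally have K or R
#' at position +3 (`[ST]Px[KR]`). Every full site is also reported as a
#' minimal site. Positions are 1-based indices of the phospho-acceptor S/T.
#' Scanning is case-insensitive.
#'
#' @param seq a single amino-acid sequence (character scalar), or a named
#'   length-1 character vector whose name is used as `protein_id`.
#' @param protein_id protein id recorded in the output (defaults to the
#'   sequence name, else `"seq"`).
#' @return data frame with columns `protein_id`, `position`, `motif_class`
#'   (`"minimal"` or `"full"`), ordered by position.
#' @export
#' @examples
#' scan_cdk_sites(c(rb1 = "AAASPAA"))
scan_cdk_sites <- function(seq, protein_id = NULL) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (is.null(protein_id)) protein_id <- names(seq) %||% "seq"
  s <- toupper(seq[[1]])
  bad <- setdiff(strsplit(s, "")[[1]], strsplit(.AA20, "")[[1]])
  if (length(bad) > 0) {
    stop("non-amino-acid character(s) in sequence: ",
         paste(unique(bad), collapse = ", "))
  }
  find_all <- function(pattern) {
    m <- gregexpr(pattern, s, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  minimal <- find_all("(?=[ST]P)")
  full <- find_all("(?=[ST]P.[KR])")
  out <- rbind(
    if (length(minimal) > 0)
      data.frame(protein_id = protein_id, position = minimal,
                 motif_class = "minimal", stringsAsFactors = FALSE),
    if (length(full) > 0)
      data.frame(protein_id = protein_id, position = full,
                 motif_class = "full", stringsAsFactors = FALSE)
  )
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), position = integer(0),
                      motif_class = character(0), stringsAsFactors = FALSE)
  }
  out[order(out$position, out$motif_class), , drop = FALSE]
}

#' Region annotation for an RB-family protein
#'
#' @param protein_id protein id.
#' @param regions data frame with columns `region`, `start`, `end` (1-based
#'   inclusive residue spans). Regions must be non-overlapping and ordered
#'   along the sequence; the canonical order is N, RB-A, L1, RB-B, C.
#' @return a `region_annotation` object.
#' @export
region_annotation <- function(protein_id, regions) {
  stopifnot(all(c("region", "start", "end") %in% names(regions)),
            all(regions$end >= regions$start))
  regions <- regions[order(regions$start), , drop = FALSE]
  if (nrow(regions) > 1 &&
      any(regions$start[-1] <= regions$end[-nrow(regions)])) {
    stop("overlapping region spans for ", protein_id)
  }
  rownames(regions) <- NULL
  structure(list(protein_id = protein_id, regions = regions),
            class = "region_annotation")
}

#' Count motif sites per annotated region
#'
#' Sites are partitioned among the annotated regions plus inter-region bins:
#' `before:<first>` for sites upstream of the first region,
#' `<r1>/<r2>` for sites between consecutive regions (the `RB-B/C` bin is
#' the key comparison), and `after:<last>` downstream of the last.
#'
#' @param sites data frame from [scan_cdk_sites()] (use one `motif_class`).
#' @param annotation a [region_annotation()] object.
#' @return named integer vector of counts over regions and inter-region
#'   bins; sums to `nrow(sites)`.
#' @export
sites_by_region <- function(sites, annotation) {
  stopifnot(inherits(annotation, "region_annotation"))
  reg <- annotation$regions
  bins <- character(0)
  lo <- integer(0); hi <- integer(0)
  add_bin <- function(name, a, b) {
    bins <<- c(bins, name); lo <<- c(lo, a); hi <<- c(hi, b)
  }
  if (reg$start[1] > 1) add_bin(paste0("before:", reg$region[1]),
                                1L, reg$start[1] - 1L)
  for (i in seq_len(nrow(reg))) {
    add_bin(reg$region[i], reg$start[i], reg$end[i])
    if (i < nrow(reg) && reg$start[i + 1] > reg$end[i] + 1) {
      add_bin(paste0(reg$region[i], "/", reg$region[i + 1]),
              reg$end[i] + 1L, reg$start[i + 1] - 1L)
    }
  }
  add_bin(paste0("after:", reg$region[nrow(reg)]),
          reg$end[nrow(reg)] + 1L, .Machine$integer.max)
  counts <- vapply(seq_along(bins), function(i) {
    sum(sites$position >= lo[i] & sites$position <= hi[i])
  }, integer(1))
  setNames(counts, bins)
}

## Map ungapped residue positions to alignment columns for one gapped
## sequence ("-" and "." are gaps).
ungapped_to_column <- function(gapped) {
  chars <- strsplit(gapped, "")[[1]]
  which(!(chars %in% c("-", ".")))
}

#' Classify aligned motif-site columns as conserved or species-specific
#'
#' Site positions (on the ungapped sequences) are mapped through the
#' alignment; a column is `conserved` when every sequence has a site mapping
#' to it, `species-specific` when exactly one does, and `partial` otherwise.
#'
#' @param alignment named character vector of aligned (gapped) sequences of
#'   equal length.
#' @param sites_list named list (same names) of site data frames from
#'   [scan_cdk_sites()] computed on the *ungapped* sequences, or of integer
#'   position vectors.
#' @return data frame with columns `column` (alignment column of the S/T)
#'   and `status`; one row per column carrying at least one site.
#' @export
compare_conservation <- function(alignment, sites_list) {
  stopifnot(!is.null(names(alignment)),
            setequal(names(alignment), names(sites_list)),
            length(unique(nchar(alignment))) == 1)
  n <- length(alignment)
  col_hits <- list()
  for (nm in names(alignment)) {
    map <- ungapped_to_column(alignment[[nm]])
    pos <- sites_list[[nm]]
    if (is.data.frame(pos)) pos <- unique(pos$position)
    if (any(pos > length(map))) {
      stop("site position beyond ungapped length for ", nm)
    }
    col_hits[[nm]] <- map[pos]
  }
  cols <- sort(unique(unlist(col_hits)))
  if (length(cols) == 0) {
    return(data.frame(column = integer(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  n_with <- vapply(cols, function(cl) {
    sum(vapply(col_hits, function(h) cl %in% h, logical(1)))
  }, integer(1))
  status <- ifelse(n_with == n, "conserved",
                   ifelse(n_with == 1, "species-specific", "partial"))
  data.frame(column = cols, status = status, stringsAsFactors = FALSE)
}

#' Length of the pocket linker (L1) region
#'
#' @param annotation a [region_annotation()] object containing an `L1` row.
#' @return span length in residues (end - start + 1).
#' @export
linker_length <- function(annotation) {
  stopifnot(inherits(annotation, "region_annotation"))
  r <- annotation$regions
  i <- which(r$region == "L1")
  if (length(i) != 1) stop("annotation has no unique L1 region")
  as.integer(r$end[i] - r$start[i] + 1)
}

#' Read region annotations from a TSV file
#'
#' Columns: `protein_id`, `region`, `start`, `end`.
#'
#' @param path path to the TSV.
#' @return named list of [region_annotation()] objects, one per protein.
#' @export
read_region_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "region", "start", "end") %in% names(df)))
  out <- lapply(split(df, df$protein_id), function(d) {
    region_annotation(d$protein_id[1],
                      d[, c("region", "start", "end"), drop = FALSE])
  })
  out
}
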