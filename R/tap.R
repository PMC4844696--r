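## Rule-based classification of transcription-associated proteins (TAPs):
## transcription factors and regulators. A family rule lists 1-3 mandatory
## domains (each with a gathering threshold, the minimum bit score that
## counts) and up to 6 forbidden domains whose presence vetoes membership at
## any score. A protein eligible for several families goes to the one with
## the highest score (maximum bit score over its mandatory-domain hits);
## score ties break toward the lexicographically smallest family name.

#' Define a TAP family classification rule
#'
#' @param family family name.
#' @param mandatory character vector of 1-3 mandatory domain ids.
#' @param forbidden character vector of 0-6 forbidden domain ids.
#' @param ga named numeric vector of gathering thresholds (minimum bit
#'   score); must cover every mandatory domain.
#' @return a `tap_rule` object.
#' @export
tap_rule <- function(family, mandatory, forbidden = character(0), ga) {
  stopifnot(is.character(family), length(family) == 1, nzchar(family),
            length(mandatory) >= 1, length(mandatory) <= 3,
            length(forbidden) <= 6)
  if (length(intersect(mandatory, forbidden)) > 0) {
    stop("mandatory and forbidden domains overlap in family ", family)
  }
  missing_ga <- setdiff(mandatory, names(ga))
  if (length(missing_ga) > 0) {
    stop("no gathering threshold for mandatory domain(s): ",
         paste(missing_ga, collapse = ", "), " in family ", family)
  }
  structure(list(family = family, mandatory = mandatory,
                 forbidden = forbidden, ga = ga[mandatory]),
            class = "tap_rule")
}

#' Calibrate a gathering threshold from true-positive hits
#'
#' The threshold is the lowest bit score among known true positives, so that
#' every true positive passes and it is as strict as the evidence allows.
#'
#' @param true_positive_hits domain-hit data frame (or numeric vector of bit
#'   scores) of known true positives; must be non-empty.
#' @return the minimum bit score.
#' @export
calibrate_ga <- function(true_positive_hits) {
  scores <- if (is.numeric(true_positive_hits)) true_positive_hits else
    true_positive_hits$bitscore
  if (length(scores) == 0) stop("no true-positive hits to calibrate from")
  min(scores)
}

#' Classify one protein into a TAP family
#'
#' A family is eligible iff every mandatory domain has a hit with bit score
#' at or above its gathering threshold and no hit matches any forbidden
#' domain (at any score). Among eligible families the call is the one with
#' the highest family score = max bit score over mandatory-domain hits; ties
#' go to the lexicographically smallest family name.
#'
#' @param hits domain-hit data frame for a single protein.
#' @param rules non-empty list of [tap_rule()] objects.
#' @return list with `protein_id`, `family` (`NA` if no family is eligible)
#'   and `score` (`NA` when unclassified).
#' @export
classify_protein <- function(hits, rules) {
  if (length(rules) == 0) stop("rules must be non-empty")
  pid <- unique(hits$protein_id)
  stopifnot(length(pid) == 1)
  best_family <- NA_character_
  best_score <- NA_real_
  for (r in rules) {
    if (any(hits$domain_id %in% r$forbidden)) next
    ok <- vapply(r$mandatory, function(d) {
      any(hits$domain_id == d & hits$bitscore >= r$ga[[d]])
    }, logical(1))
    if (!all(ok)) next
    score <- max(hits$bitscore[hits$domain_id %in% r$mandatory])
    if (is.na(best_score) || score > best_score ||
        (score == best_score && r$family < best_family)) {
      best_family <- r$family
      best_score <- score
    }
  }
  list(protein_id = pid, family = best_family,
       score = if (is.na(best_family)) NA_real_ else best_score)
}

#' Classify every protein in a domain-hit table
#'
#' @param hits domain-hit data frame for many proteins.
#' @param rules non-empty list of [tap_rule()] objects.
#' @return data frame with columns `protein_id`, `family`, `score`; one row
#'   per protein, each assigned to at most one family.
#' @export
classify_proteins <- function(hits, rules) {
  if (length(rules) == 0) stop("rules must be non-empty")
  prots <- unique(hits$protein_id)
  out <- lapply(prots, function(p) {
    cl <- classify_protein(hits[hits$protein_id == p, , drop = FALSE], rules)
    data.frame(protein_id = cl$protein_id, family = cl$family,
               score = cl$score, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' TAP family abundance matrix across species
#'
#' @param hits_by_species named list of domain-hit data frames, one per
#'   species.
#' @param rules non-empty list of [tap_rule()] objects.
#' @return integer matrix, families x species; entry = number of proteins of
#'   that species called to that family. Each protein contributes to at most
#'   one family, so column sums never exceed proteome sizes.
#' @export
tap_abundance <- function(hits_by_species, rules) {
  stopifnot(!is.null(names(hits_by_species)),
            all(nzchar(names(hits_by_species))))
  families <- sort(vapply(rules, `[[`, character(1), "family"))
  mat <- matrix(0L, nrow = length(families), ncol = length(hits_by_species),
                dimnames = list(families, names(hits_by_species)))
  for (sp in names(hits_by_species)) {
    calls <- classify_proteins(hits_by_species[[sp]], rules)
    tab <- table(calls$family[!is.na(calls$family)])
    mat[names(tab), sp] <- as.integer(tab)
  }
  mat
}

#' Read TAP family rules from a TSV or YAML file
#'
#' TSV columns: `family`, `mandatory` (comma-separated domain ids),
#' `forbidden` (comma-separated, may be empty) and `ga` (comma-separated
#' `domain=score` pairs). YAML: a list of mappings with the same keys
#' (`ga` a mapping domain -> score).
#'
#' @param path path to the rule file (`.yml`/`.yaml` parsed as YAML,
#'   anything else as TSV).
#' @return list of [tap_rule()] objects.
#' @export
read_tap_rules <- function(path) {
  if (!file.exists(path)) stop("rule file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    raw <- yaml::read_yaml(path)
    return(lapply(raw, function(r) {
      tap_rule(r$family, unlist(r$mandatory),
               as.character(unlist(r$forbidden %||% character(0))),
               unlist(r$ga))
    }))
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("family", "mandatory", "forbidden", "ga") %in% names(df)))
  lapply(seq_len(nrow(df)), function(i) {
    split_list <- function(x) {
      if (is.na(x) || !nzchar(trimws(x))) character(0) else
        trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    }
    ga_pairs <- split_list(df$ga[i])
    kv <- strsplit(ga_pairs, "=", fixed = TRUE)
    ga <- setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                   vapply(kv, `[`, character(1), 1))
    tap_rule(df$family[i], split_list(df$mandatory[i]),
             split_list(df$forbidden[i]), ga)
  })
}

#' Write TAP family rules to a TSV file
#'
#' @param rules list of [tap_rule()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tap_rules <- function(rules, path) {
  df <- do.call(rbind, lapply(rules, function(r) {
    data.frame(family = r$family,
               mandatory = paste(r$mandatory, collapse = ","),
               forbidden = paste(r$forbidden, collapse = ","),
               ga = paste(sprintf("%s=%g", names(r$ga), r$ga), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
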