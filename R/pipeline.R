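## End-to-end orchestration: one configuration drives synthetic-data
## generation and the analysis stages in dependency order, writing
## deterministic TSV outputs plus a JSON manifest of parameters and file
## checksums. Rerunning with the same configuration and seed is
## byte-identical (no timestamps in any output).

.default_config <- function() {
  list(
    seed = 1L,
    stages = c("synth", "stats", "phylostrat", "tap", "enrich", "parsimony"),
    synth = list(
      tree = "((Chlamydomonas,(Gonium,Volvox)),Chlorella);",
      gain_rate = 3, loss_rate = 1, dup_rate = 0.05, root_families = 40,
      n_genes = 60, n_members_per_family = 4, n_background = 30,
      noise = 0, gc = 0.641, intron_len_mean = 200
    ),
    phylostrat = list(evalue_max = 0.001,
                      ladder = c("cellular organisms", "Eukaryota",
                                 "Viridiplantae", "Chlorophyta",
                                 "Chlorophyceae", "Chlamydomonadales",
                                 "Goniaceae", "Gonium", "Gonium pectorale")),
    tap = list(),
    enrich = list(alpha = 0.05, group_a = c("Gonium", "Volvox"),
                  group_b = c("Chlamydomonas", "Chlorella"), adjust = "none"),
    parsimony = list(mode = "wagner-asym", gain_cost = 2, loss_cost = 1)
  )
}

.known_keys <- list(
  top = c("seed", "stages", "synth", "phylostrat", "tap", "enrich",
          "parsimony"),
  synth = c("tree", "gain_rate", "loss_rate", "dup_rate", "root_families",
            "n_genes", "n_members_per_family", "n_background", "noise", "gc",
            "intron_len_mean"),
  phylostrat = c("evalue_max", "ladder"),
  tap = character(0),
  enrich = c("alpha", "group_a", "group_b", "adjust"),
  parsimony = c("mode", "gain_cost", "loss_cost")
)

#' Validate and complete a pipeline configuration
#'
#' Fills defaults (alpha 0.05, E-value threshold 0.001, asymmetric gain:loss
#' 2:1), rejects unknown keys, and checks cross-references (enrichment
#' groups disjoint, parsimony mode known, stage names known).
#'
#' @param config a nested list, or the path to a YAML file holding one;
#'   `NULL` gives the built-in demo configuration.
#' @return the completed configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- .default_config()
  if (is.null(config)) config <- list()
  unknown <- setdiff(names(config), .known_keys$top)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  merged <- def
  for (key in names(config)) {
    if (is.list(def[[key]]) && !is.null(names(def[[key]]))) {
      sub_unknown <- setdiff(names(config[[key]]), .known_keys[[key]])
      if (length(sub_unknown) > 0) {
        stop("unknown config key(s) under '", key, "': ",
             paste(sub_unknown, collapse = ", "))
      }
      merged[[key]] <- utils::modifyList(def[[key]], config[[key]])
    } else {
      merged[[key]] <- config[[key]]
    }
  }
  bad_stage <- setdiff(merged$stages, def$stages)
  if (length(bad_stage) > 0) {
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  }
  stopifnot(is.numeric(merged$seed), length(merged$seed) == 1)
  merged$seed <- as.integer(merged$seed)
  if (!merged$parsimony$mode %in% c("wagner-sym", "wagner-asym", "dollo")) {
    stop("parsimony mode must be wagner-sym, wagner-asym or dollo")
  }
  if (length(intersect(merged$enrich$group_a, merged$enrich$group_b)) > 0) {
    stop("enrichment groups must be disjoint")
  }
  tree <- read_newick(text = merged$synth$tree)
  species <- tree$tip.label
  for (g in c("group_a", "group_b")) {
    missing <- setdiff(merged$enrich[[g]], species)
    if (length(missing) > 0) {
      stop("enrichment ", g, " species not in the species tree: ",
           paste(missing, collapse = ", "))
    }
  }
  merged
}

## Demo TAP rules used when the config supplies none.
.demo_tap_rules <- function() {
  list(
    tap_rule("bZIP", mandatory = "PF00170",
             ga = c(PF00170 = 25)),
    tap_rule("MYB", mandatory = "PF00249", forbidden = "PF01388",
             ga = c(PF00249 = 20)),
    tap_rule("E2F_DP", mandatory = "PF02319", forbidden = "PF00249",
             ga = c(PF02319 = 30))
  )
}

#' Run the pipeline end-to-end
#'
#' Stages run in dependency order (synth first); each stage writes TSV
#' outputs under `out_dir` and the run finishes with a `manifest.json`
#' recording every parameter used and the MD5 checksum of every output, so
#' a rerun with the same configuration can be verified byte-identical.
#'
#' @param config a configuration list or YAML path ([validate_config()] is
#'   applied).
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (list with `parameters`, `stages`,
#'   `outputs` mapping file name -> md5).
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, msg) {
    message("[", stage, "] ", msg)
  }
  outputs <- character(0)
  add_output <- function(path) outputs <<- c(outputs, path)
  stage_info <- list()

  tree <- read_newick(text = cfg$synth$tree)
  species <- tree$tip.label

  if ("synth" %in% cfg$stages) {
    log_stage("synth", "generating inputs with planted truth")
    ## gene families
    fam <- simulate_family_evolution(tree, evolution_params(
      gain_rate = cfg$synth$gain_rate, loss_rate = cfg$synth$loss_rate,
      dup_rate = cfg$synth$dup_rate, root_families = cfg$synth$root_families,
      seed = child_seed(cfg$seed, 1)))
    write_family_matrix(fam$matrix, file.path(out_dir, "families.tsv"))
    add_output(file.path(out_dir, "families.tsv"))
    ## toy genome
    toy <- simulate_toy_genome(cfg$synth$n_genes,
                               intron_len_mean = cfg$synth$intron_len_mean,
                               gc = cfg$synth$gc,
                               seed = child_seed(cfg$seed, 2))
    write_fasta(toy$genome, file.path(out_dir, "genome.fa"))
    write_gff3(toy$models, file.path(out_dir, "genes.gff3"))
    add_output(file.path(out_dir, "genome.fa"))
    add_output(file.path(out_dir, "genes.gff3"))
    ## homology hits with planted strata
    ladder <- build_ladder(cfg$phylostrat$ladder)
    genes <- sprintf("gene%03d", seq_len(cfg$synth$n_genes))
    planted <- setNames(
      local_seed(child_seed(cfg$seed, 3),
                 sample(seq_len(ladder$k), cfg$synth$n_genes, replace = TRUE)),
      genes)
    hh <- simulate_homology_hits(genes, ladder, planted,
                                 seed = child_seed(cfg$seed, 4),
                                 evalue_max = cfg$phylostrat$evalue_max)
    write_hit_table(hh, file.path(out_dir, "homology_hits.tsv"), "homology")
    add_output(file.path(out_dir, "homology_hits.tsv"))
    writeLines(ladder$taxa, file.path(out_dir, "ladder.txt"))
    add_output(file.path(out_dir, "ladder.txt"))
    ## TAP proteomes, one per species
    rules <- .demo_tap_rules()
    write_tap_rules(rules, file.path(out_dir, "tap_rules.tsv"))
    add_output(file.path(out_dir, "tap_rules.tsv"))
    for (i in seq_along(species)) {
      tp <- simulate_tap_proteome(rules, cfg$synth$n_members_per_family,
                                  cfg$synth$n_background,
                                  noise = cfg$synth$noise,
                                  seed = child_seed(cfg$seed, 10 + i))
      write_hit_table(tp$hits,
                      file.path(out_dir, paste0("domains_", species[i], ".tsv")),
                      "domain")
      add_output(file.path(out_dir, paste0("domains_", species[i], ".tsv")))
    }
    write_newick(tree, file.path(out_dir, "tree.nwk"))
    add_output(file.path(out_dir, "tree.nwk"))
    stage_info$synth <- list(planted_strata = as.list(planted),
                             n_family_events = nrow(fam$truth$events))
  }

  if ("stats" %in% cfg$stages) {
    log_stage("stats", "genome summary statistics")
    genome <- read_fasta(file.path(out_dir, "genome.fa"))
    models <- read_gff3_genes(file.path(out_dir, "genes.gff3"))
    summ <- format_genome_summary(genome_summary(genome, models))
    write.table(summ, file.path(out_dir, "summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    add_output(file.path(out_dir, "summary.tsv"))
    stage_info$stats <- as.list(summ)
  }

  if ("phylostrat" %in% cfg$stages) {
    log_stage("phylostrat", "assigning phylostrata")
    ladder <- build_ladder(readLines(file.path(out_dir, "ladder.txt")))
    hh <- read_hit_table(file.path(out_dir, "homology_hits.tsv"), "homology")
    genes <- sprintf("gene%03d", seq_len(cfg$synth$n_genes))
    asg <- assign_phylostrata(genes, hh, ladder,
                              evalue_max = cfg$phylostrat$evalue_max)
    write.table(asg, file.path(out_dir, "strata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    add_output(file.path(out_dir, "strata.tsv"))
    counts <- stratum_counts(asg, ladder)
    write.table(data.frame(stratum = names(counts), n_genes = counts),
                file.path(out_dir, "stratum_counts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    add_output(file.path(out_dir, "stratum_counts.tsv"))
    stage_info$phylostrat <- as.list(counts)
  }

  tap_mat <- NULL
  if ("tap" %in% cfg$stages) {
    log_stage("tap", "classifying transcription-associated proteins")
    rules <- read_tap_rules(file.path(out_dir, "tap_rules.tsv"))
    hits_by_species <- setNames(lapply(species, function(sp) {
      read_hit_table(file.path(out_dir, paste0("domains_", sp, ".tsv")),
                     "domain")
    }), species)
    tap_mat <- tap_abundance(hits_by_species, rules)
    write_family_matrix(tap_mat, file.path(out_dir, "tap_matrix.tsv"))
    add_output(file.path(out_dir, "tap_matrix.tsv"))
    stage_info$tap <- list(n_families = nrow(tap_mat),
                           total_calls = sum(tap_mat))
  }

  if ("enrich" %in% cfg$stages) {
    log_stage("enrich", "domain enrichment scan")
    hits_by_species <- setNames(lapply(species, function(sp) {
      read_hit_table(file.path(out_dir, paste0("domains_", sp, ".tsv")),
                     "domain")
    }), species)
    dm <- domain_matrix(hits_by_species)
    scan <- enrichment_scan(dm$abundance, cfg$enrich$group_a,
                            cfg$enrich$group_b, alpha = cfg$enrich$alpha,
                            adjust = cfg$enrich$adjust)
    write.table(scan, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    add_output(file.path(out_dir, "enrichment.tsv"))
    stage_info$enrich <- list(n_over = sum(scan$sign == 1),
                              n_under = sum(scan$sign == -1))
  }

  if ("parsimony" %in% cfg$stages) {
    log_stage("parsimony", paste("ancestral reconstruction,",
                                 cfg$parsimony$mode))
    mat <- read_family_matrix(file.path(out_dir, "families.tsv"))
    recon <- switch(cfg$parsimony$mode,
      "wagner-sym" = wagner_reconstruct(tree, mat, cost_model(1, 1)),
      "wagner-asym" = wagner_reconstruct(
        tree, mat, cost_model(cfg$parsimony$gain_cost,
                              cfg$parsimony$loss_cost)),
      "dollo" = dollo_reconstruct(tree, mat))
    bs <- branch_summary(recon)
    write.table(bs, file.path(out_dir, "branches.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    add_output(file.path(out_dir, "branches.tsv"))
    write_family_matrix(t(recon$node_states),
                        file.path(out_dir, "node_states.tsv"))
    add_output(file.path(out_dir, "node_states.tsv"))
    stage_info$parsimony <- list(total_cost = recon$total_cost,
                                 net_by_branch = setNames(as.list(bs$net),
                                                          bs$branch))
  }

  manifest <- list(
    parameters = cfg,
    stages = stage_info,
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
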