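#' Pipeline configuration
#'
#' Bundles every tunable threshold of the pipeline with its default:
#' filtering minima 5/5, pairs must co-occur in more than 5 samples to
#' merge, target false-positive rate 1e-4, 1000 null matrices, 100
#' clustering runs per environment, node/edge support minimum 10, consensus
#' edge support 70, phylogenetic matching tolerances 0.05 (redundancy
#' comparisons) and 0.1 (pathway classification), 20% genome-size
#' tolerance, and a large-assemblage threshold of 5 members.
#'
#' @param occurrence_path,annotation_path,pathway_path paths to the input
#'   TSVs (occurrence matrix, sample annotation, genome x pathway table).
#' @param distance_path species- or genus-level distance TSV (`NULL` to
#'   skip phylogeny-dependent stages).
#' @param species_to_genus_path two-column TSV (`species`, `genus`) when
#'   `distance_path` is species-level.
#' @param cost_path amino-acid cost TSV (`NULL` to skip auxotrophy).
#' @param aa_pathway_path TSV mapping `pathway` -> `amino_acid` (`NULL` to
#'   skip auxotrophy).
#' @param out_dir output directory.
#' @param seed master seed; per-stage and per-run seeds are derived from it
#'   and logged in the manifest.
#' @param min_genera_per_sample,min_samples_per_genus filtering minima.
#' @param min_cooccurrence merge eligibility threshold (strictly more
#'   samples than this).
#' @param target_fpr calibration false-positive rate.
#' @param n_null null ensemble size per environment.
#' @param n_runs clustering runs per environment.
#' @param min_support consensus support minimum for nodes and edges.
#' @param consensus_support edge support the consensus subnetwork must
#'   exceed.
#' @param phylo_tolerance_redundancy,phylo_tolerance_classification
#'   phylogenetic matching tolerances (substitutions/site).
#' @param size_rel_tolerance genome-size matching tolerance (relative).
#' @param size_threshold large-assemblage member threshold.
#' @param n_random_classification random assemblages per terminal
#'   assemblage.
#' @return A `run_config` list.
#' @export
run_config <- function(occurrence_path, annotation_path,
                       pathway_path = NULL, distance_path = NULL,
                       species_to_genus_path = NULL, cost_path = NULL,
                       aa_pathway_path = NULL, out_dir = "assemblnet_run",
                       seed = 1L, min_genera_per_sample = 5,
                       min_samples_per_genus = 5, min_cooccurrence = 5,
                       target_fpr = 1e-4, n_null = 1000, n_runs = 100,
                       min_support = 10, consensus_support = 70,
                       phylo_tolerance_redundancy = 0.05,
                       phylo_tolerance_classification = 0.1,
                       size_rel_tolerance = 0.2, size_threshold = 5,
                       n_random_classification = 1000) {
  cfg <- as.list(environment())
  stopifnot(min_genera_per_sample >= 1, min_samples_per_genus >= 1,
            min_cooccurrence >= 0, target_fpr > 0, n_null >= 1, n_runs >= 1,
            min_support >= 1, consensus_support >= 0,
            phylo_tolerance_redundancy > 0,
            phylo_tolerance_classification > 0, size_rel_tolerance > 0,
            size_threshold >= 1)
  structure(cfg, class = "run_config")
}

#' Run the full pipeline
#'
#' Stages: read + filter occurrence data; fit subtype-wise null
#' probabilities per environment; build a fixed-margin null ensemble and
#' calibrate the Z cutoff per environment; run the clustering ensemble per
#' environment; combine runs into a supported network; summarize
#' assemblages; redundancy comparisons; pathway classification on consensus
#' terminals; auxotrophy regression. Stages whose inputs were not supplied
#' are skipped. All artifacts are TSV/GraphML files under `out_dir`; a
#' manifest records derived seeds and the effective configuration.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the main in-memory results (`network`,
#'   `summaries`, `redundancy`, `classifications`, `auxotrophy`,
#'   `regression`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  say("stage read: %s", config$occurrence_path)
  inp <- read_occurrence_table(config$occurrence_path,
                               config$annotation_path)
  say("stage filter (>=%d genera/sample, >=%d samples/genus)",
      config$min_genera_per_sample, config$min_samples_per_genus)
  tab <- filter_occurrence_table(inp$table, config$min_genera_per_sample,
                                 config$min_samples_per_genus)
  ann <- inp$annotation[inp$annotation$sample_id %in% colnames(tab), ]
  envs <- unique(ann$env_type)
  runs <- list()
  seeds <- list()
  for (ei in seq_along(envs)) {
    env <- envs[ei]
    samp <- ann$sample_id[ann$env_type == env]
    sub <- unclass(tab)[, colnames(tab) %in% samp, drop = FALSE]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    if (nrow(sub) < 2 || ncol(sub) < 2) next
    etab <- occurrence_table(sub)
    say("stage fit-null (%s): %d genera x %d samples", env, nrow(etab),
        ncol(etab))
    pi_env <- fit_null_by_subtype(etab, ann)
    s_ens <- child_seed(config$seed, 1000 + ei)
    say("stage calibrate (%s): %d null matrices, seed %d", env,
        config$n_null, s_ens)
    ens <- sample_null_matrices(etab, n = config$n_null, seed = s_ens)
    cal <- calibrate_scores(etab, pi_env, ens,
                            target_fpr = config$target_fpr)
    s_run <- child_seed(config$seed, 2000 + ei)
    say("stage cluster (%s): %d runs, base seed %d, z cutoff %.3f", env,
        config$n_runs, s_run, cal$z_cutoff)
    runs_env <- run_ensemble(etab, pi_env, cal, n_runs = config$n_runs,
                             base_seed = s_run,
                             min_cooccurrence = config$min_cooccurrence,
                             environment = env)
    runs <- c(runs, runs_env)
    seeds[[env]] <- c(ensemble = s_ens, runs = s_run)
  }
  say("stage combine: %d runs, min support %d", length(runs),
      config$min_support)
  net <- combine_runs(runs, min_support = config$min_support)
  export_network(net,
                 graphml_path = file.path(config$out_dir, "network.graphml"),
                 nodes_path = file.path(config$out_dir, "nodes.tsv"),
                 edges_path = file.path(config$out_dir, "edges.tsv"))
  res <- list(network = net)
  profiles <- distances <- NULL
  if (!is.null(config$pathway_path)) {
    genomes <- read_genome_pathways(config$pathway_path)
    profiles <- core_pathways(genomes)
  }
  if (!is.null(config$distance_path)) {
    D <- read_distance_matrix(config$distance_path)
    if (!is.null(config$species_to_genus_path)) {
      s2g <- read.delim(config$species_to_genus_path,
                        stringsAsFactors = FALSE)
      distances <- genus_distances(D, setNames(s2g$genus, s2g$species))
    } else distances <- D
  }
  pool <- genus_pool(tab, ann)
  if (!is.null(profiles) && !is.null(distances)) {
    say("stage metrics")
    summaries <- summarize_network(net, profiles, distances)
    res$summaries <- summaries
    if (!is.null(summaries)) {
      write.table(summaries, file.path(config$out_dir, "assemblages.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      say("stage redundancy")
      real <- attach_subtypes(summaries, net, tab, ann)
      red <- redundancy_report(
        real, pool, profiles, distances,
        constraints = list(
          random_assemblage_constraint("fully_random"),
          random_assemblage_constraint("same_environment"),
          random_assemblage_constraint(
            "env_and_phylo",
            phylo_tolerance = config$phylo_tolerance_redundancy),
          random_assemblage_constraint(
            "env_and_genome_size",
            size_rel_tolerance = config$size_rel_tolerance)),
        seed = child_seed(config$seed, 3000))
      res$redundancy <- red
      if (!is.null(red))
        write.table(red, file.path(config$out_dir, "redundancy.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      say("stage classify: consensus edge support > %d",
          config$consensus_support)
      term_keys <- consensus_terminals(net, config$consensus_support)
      if (length(term_keys)) {
        subtypes <- vapply(term_keys, function(k)
          dominant_subtype(net$taxa[[k]], tab, ann), "")
        cls <- classify_network(
          net$taxa[term_keys], profiles, distances, pool, subtypes,
          n_random = config$n_random_classification,
          phylo_tolerance = config$phylo_tolerance_classification,
          seed = child_seed(config$seed, 4000))
        res$classifications <- cls
        if (!is.null(cls)) {
          write.table(cls, file.path(config$out_dir, "classification.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          res$size_classes <- size_class_comparison(cls,
                                                    config$size_threshold)
          if (!is.null(config$cost_path) &&
              !is.null(config$aa_pathway_path)) {
            say("stage auxotrophy")
            costs <- read_aa_costs(config$cost_path)
            aa_map <- read.delim(config$aa_pathway_path,
                                 stringsAsFactors = FALSE)
            recs <- try(auxotrophy_records(cls, aa_map, costs,
                                           config$size_threshold),
                        silent = TRUE)
            if (!inherits(recs, "try-error")) {
              res$auxotrophy <- recs
              write.table(recs, file.path(config$out_dir, "auxotrophy.tsv"),
                          sep = "\t", quote = FALSE, row.names = FALSE)
              if (nrow(recs) >= 3)
                res$regression <- cost_regression(recs)
            }
          }
        }
      }
    }
  }
  manifest <- c(list(seed = config$seed,
                     derived_seeds = seeds,
                     package_version =
                       as.character(utils::packageVersion("assemblnet"))),
                config[setdiff(names(config), "seed")])
  writeLines(paste(names(unlist(manifest)), unlist(manifest), sep = "\t"),
             file.path(config$out_dir, "manifest.tsv"))
  say("done")
  invisible(res)
}

# genera observed at least once in each env_subtype
genus_pool <- function(table, annotation) {
  X <- unclass(table)
  sub <- annotation$env_subtype[match(colnames(X), annotation$sample_id)]
  out <- list()
  for (s in unique(sub[!is.na(sub)])) {
    g <- rownames(X)[rowSums(X[, which(sub == s), drop = FALSE]) > 0]
    if (length(g))
      out[[length(out) + 1L]] <- data.frame(genus = g, env_subtype = s,
                                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# subtype contributing most joint-presence samples of an assemblage
dominant_subtype <- function(taxa, tab, annotation) {
  X <- unclass(tab)
  joint <- colSums(X[taxa, , drop = FALSE]) == length(taxa)
  sub <- annotation$env_subtype[match(colnames(X), annotation$sample_id)]
  tt <- table(sub[joint & !is.na(sub)])
  if (!length(tt)) {
    tt <- table(sub[colSums(X[taxa, , drop = FALSE]) > 0 & !is.na(sub)])
  }
  names(tt)[which.max(tt)]
}

# attach an env_subtype column to network summaries for random matching
attach_subtypes <- function(summaries, net, table, annotation) {
  summaries$env_subtype <- vapply(summaries$key, function(k)
    dominant_subtype(net$taxa[[k]], table, annotation), "")
  summaries
}

#' Write a synthetic data set preset to disk
#'
#' Presets: `null` (no planted structure), `planted` (three strong planted
#' assemblages), `conditional` (one taxon with different partners in two
#' subtypes), `pathways` (planted structure plus pathway tables, distances
#' and costs). Files use the same TSV dialects the readers consume; ground
#' truth tables are written alongside.
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param n_genera,n_samples scale of the occurrence table.
#' @return Invisibly, the list of written paths.
#' @export
simulate_preset <- function(preset = c("null", "planted", "conditional",
                                       "pathways"),
                            seed = 1L, out_dir = "assemblnet_sim",
                            n_genera = 120, n_samples = 400) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layout <- list(env1 = c(sub1 = ceiling(n_samples / 2)),
                 env2 = c(sub2 = floor(n_samples / 2)))
  base <- generate_null_occurrences(n_genera, env_layout = layout,
                                    seed = seed)
  gt <- NULL
  if (preset %in% c("planted", "pathways")) {
    top <- names(sort(rowSums(unclass(base$table)), decreasing = TRUE))
    plants <- list(plant_spec(top[1:2], "sub1", boost = 50),
                   plant_spec(top[3:4], "sub2", boost = 50))
    pl <- plant_assemblages(base, plants, seed = child_seed(seed, 1))
    base$table <- pl$table; gt <- pl$ground_truth
  } else if (preset == "conditional") {
    top <- names(sort(rowSums(unclass(base$table)), decreasing = TRUE))
    plants <- conditional_plants(top[1],
                                 list(sub1 = top[2], sub2 = top[3]),
                                 boost = 50)
    pl <- plant_assemblages(base, plants, seed = child_seed(seed, 1))
    base$table <- pl$table; gt <- pl$ground_truth
  }
  paths <- list(
    occurrence = file.path(out_dir, "occurrence.tsv"),
    annotation = file.path(out_dir, "annotation.tsv"))
  write_occurrence_table(base$table, paths$occurrence, base$annotation,
                         paths$annotation)
  if (!is.null(gt)) {
    paths$ground_truth <- file.path(out_dir, "planted_ground_truth.tsv")
    write.table(gt, paths$ground_truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (preset == "pathways") {
    genera <- rownames(base$table)
    pu <- generate_pathway_universe(genera, seed = child_seed(seed, 2))
    paths$pathways <- file.path(out_dir, "genome_pathways.tsv")
    write.table(pu$genomes, paths$pathways, sep = "\t", quote = FALSE,
                row.names = FALSE)
    ph <- generate_phylo_distances(genera, seed = child_seed(seed, 3))
    paths$distances <- file.path(out_dir, "species_distances.tsv")
    write.table(data.frame(species = rownames(ph$D), ph$D,
                           check.names = FALSE),
                paths$distances, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths$species_to_genus <- file.path(out_dir, "species_to_genus.tsv")
    write.table(data.frame(species = names(ph$species_to_genus),
                           genus = unname(ph$species_to_genus)),
                paths$species_to_genus, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}
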