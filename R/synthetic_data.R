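#' Generate a null occurrence table with heterogeneous margins
#'
#' Cells are filled independently under a margin-product model: each genus
#' draws an occupancy p_i from a (heavy-tailed) Beta distribution, each
#' sample draws a richness multiplier q_a, and X_ia ~ Bernoulli(min(p_i *
#' q_a, 1)). Samples are laid out over an environment hierarchy (type ->
#' subtype -> sample count) and annotated accordingly. No taxon-taxon
#' dependence is introduced, so the result is a genuine null for
#' co-occurrence inference.
#'
#' @param n_genera number of genera.
#' @param n_samples number of samples; ignored when `env_layout` is given.
#' @param occupancy_shape1,occupancy_shape2 Beta shapes for genus occupancy
#'   (defaults give mean occupancy ~0.14 with a heavy right tail).
#' @param richness_shape1,richness_shape2 Beta shapes for the per-sample
#'   richness multiplier (scaled to mean 1); the default is broad, matching
#'   the wide per-sample richness variation of environmental surveys.
#' @param env_layout named list env_type -> named integer vector
#'   subtype -> sample count; default a single environment with one subtype.
#' @param occupancy optional explicit occupancy vector (overrides the Beta
#'   draw).
#' @param richness optional explicit richness multiplier vector.
#' @param seed integer seed.
#' @return List with `table` (an [occurrence_table()]), `annotation` (data
#'   frame), `occupancy`, `richness`.
#' @export
generate_null_occurrences <- function(n_genera, n_samples = NULL,
                                      occupancy_shape1 = 0.8,
                                      occupancy_shape2 = 5,
                                      richness_shape1 = 2,
                                      richness_shape2 = 2,
                                      env_layout = NULL,
                                      occupancy = NULL, richness = NULL,
                                      seed = 1L) {
  stopifnot(n_genera >= 1)
  if (is.null(env_layout)) {
    stopifnot(!is.null(n_samples), n_samples >= 1)
    env_layout <- list(env1 = c(sub1 = n_samples))
  }
  if (any(c(occupancy_shape1, occupancy_shape2, richness_shape1,
            richness_shape2) <= 0))
    stop("Beta shapes must be positive")
  ann <- do.call(rbind, lapply(names(env_layout), function(et) {
    subs <- env_layout[[et]]
    do.call(rbind, lapply(names(subs), function(st)
      data.frame(env_type = et, env_subtype = st,
                 n = subs[[st]], stringsAsFactors = FALSE)))
  }))
  total <- sum(ann$n)
  annotation <- data.frame(
    sample_id = sprintf("s%05d", seq_len(total)),
    env_type = rep(ann$env_type, ann$n),
    env_subtype = rep(ann$env_subtype, ann$n),
    stringsAsFactors = FALSE)
  set.seed(seed)
  if (is.null(occupancy))
    occupancy <- rbeta(n_genera, occupancy_shape1, occupancy_shape2)
  if (is.null(richness))
    richness <- 2 * rbeta(total, richness_shape1, richness_shape2)
  stopifnot(length(occupancy) == n_genera, length(richness) == total)
  P <- pmin(outer(occupancy, richness), 1)
  X <- matrix(rbinom(length(P), 1L, P), nrow = n_genera,
              dimnames = list(sprintf("g%04d", seq_len(n_genera)),
                              annotation$sample_id))
  list(table = occurrence_table(X), annotation = annotation,
       occupancy = occupancy, richness = richness)
}

#' Specify a planted co-occurring assemblage
#'
#' @param taxa genus labels to associate.
#' @param env_subtype subtype whose samples carry the association.
#' @param boost joint co-occurrence odds multiplier (>= 1).
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(taxa, env_subtype, boost = 10,
                       localized_taxa = character(0)) {
  stopifnot(boost >= 1, length(taxa) >= 2)
  structure(list(taxa = taxa, env_subtype = env_subtype, boost = boost,
                 localized_taxa = localized_taxa),
            class = "plant_spec")
}

#' Expand a conditional partner map into plant specifications
#'
#' Describes one taxon associating with different partners in different
#' subtypes (e.g. A with B in subtype 1, A with C in subtype 2), the
#' structure the residual-node mechanism of the clustering is designed to
#' capture. Each partner is localized to its subtype (its presence outside
#' it is suppressed), since a conditional association is only recoverable
#' as two distinct nodes when the partners are habitat-restricted.
#'
#' @param genus the shared taxon.
#' @param partner_map named list env_subtype -> partner genus vector.
#' @param boost odds multiplier applied to every conditional association.
#' @return List of [plant_spec()].
#' @export
conditional_plants <- function(genus, partner_map, boost = 10) {
  lapply(names(partner_map), function(st)
    plant_spec(c(genus, partner_map[[st]]), st, boost,
               localized_taxa = partner_map[[st]]))
}

#' Plant co-occurring assemblages into a null occurrence table
#'
#' Within each plant's subtype samples, member presences are re-drawn from a
#' shared-indicator mixture: with probability w the whole assemblage is
#' present, otherwise members occur independently with probabilities reduced
#' so that each member's marginal occupancy is preserved in expectation. w
#' is chosen so that the pairwise joint presence probability is
#' approximately `boost` times the independent baseline; when the requested
#' boost is unattainable (joint probability capped by the smallest
#' marginal), the achievable maximum is used and a warning reports the
#' achieved boost.
#'
#' @param base output of [generate_null_occurrences()] (or a list with
#'   `table` and `annotation`).
#' @param plants list of [plant_spec()] (a single spec is accepted).
#' @param seed integer seed.
#' @return List with the modified `table`, the `annotation`, and
#'   `ground_truth` (data frame: plant taxa, subtype, requested and achieved
#'   boost).
#' @export
plant_assemblages <- function(base, plants, seed = 1L) {
  if (inherits(plants, "plant_spec")) plants <- list(plants)
  X <- unclass(base$table)
  ann <- base$annotation
  set.seed(seed)
  gt <- list()
  for (pl in plants) {
    if (!all(pl$taxa %in% rownames(X)))
      stop("plant taxa not in table: ",
           paste(setdiff(pl$taxa, rownames(X)), collapse = ", "))
    cols <- which(colnames(X) %in%
                    ann$sample_id[ann$env_subtype == pl$env_subtype])
    if (!length(cols)) stop("no samples for subtype ", pl$env_subtype)
    for (t in pl$localized_taxa) {
      outside <- setdiff(seq_len(ncol(X)), cols)
      X[t, outside] <- rbinom(length(outside), 1L, 0.02)
    }
    p <- pmax(rowMeans(X[pl$taxa, cols, drop = FALSE]), 0.02)
    pbar <- mean(p)
    target <- min(pl$boost * pbar^2, 0.999 * min(p))
    f <- function(w) w + (1 - w) * ((pbar - w) / (1 - w))^2
    w <- if (f(0) >= target) 0 else
      stats::uniroot(function(w) f(w) - target, c(0, min(p) * 0.999))$root
    achieved <- f(w) / pbar^2
    if (achieved < pl$boost * 0.99)
      warning(sprintf("plant (%s): requested boost %.1f, achieved %.2f",
                      paste(pl$taxa, collapse = ","), pl$boost, achieved))
    p_resid <- pmax((p - w) / (1 - w), 0)
    z <- rbinom(length(cols), 1L, w)
    for (t in seq_along(pl$taxa)) {
      ind <- rbinom(length(cols), 1L, p_resid[t])
      X[pl$taxa[t], cols] <- ifelse(z == 1L, 1L, ind)
    }
    gt[[length(gt) + 1L]] <- data.frame(
      taxa = paste(pl$taxa, collapse = ","), env_subtype = pl$env_subtype,
      boost_requested = pl$boost, boost_achieved = achieved,
      stringsAsFactors = FALSE)
  }
  list(table = occurrence_table(X), annotation = ann,
       ground_truth = do.call(rbind, gt))
}

#' Generate genome-by-pathway tables with planted selection structure
#'
#' Per genus, 1-5 genomes share a core of background pathways plus
#' genome-specific noise pathways (each noise pathway is absent from at
#' least one genome, so the core is exactly the planted one). Planted roles
#' modify the cores of the named assemblage members: `redundant` pathways
#' are carried by every member but are rare in the background; `specific`
#' pathways by exactly one member while common in the background; `missing`
#' pathways by no member while common in the background.
#'
#' @param genera genus labels.
#' @param n_pathways number of background pathways.
#' @param core_size_range range (2-vector) of core sizes per genus.
#' @param planted list of lists with elements `taxa` (assemblage members),
#'   `pathway` (label; created if absent) and `role` in
#'   `c("redundant", "specific", "missing")`.
#' @param n_genomes_range range of genomes per genus.
#' @param background_common,background_rare background prevalence of planted
#'   common/rare pathways among non-member genera.
#' @param noise_rate expected genome-specific noise pathways per genome.
#' @param seed integer seed.
#' @return List with `genomes` (incidence data frame `genome_id`, `genus`,
#'   `pathway`), `core` (named list genus -> core pathways), `ground_truth`
#'   (data frame of planted roles).
#' @export
generate_pathway_universe <- function(genera, n_pathways = 100,
                                      core_size_range = c(20, 40),
                                      planted = list(),
                                      n_genomes_range = c(1, 5),
                                      background_common = 0.85,
                                      background_rare = 0.05,
                                      noise_rate = 3, seed = 1L) {
  set.seed(seed)
  pws <- sprintf("pw%04d", seq_len(n_pathways))
  freq <- rbeta(n_pathways, 1.2, 1.8)
  names(freq) <- pws
  core <- lapply(genera, function(g) {
    sz <- sample(seq(core_size_range[1], core_size_range[2]), 1)
    sample(pws, min(sz, n_pathways), prob = freq)
  })
  names(core) <- genera
  # consistency check and planted role realization
  seen <- list()
  for (pl in planted) {
    key <- paste(sort(pl$taxa), collapse = "|")
    prev <- seen[[key]][[pl$pathway]]
    if (!is.null(prev) && prev != pl$role)
      stop("inconsistent planted roles for pathway ", pl$pathway,
           " in assemblage ", key)
    seen[[key]][[pl$pathway]] <- pl$role
    stopifnot(all(pl$taxa %in% genera),
              pl$role %in% c("redundant", "specific", "missing"))
    others <- setdiff(genera, pl$taxa)
    if (pl$role == "redundant") {
      for (g in pl$taxa) core[[g]] <- union(core[[g]], pl$pathway)
      for (g in others)
        if (runif(1) > background_rare)
          core[[g]] <- setdiff(core[[g]], pl$pathway)
        else core[[g]] <- union(core[[g]], pl$pathway)
    } else {
      carrier <- if (pl$role == "specific") sample(pl$taxa, 1) else character(0)
      for (g in pl$taxa)
        core[[g]] <- if (g %in% carrier) union(core[[g]], pl$pathway)
          else setdiff(core[[g]], pl$pathway)
      for (g in others)
        if (runif(1) < background_common)
          core[[g]] <- union(core[[g]], pl$pathway)
        else core[[g]] <- setdiff(core[[g]], pl$pathway)
    }
  }
  planted_pws <- unique(vapply(planted, `[[`, "", "pathway"))
  noise_pool <- setdiff(pws, planted_pws)
  rows <- list()
  for (g in genera) {
    ng <- sample(seq(n_genomes_range[1], n_genomes_range[2]), 1)
    sets <- rep(list(core[[g]]), ng)
    if (ng >= 2) {
      # accessory pathways land in a random proper subset of genomes, so
      # the intersection always recovers exactly the planted core
      avail <- setdiff(noise_pool, core[[g]])
      n_acc <- min(stats::rpois(1, noise_rate * ng), length(avail))
      acc <- sample(avail, n_acc)
      for (pw in acc) {
        carriers <- sample(ng, sample(ng - 1L, 1))
        for (k in carriers) sets[[k]] <- c(sets[[k]], pw)
      }
    }
    for (k in seq_len(ng)) {
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = sprintf("%s_gen%02d", g, k), genus = g,
        pathway = sets[[k]], stringsAsFactors = FALSE)
    }
  }
  gt <- if (length(planted))
    do.call(rbind, lapply(planted, function(pl)
      data.frame(assemblage = paste(sort(pl$taxa), collapse = "|"),
                 pathway = pl$pathway, role = pl$role,
                 stringsAsFactors = FALSE)))
  else NULL
  list(genomes = do.call(rbind, rows), core = lapply(core, sort),
       ground_truth = gt)
}

# random coalescent-style ultrametric over labels; returns distance matrix
coalescent_distances <- function(labels, scale) {
  n <- length(labels)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n == 1) return(D)
  clusters <- as.list(seq_len(n))
  h <- 0
  while (length(clusters) > 1) {
    k <- length(clusters)
    h <- h + stats::rexp(1, rate = choose(k, 2)) * scale * k
    pick <- sample(k, 2)
    a <- clusters[[pick[1]]]; b <- clusters[[pick[2]]]
    D[a, b] <- 2 * h
    D[b, a] <- 2 * h
    clusters[[pick[1]]] <- c(a, b)
    clusters[[pick[2]]] <- NULL
  }
  D
}

#' Generate species-level phylogenetic distances with genus structure
#'
#' Between-genus distances come from a random coalescent-style ultrametric
#' hierarchy over genera; within each genus, member species coalesce on a
#' much shorter timescale, so within-genus distances are smaller than
#' between-genus distances on average. Distances are in substitutions/site
#' units.
#'
#' @param genera genus labels.
#' @param n_species_range range of species per genus.
#' @param between_scale,within_scale coalescent time scales.
#' @param seed integer seed.
#' @return List with `D` (species distance matrix), `species_to_genus`
#'   (named character vector).
#' @export
generate_phylo_distances <- function(genera, n_species_range = c(1, 4),
                                     between_scale = 0.05,
                                     within_scale = 0.004, seed = 1L) {
  set.seed(seed)
  G <- coalescent_distances(genera, between_scale)
  sp <- list(); s2g <- character(0)
  for (g in genera) {
    ns <- sample(seq(n_species_range[1], n_species_range[2]), 1)
    ids <- sprintf("%s_sp%02d", g, seq_len(ns))
    sp[[g]] <- ids
    s2g[ids] <- g
  }
  all_sp <- unlist(sp, use.names = FALSE)
  D <- matrix(0, length(all_sp), length(all_sp),
              dimnames = list(all_sp, all_sp))
  for (g in genera) {
    W <- coalescent_distances(sp[[g]], within_scale)
    D[sp[[g]], sp[[g]]] <- W
  }
  for (i in seq_along(genera)) {
    for (j in seq_len(i - 1L)) {
      gi <- genera[i]; gj <- genera[j]
      D[sp[[gi]], sp[[gj]]] <- G[gi, gj]
      D[sp[[gj]], sp[[gi]]] <- G[gi, gj]
    }
  }
  list(D = D, species_to_genus = s2g)
}
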