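#' Constraints for random assemblage generation
#'
#' Four classes of constrained random assemblages serve as baselines for the
#' redundancy comparisons: `fully_random` (any genera from the network
#' pool), `same_environment` (genera observed in the reference assemblage's
#' environmental subtype), `env_and_phylo` (additionally matching the
#' reference's mean pairwise phylogenetic distance within
#' `phylo_tolerance`), and `env_and_genome_size` (additionally matching the
#' reference's mean pathways per genus within `size_rel_tolerance`,
#' relative).
#'
#' @param kind one of `fully_random`, `same_environment`, `env_and_phylo`,
#'   `env_and_genome_size`.
#' @param n_replicates random assemblages per real assemblage (default 1000
#'   for `fully_random`, 100 otherwise).
#' @param phylo_tolerance absolute tolerance, substitutions/site.
#' @param size_rel_tolerance relative tolerance on mean pathways per genus.
#' @param max_attempts rejection-sampling attempts per replicate before the
#'   replicate is declared infeasible.
#' @return A `random_assemblage_constraint` list.
#' @export
random_assemblage_constraint <- function(kind = c("fully_random",
                                                  "same_environment",
                                                  "env_and_phylo",
                                                  "env_and_genome_size"),
                                         n_replicates = NULL,
                                         phylo_tolerance = 0.05,
                                         size_rel_tolerance = 0.20,
                                         max_attempts = 10000L) {
  kind <- match.arg(kind)
  if (is.null(n_replicates))
    n_replicates <- if (kind == "fully_random") 1000L else 100L
  stopifnot(phylo_tolerance > 0, size_rel_tolerance > 0, max_attempts >= 1)
  structure(list(kind = kind, n_replicates = n_replicates,
                 phylo_tolerance = phylo_tolerance,
                 size_rel_tolerance = size_rel_tolerance,
                 max_attempts = max_attempts),
            class = "random_assemblage_constraint")
}

#' Draw one constrained random assemblage
#'
#' Rejection sampling without replacement from the genus pool. Environmental
#' kinds restrict the pool to genera observed in the reference assemblage's
#' `env_subtype`; the phylogenetic kind additionally requires the mean
#' pairwise distance of the draw to be within `phylo_tolerance` of the
#' reference; the genome-size kind requires the mean pathways per genus to
#' be within `size_rel_tolerance` (relative) of the reference.
#'
#' @param size number of genera to draw.
#' @param constraint a [random_assemblage_constraint()].
#' @param reference list describing the real assemblage: needs
#'   `env_subtype` (for environmental kinds), `mean_phylo_distance`,
#'   `mean_pathways_per_genus` as applicable.
#' @param pool data frame with columns `genus` and `env_subtype` (a genus
#'   may appear under several subtypes).
#' @param profiles named list genus -> core pathways (genome-size kind).
#' @param distances genus distance matrix (phylogenetic kind).
#' @return Character vector of genera, or `NULL` if no draw satisfied the
#'   constraint within `max_attempts` (an "infeasible constraint" warning is
#'   raised).
#' @export
sample_random_assemblage <- function(size, constraint, reference, pool,
                                     profiles = NULL, distances = NULL) {
  cand <- unique(pool$genus)
  if (constraint$kind != "fully_random") {
    cand <- unique(pool$genus[pool$env_subtype == reference$env_subtype])
  }
  if (constraint$kind == "env_and_phylo")
    cand <- intersect(cand, rownames(distances))
  if (constraint$kind == "env_and_genome_size")
    cand <- intersect(cand, names(profiles))
  if (length(cand) < size)
    stop("pool too small for assemblage size ", size)
  if (length(cand) == size) return(cand)
  for (att in seq_len(constraint$max_attempts)) {
    draw <- sample(cand, size)
    ok <- switch(constraint$kind,
      fully_random = , same_environment = TRUE,
      env_and_phylo = {
        prs <- combn(draw, 2)
        d <- mean(distances[cbind(prs[1, ], prs[2, ])])
        abs(d - reference$mean_phylo_distance) <= constraint$phylo_tolerance
      },
      env_and_genome_size = {
        mp <- mean(lengths(profiles[draw]))
        abs(mp - reference$mean_pathways_per_genus) /
          reference$mean_pathways_per_genus <= constraint$size_rel_tolerance
      })
    if (ok) return(draw)
  }
  warning(sprintf("infeasible constraint (%s) after %d attempts",
                  constraint$kind, constraint$max_attempts))
  NULL
}

# summarize many random assemblages matched to the real ones
random_group_summaries <- function(real, constraint, pool, profiles,
                                   distances) {
  out <- vector("list", 0)
  for (r in seq_len(nrow(real))) {
    ref <- list(env_subtype = real$env_subtype[r],
                mean_phylo_distance = real$mean_phylo_distance[r],
                mean_pathways_per_genus = real$mean_pathways_per_genus[r])
    for (k in seq_len(constraint$n_replicates)) {
      draw <- sample_random_assemblage(real$size[r], constraint, ref, pool,
                                       profiles, distances)
      if (is.null(draw)) next
      s <- suppressWarnings(summarize_assemblage(draw, profiles, distances))
      if (is.null(s)) next
      out[[length(out) + 1L]] <- data.frame(
        size = s$size,
        mean_functional_distance = s$mean_functional_distance,
        mean_phylo_distance = s$mean_phylo_distance,
        mean_pathways_per_genus = s$mean_pathways_per_genus)
    }
  }
  do.call(rbind, out)
}

#' Size-stratified comparison of real versus random assemblages
#'
#' For each assemblage size and each metric (mean pairwise functional
#' distance, mean pairwise phylogenetic distance, mean pathways per genus),
#' compares the distributions across groups — real single-environment, real
#' multi-environment, and one group per random constraint kind — with
#' two-sided Mann-Whitney U tests, Benjamini-Hochberg corrected within each
#' (metric, size) family.
#'
#' @param real data frame of real assemblage summaries; needs columns
#'   `size`, `multi_env`, `env_subtype`, `mean_functional_distance`,
#'   `mean_phylo_distance`, `mean_pathways_per_genus`.
#' @param pool genus pool data frame (`genus`, `env_subtype`).
#' @param profiles named list genus -> core pathways.
#' @param distances genus distance matrix.
#' @param constraints list of [random_assemblage_constraint()].
#' @param alpha significance level applied to adjusted p-values.
#' @param sizes assemblage sizes to analyse.
#' @param seed integer seed.
#' @return Data frame with columns `size`, `metric`, `group_a`, `group_b`,
#'   `n_a`, `n_b`, `U`, `p_raw`, `p_adj`, `significant` (`NA` p-values mark
#'   non-testable comparisons with fewer than 2 observations in a group).
#' @export
redundancy_report <- function(real, pool, profiles, distances,
                              constraints = list(
                                random_assemblage_constraint("fully_random"),
                                random_assemblage_constraint("same_environment"),
                                random_assemblage_constraint("env_and_phylo"),
                                random_assemblage_constraint("env_and_genome_size")),
                              alpha = 0.05, sizes = 2:12, seed = 1L) {
  set.seed(seed)
  metrics <- c("mean_functional_distance", "mean_phylo_distance",
               "mean_pathways_per_genus")
  rows <- list()
  for (sz in sizes) {
    rs <- real[real$size == sz, , drop = FALSE]
    if (nrow(rs) == 0) next
    groups <- list(real_single = rs[!rs$multi_env, , drop = FALSE],
                   real_multi = rs[rs$multi_env, , drop = FALSE])
    for (con in constraints)
      groups[[con$kind]] <- random_group_summaries(rs, con, pool, profiles,
                                                   distances)
    groups <- Filter(function(g) !is.null(g) && nrow(g) > 0, groups)
    gn <- names(groups)
    if (length(gn) < 2) next
    cmb <- combn(gn, 2)
    for (met in metrics) {
      fam <- lapply(seq_len(ncol(cmb)), function(ci) {
        a <- groups[[cmb[1, ci]]][[met]]; b <- groups[[cmb[2, ci]]][[met]]
        testable <- length(a) >= 2 && length(b) >= 2
        if (testable) {
          wt <- suppressWarnings(
            wilcox.test(a, b, exact = length(a) < 20 && length(b) < 20))
          U <- unname(wt$statistic); p <- wt$p.value
        } else {
          U <- NA_real_; p <- NA_real_
        }
        data.frame(size = sz, metric = met, group_a = cmb[1, ci],
                   group_b = cmb[2, ci], n_a = length(a), n_b = length(b),
                   U = U, p_raw = p, stringsAsFactors = FALSE)
      })
      fam <- do.call(rbind, fam)
      fam$p_adj <- p.adjust(fam$p_raw, method = "BH")
      fam$significant <- !is.na(fam$p_adj) & fam$p_adj < alpha
      rows[[length(rows) + 1L]] <- fam
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
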