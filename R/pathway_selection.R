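#' Classify a pathway in one assemblage as Redundant, Specific or Missing
#'
#' Against the distribution of the pathway's prevalence in matched random
#' assemblages: Redundant if it appears in at least two members and its real
#' prevalence strictly exceeds the random prevalence in at least 95% of
#' replicates; Specific if it appears in the assemblage but its prevalence
#' is strictly below the random prevalence in at least 95% of replicates;
#' Missing if it is absent from the assemblage while the random prevalence
#' is at least 1 in at least 95% of replicates; otherwise Unclassified.
#' Ties count against classification.
#'
#' @param P prevalence in the real assemblage (members carrying the
#'   pathway).
#' @param S assemblage size.
#' @param random_prevalences integer vector of prevalences in the random
#'   replicates.
#' @param level fraction of replicates the inequality must hold for.
#' @return One of `"Redundant"`, `"Specific"`, `"Missing"`,
#'   `"Unclassified"`.
#' @export
classify_pathway <- function(P, S, random_prevalences, level = 0.95) {
  if (!length(random_prevalences)) stop("empty random prevalence distribution")
  stopifnot(P >= 0, P <= S)
  if (P >= 2 && mean(P > random_prevalences) >= level) return("Redundant")
  if (P >= 1 && mean(P < random_prevalences) >= level) return("Specific")
  if (P == 0 && mean(random_prevalences >= 1) >= level) return("Missing")
  "Unclassified"
}

#' Classify every pathway in every terminal assemblage
#'
#' For each terminal assemblage, generates `n_random` environmentally and
#' phylogenetically equivalent random assemblages of the same size and
#' classifies each pathway of the pathway universe by
#' [classify_pathway()]. Assemblages for which random generation is
#' infeasible are skipped with a warning.
#'
#' @param terminals named list key -> character vector of member genera
#'   (e.g. `net$taxa[consensus_terminals(net)]`).
#' @param profiles named list genus -> core pathways.
#' @param distances genus distance matrix.
#' @param pool genus pool data frame (`genus`, `env_subtype`).
#' @param terminal_subtypes named character vector key -> env_subtype of the
#'   assemblage.
#' @param n_random random replicates per assemblage.
#' @param phylo_tolerance tolerance on mean pairwise phylogenetic distance
#'   (substitutions/site) for the random assemblages.
#' @param seed integer seed.
#' @param level classification stringency (fraction of replicates).
#' @return Data frame with columns `assemblage`, `pathway`, `P`, `S`,
#'   `call`, `quantile` (empirical fraction of replicates with prevalence
#'   strictly below P).
#' @export
classify_network <- function(terminals, profiles, distances, pool,
                             terminal_subtypes, n_random = 1000,
                             phylo_tolerance = 0.1, seed = 1L,
                             level = 0.95) {
  set.seed(seed)
  con <- random_assemblage_constraint("env_and_phylo",
                                      n_replicates = n_random,
                                      phylo_tolerance = phylo_tolerance)
  universe <- sort(unique(unlist(profiles[unique(pool$genus)])))
  out <- list()
  for (key in names(terminals)) {
    taxa <- terminals[[key]]
    if (!all(taxa %in% names(profiles)) ||
        !all(taxa %in% rownames(distances))) {
      warning("unannotatable assemblage skipped: ", key)
      next
    }
    S <- length(taxa)
    prs <- combn(taxa, 2)
    ref <- list(env_subtype = unname(terminal_subtypes[key]),
                mean_phylo_distance = mean(distances[cbind(prs[1, ],
                                                           prs[2, ])]))
    draws <- vector("list", n_random)
    ok <- TRUE
    for (k in seq_len(n_random)) {
      d <- sample_random_assemblage(S, con, ref, pool, profiles, distances)
      if (is.null(d)) { ok <- FALSE; break }
      draws[[k]] <- d
    }
    if (!ok) {
      warning("random assemblage generation infeasible for ", key,
              "; assemblage skipped")
      next
    }
    # prevalence of each pathway among each draw's member cores
    prev_real <- pathway_prevalences(taxa, profiles, universe)
    rnd <- vapply(draws, pathway_prevalences, integer(length(universe)),
                  profiles = profiles, universe = universe)
    calls <- character(length(universe))
    qtl <- numeric(length(universe))
    for (pw in seq_along(universe)) {
      calls[pw] <- classify_pathway(prev_real[pw], S, rnd[pw, ], level)
      qtl[pw] <- mean(prev_real[pw] > rnd[pw, ])
    }
    out[[length(out) + 1L]] <- data.frame(
      assemblage = key, pathway = universe, P = prev_real, S = S,
      call = calls, quantile = qtl, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# count of members whose core contains each pathway of the universe
pathway_prevalences <- function(taxa, profiles, universe) {
  tab <- table(factor(unlist(profiles[taxa]), levels = universe))
  as.integer(tab)
}

#' Fraction of auxotrophs for a pathway in an assemblage
#'
#' 1 - P/S: the fraction of members lacking the (biosynthesis) pathway,
#' presumed to rely on external supply of its product.
#'
#' @param P members carrying the pathway.
#' @param S assemblage size (>= 1).
#' @return Value in \[0, 1\].
#' @export
auxotroph_fraction <- function(P, S) {
  stopifnot(S >= 1)
  if (any(P > S) || any(P < 0)) stop("P must lie in [0, S]")
  1 - P / S
}

#' Compare small and large assemblages per pathway class
#'
#' Splits assemblages at `size_threshold` members and compares, per call
#' class (`total` plus Redundant/Specific/Missing), the per-assemblage
#' average pathways per genome (sum of pathway prevalences in the class
#' divided by assemblage size) between the two groups with a two-sided
#' rank-sum test.
#'
#' @param classifications output of [classify_network()].
#' @param size_threshold assemblages with at least this many members are
#'   "large".
#' @return Data frame with columns `class`, `n_small`, `n_large`,
#'   `mean_small`, `mean_large`, `p` (NA marks non-testable classes).
#' @export
size_class_comparison <- function(classifications, size_threshold = 5) {
  cls <- c("total", "Redundant", "Specific", "Missing")
  per_asm <- split(classifications, classifications$assemblage)
  rows <- lapply(cls, function(cl) {
    vals <- vapply(per_asm, function(df) {
      sel <- if (cl == "total") rep(TRUE, nrow(df)) else df$call == cl
      sum(df$P[sel]) / df$S[1]
    }, 1)
    sizes <- vapply(per_asm, function(df) df$S[1], 1)
    small <- vals[sizes < size_threshold]
    large <- vals[sizes >= size_threshold]
    testable <- length(small) >= 2 && length(large) >= 2
    p <- if (testable)
      suppressWarnings(wilcox.test(small, large)$p.value) else NA_real_
    data.frame(class = cl, n_small = length(small), n_large = length(large),
               mean_small = if (length(small)) mean(small) else NA_real_,
               mean_large = if (length(large)) mean(large) else NA_real_,
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean auxotroph fraction per amino acid over large assemblages
#'
#' For each amino-acid biosynthesis pathway, averages 1 - P/S over the
#' terminal assemblages of at least `size_threshold` members and attaches
#' the biosynthetic cost.
#'
#' @param classifications output of [classify_network()].
#' @param aa_pathways data frame mapping `pathway` -> `amino_acid`.
#' @param costs cost table (`amino_acid`, `cost`), e.g. [read_aa_costs()].
#' @param size_threshold minimum assemblage size.
#' @return Data frame with `amino_acid`, `mean_auxotroph_fraction`, `cost`,
#'   `n_assemblages`.
#' @export
auxotrophy_records <- function(classifications, aa_pathways, costs,
                               size_threshold = 5) {
  big <- classifications[classifications$S >= size_threshold &
                           classifications$pathway %in% aa_pathways$pathway, ,
                         drop = FALSE]
  if (!nrow(big)) stop("no large assemblages carry amino-acid pathways")
  big$amino_acid <- aa_pathways$amino_acid[match(big$pathway,
                                                 aa_pathways$pathway)]
  agg <- do.call(rbind, lapply(split(big, big$amino_acid), function(df)
    data.frame(amino_acid = df$amino_acid[1],
               mean_auxotroph_fraction = mean(auxotroph_fraction(df$P, df$S)),
               n_assemblages = nrow(df), stringsAsFactors = FALSE)))
  agg$cost <- costs$cost[match(agg$amino_acid, costs$amino_acid)]
  rownames(agg) <- NULL
  agg[!is.na(agg$cost), , drop = FALSE]
}

#' Regress mean auxotroph fraction on biosynthetic cost
#'
#' Ordinary least squares of the per-amino-acid mean auxotroph fraction on
#' biosynthetic cost, optionally excluding amino acids (tryptophan is the
#' canonical outlier: expensive but tightly regulated and rarely leaked, so
#' auxotrophy for it is rarer than its cost suggests).
#'
#' @param records data frame with `amino_acid`, `mean_auxotroph_fraction`,
#'   `cost` (see [auxotrophy_records()]).
#' @param exclude amino acids to drop before fitting.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value` (two-sided
#'   on the slope), `n`.
#' @export
cost_regression <- function(records, exclude = character(0)) {
  df <- records[!(records$amino_acid %in% exclude), , drop = FALSE]
  if (nrow(df) < 3) stop("need at least 3 amino acids after exclusion")
  fit <- lm(mean_auxotroph_fraction ~ cost, data = df)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       slope_se = unname(sm$coefficients[2, 2]),
       n = nrow(df))
}
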