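#' Jaccard dissimilarity between two core pathway profiles
#'
#' 1 - |intersection| / |union| of the two genera's core pathway sets.
#'
#' @param u,v character vectors of core pathways.
#' @return Dissimilarity in \[0, 1\].
#' @export
functional_distance <- function(u, v) {
  un <- union(u, v)
  if (length(un) == 0) stop("Jaccard undefined: both pathway sets empty")
  1 - length(intersect(u, v)) / length(un)
}

#' Summarize an assemblage's functional and phylogenetic structure
#'
#' Computes, over all unordered pairs of member genera, the mean Jaccard
#' functional distance and the mean phylogenetic distance, plus the mean
#' number of core pathways per genus (a genome-size proxy) and the set union
#' of member pathways.
#'
#' Assemblages with a genus lacking a pathway profile or distance entry are
#' not summarizable: the function returns `NULL` with a warning (callers
#' skip them).
#'
#' @param taxa character vector of member genera (length >= 2).
#' @param profiles named list genus -> character vector of core pathways.
#' @param distances genus x genus distance matrix.
#' @return List with `taxa`, `size`, `mean_functional_distance`,
#'   `mean_phylo_distance`, `mean_pathways_per_genus`, `union_pathways`; or
#'   `NULL` if the assemblage cannot be annotated.
#' @export
summarize_assemblage <- function(taxa, profiles, distances) {
  taxa <- unique(taxa)
  if (length(taxa) < 2) stop("assemblage summaries need >= 2 genera")
  if (!all(taxa %in% names(profiles)) ||
      !all(taxa %in% rownames(distances))) {
    warning("unannotatable assemblage: ", paste(taxa, collapse = ","))
    return(NULL)
  }
  prs <- combn(taxa, 2)
  fd <- apply(prs, 2, function(p)
    functional_distance(profiles[[p[1]]], profiles[[p[2]]]))
  pd <- distances[cbind(prs[1, ], prs[2, ])]
  list(taxa = sort(taxa), size = length(taxa),
       mean_functional_distance = mean(fd),
       mean_phylo_distance = mean(pd),
       mean_pathways_per_genus = mean(lengths(profiles[taxa])),
       union_pathways = sort(unique(unlist(profiles[taxa]))))
}

#' Summarize all multi-genus assemblages of a combined network
#'
#' @param net a `combined_network`.
#' @param profiles named list genus -> core pathways.
#' @param distances genus x genus distance matrix.
#' @return Data frame with one row per annotatable assemblage (columns
#'   `key`, `size`, `support`, `environments`, `multi_env`,
#'   `mean_functional_distance`, `mean_phylo_distance`,
#'   `mean_pathways_per_genus`).
#' @export
summarize_network <- function(net, profiles, distances) {
  keep <- net$nodes$size >= 2
  rows <- lapply(which(keep), function(r) {
    key <- net$nodes$key[r]
    s <- suppressWarnings(
      summarize_assemblage(net$taxa[[key]], profiles, distances))
    if (is.null(s)) return(NULL)
    data.frame(key = key, size = s$size, support = net$nodes$support[r],
               environments = net$nodes$environments[r],
               multi_env = net$nodes$multi_env[r],
               mean_functional_distance = s$mean_functional_distance,
               mean_phylo_distance = s$mean_phylo_distance,
               mean_pathways_per_genus = s$mean_pathways_per_genus,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
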