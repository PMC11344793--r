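node_key <- function(taxa) paste(sort(taxa), collapse = "|")

#' Merge two nodes of the agglomeration
#'
#' The merged node k keeps the samples where both parents are present
#' (X_k = X_i * X_j, pi_k = pi_i * pi_j); the residual nodes keep each
#' parent's remaining samples (X_i' = X_i * (1 - X_j), pi_i' =
#' pi_i * (1 - pi_j), and symmetrically for j). The three children partition
#' each parent's support exactly: X_k + X_i' = X_i.
#'
#' @param i,j nodes: lists with elements `taxa` (character), `presence`
#'   (0/1 vector) and `prob` (numeric vector), aligned to a common sample
#'   order.
#' @return List with nodes `k`, `i_residual`, `j_residual` (residuals carry
#'   `is_residual = TRUE`).
#' @export
merge_pair <- function(i, j) {
  if (sum(i$presence * j$presence) == 0)
    stop("non-co-occurring merge: nodes share no samples")
  k <- list(taxa = sort(union(i$taxa, j$taxa)),
            presence = i$presence * j$presence,
            prob = i$prob * j$prob,
            is_residual = FALSE)
  ir <- list(taxa = i$taxa,
             presence = i$presence * (1L - j$presence),
             prob = i$prob * (1 - j$prob),
             is_residual = TRUE)
  jr <- list(taxa = j$taxa,
             presence = j$presence * (1L - i$presence),
             prob = j$prob * (1 - i$prob),
             is_residual = TRUE)
  list(k = k, i_residual = ir, j_residual = jr)
}

# score rows of node matrices and return eligible pair table with z
eligible_pairs <- function(Xn, Pn, taxa, calibration, min_cooccurrence,
                           pairs = NULL) {
  if (is.null(pairs)) pairs <- pair_score_table(Xn, Pn)
  occ <- rowSums(Xn)
  keep <- pairs$n_co > min_cooccurrence
  if (!any(keep)) return(pairs[0, , drop = FALSE])
  el <- pairs[keep, , drop = FALSE]
  zs <- pair_zscore(el$score, occ[el$i], occ[el$j], calibration)
  el$z <- zs$z
  el <- el[zs$significant, , drop = FALSE]
  if (nrow(el) == 0) return(el)
  # nodes sharing taxa have disjoint supports by construction; guard anyway
  share <- mapply(function(a, b) length(intersect(taxa[[a]], taxa[[b]])) > 0,
                  el$i, el$j)
  el[!share, , drop = FALSE]
}

#' Agglomerative conditional clustering of one environment
#'
#' Starting from one node per genus, repeatedly selects a significantly
#' associated pair of nodes (Z above the calibrated cutoff and co-occurring
#' in more than `min_cooccurrence` samples) at random with probability
#' proportional to its Z-score, merges it with [merge_pair()], records the
#' directed edges parent -> merged node, and rescores the affected nodes
#' until no eligible pair remains. Residual nodes with an empty presence
#' vector are dropped.
#'
#' @param table [occurrence_table()] for one environment (annotated samples).
#' @param pi matching `probability_matrix` (subtype-wise fit).
#' @param calibration `score_calibration` from the same environment's null
#'   ensemble.
#' @param seed integer seed for the weighted pair selection.
#' @param min_cooccurrence pairs must co-occur in strictly more samples than
#'   this to be mergeable.
#' @param initial_pairs optional precomputed initial pair score table (as
#'   produced internally); lets ensemble runs share the first, deterministic
#'   scoring pass.
#' @param environment environment label stored on the network.
#' @return An `assembly_network`: list with `nodes` (list of node lists),
#'   `edges` (data frame `from`, `to` of node keys), `environment`,
#'   `run_seed`.
#' @export
cluster_environment <- function(table, pi, calibration, seed = 1L,
                                min_cooccurrence = 5, initial_pairs = NULL,
                                environment = "env") {
  X <- unclass(table); Pi <- unclass(pi)
  n0 <- nrow(X)
  cap <- 3L * n0 + 10L
  Xn <- matrix(0L, cap, ncol(X)); Pn <- matrix(0, cap, ncol(X))
  Xn[seq_len(n0), ] <- X; Pn[seq_len(n0), ] <- Pi
  taxa <- vector("list", cap)
  for (ii in seq_len(n0)) taxa[[ii]] <- rownames(X)[ii]
  residual <- logical(cap)
  active <- c(rep(TRUE, n0), rep(FALSE, cap - n0))
  n_nodes <- n0
  edges_from <- character(0); edges_to <- character(0)
  set.seed(seed)
  pairs <- initial_pairs
  repeat {
    act <- which(active)
    sub <- seq_along(act)
    el <- eligible_pairs(Xn[act, , drop = FALSE], Pn[act, , drop = FALSE],
                         taxa[act], calibration, min_cooccurrence,
                         pairs = pairs)
    pairs <- NULL
    if (nrow(el) == 0) break
    pick <- if (nrow(el) == 1) 1L else
      sample.int(nrow(el), 1L, prob = pmax(el$z, 0))
    gi <- act[el$i[pick]]; gj <- act[el$j[pick]]
    ni <- list(taxa = taxa[[gi]], presence = Xn[gi, ], prob = Pn[gi, ])
    nj <- list(taxa = taxa[[gj]], presence = Xn[gj, ], prob = Pn[gj, ])
    mg <- merge_pair(ni, nj)
    if (n_nodes + 3L > cap) {  # grow storage
      extra <- cap
      Xn <- rbind(Xn, matrix(0L, extra, ncol(Xn)))
      Pn <- rbind(Pn, matrix(0, extra, ncol(Pn)))
      taxa <- c(taxa, vector("list", extra))
      residual <- c(residual, logical(extra))
      active <- c(active, logical(extra))
      cap <- cap + extra
    }
    add_node <- function(nd) {
      n_nodes <<- n_nodes + 1L
      Xn[n_nodes, ] <<- nd$presence
      Pn[n_nodes, ] <<- nd$prob
      taxa[[n_nodes]] <<- nd$taxa
      residual[n_nodes] <<- isTRUE(nd$is_residual)
      active[n_nodes] <<- sum(nd$presence) > 0
    }
    add_node(mg$k)
    add_node(mg$i_residual)
    add_node(mg$j_residual)
    active[c(gi, gj)] <- FALSE
    kk <- node_key(mg$k$taxa)
    edges_from <- c(edges_from, node_key(ni$taxa), node_key(nj$taxa))
    edges_to <- c(edges_to, kk, kk)
  }
  nodes <- lapply(seq_len(n_nodes), function(ii)
    list(taxa = taxa[[ii]], presence = Xn[ii, ], prob = Pn[ii, ],
         is_residual = residual[ii], active = active[ii]))
  names(nodes) <- vapply(nodes, function(nd) node_key(nd$taxa), "")
  # collapse duplicate keys (residuals share the parent's taxa set)
  nodes <- nodes[!duplicated(names(nodes))]
  structure(list(nodes = nodes,
                 edges = unique(data.frame(from = edges_from, to = edges_to,
                                           stringsAsFactors = FALSE)),
                 environment = environment, run_seed = seed),
            class = "assembly_network")
}

#' @export
print.assembly_network <- function(x, ...) {
  sizes <- vapply(x$nodes, function(nd) length(nd$taxa), 1L)
  cat(sprintf("assembly_network (%s): %d nodes (%d multi-genus), %d edges\n",
              x$environment, length(x$nodes), sum(sizes > 1), nrow(x$edges)))
  invisible(x)
}

# deterministic child seed derivation, kept below 2^31
child_seed <- function(base_seed, k) {
  (as.numeric(base_seed) * 48271 + k * 16807) %% 2147483629
}

#' Run an ensemble of independent clustering runs
#'
#' The clustering is stochastic (weighted random pair selection); running it
#' repeatedly and combining the runs minimizes path dependency. The initial
#' all-pairs scoring is deterministic and shared across runs.
#'
#' @inheritParams cluster_environment
#' @param n_runs number of independent runs.
#' @param base_seed master seed from which per-run seeds are derived.
#' @return List of `assembly_network`, one per run.
#' @export
run_ensemble <- function(table, pi, calibration, n_runs = 100,
                         base_seed = 1L, min_cooccurrence = 5,
                         environment = "env") {
  stopifnot(n_runs >= 1)
  init <- pair_score_table(unclass(table), unclass(pi))
  lapply(seq_len(n_runs), function(r)
    cluster_environment(table, pi, calibration,
                        seed = child_seed(base_seed, r),
                        min_cooccurrence = min_cooccurrence,
                        initial_pairs = init, environment = environment))
}

#' Combine clustering runs into a supported consensus network
#'
#' Nodes with the same taxa set are collapsed; the support of a node or edge
#' is the number of individual run networks containing it. Nodes and edges
#' below `min_support` are discarded, as are edges with a discarded
#' endpoint. Each node is annotated with the environments of the runs that
#' produced it; nodes of two or more genera found in more than one
#' environment are flagged multi-environment.
#'
#' @param runs flat list of `assembly_network` objects (all environments).
#' @param min_support minimum support to retain a node or edge.
#' @return A `combined_network`: list with `nodes` (data frame `key`,
#'   `size`, `support`, `environments`, `multi_env`), `edges` (data frame
#'   `from`, `to`, `support`) and `taxa` (named list key -> genus vector).
#' @export
combine_runs <- function(runs, min_support = 10) {
  node_support <- new.env(hash = TRUE)
  node_envs <- list()
  taxa_map <- list()
  edge_count <- list()
  for (net in runs) {
    keys <- names(net$nodes)
    for (k in keys) {
      node_envs[[k]] <- union(node_envs[[k]], net$environment)
      if (is.null(taxa_map[[k]])) taxa_map[[k]] <- net$nodes[[k]]$taxa
    }
    cnt <- mget(keys, envir = node_support, ifnotfound = 0L)
    for (k in keys) assign(k, cnt[[k]] + 1L, envir = node_support)
    if (nrow(net$edges)) {
      ek <- paste(net$edges$from, net$edges$to, sep = " -> ")
      for (e in unique(ek))
        edge_count[[e]] <- (edge_count[[e]] %||% 0L) + 1L
    }
  }
  keys <- ls(node_support)
  sup <- vapply(keys, function(k) get(k, envir = node_support), 1L)
  keep <- sup >= min_support
  keys <- keys[keep]; sup <- sup[keep]
  sizes <- vapply(taxa_map[keys], length, 1L)
  envs <- vapply(node_envs[keys], function(v) paste(sort(v), collapse = ","), "")
  multi <- vapply(node_envs[keys], length, 1L) > 1 & sizes >= 2
  nodes <- data.frame(key = unname(keys), size = unname(sizes),
                      support = unname(sup), environments = unname(envs),
                      multi_env = unname(multi), stringsAsFactors = FALSE)
  edges <- data.frame(from = character(0), to = character(0),
                      support = integer(0), stringsAsFactors = FALSE)
  if (length(edge_count)) {
    ek <- names(edge_count)
    es <- unlist(edge_count, use.names = FALSE)
    parts <- strsplit(ek, " -> ", fixed = TRUE)
    ef <- vapply(parts, `[`, "", 1L); et <- vapply(parts, `[`, "", 2L)
    keep_e <- es >= min_support & ef %in% nodes$key & et %in% nodes$key
    edges <- data.frame(from = ef[keep_e], to = et[keep_e],
                        support = es[keep_e], stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, taxa = taxa_map[nodes$key]),
            class = "combined_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.combined_network <- function(x, ...) {
  cat(sprintf(
    "combined_network: %d nodes (%d assemblages of 2+ genera), %d edges\n",
    nrow(x$nodes), sum(x$nodes$size >= 2), nrow(x$edges)))
  invisible(x)
}

#' Terminal assemblages of the highly supported consensus subnetwork
#'
#' Restricts the combined network to edges with support strictly above
#' `min_edge_support` and returns the keys of multi-genus nodes with no
#' outgoing edge in that restricted graph: the sink assemblages, i.e. the
#' final products of agglomeration.
#'
#' @param net a `combined_network`.
#' @param min_edge_support support an edge must exceed to be retained.
#' @return Character vector of node keys.
#' @export
consensus_terminals <- function(net, min_edge_support = 70) {
  hi <- net$edges[net$edges$support > min_edge_support, , drop = FALSE]
  multi <- net$nodes$key[net$nodes$size >= 2]
  setdiff(multi, unique(hi$from))
}

#' Export a combined network to GraphML and TSV
#'
#' @param net a `combined_network`.
#' @param graphml_path output GraphML path (or `NULL` to skip).
#' @param nodes_path,edges_path output TSV paths (or `NULL` to skip).
#' @return The igraph graph, invisibly.
#' @export
export_network <- function(net, graphml_path = NULL, nodes_path = NULL,
                           edges_path = NULL) {
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = net$nodes)
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(nodes_path))
    write.table(net$nodes, nodes_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(edges_path))
    write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(g)
}
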