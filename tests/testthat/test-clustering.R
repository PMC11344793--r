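test_that("merging partitions each parent's samples exactly", {
  ni <- list(taxa = "A", presence = c(1L, 1L, 0L), prob = c(.5, .6, .7))
  nj <- list(taxa = "B", presence = c(1L, 0L, 1L), prob = c(.4, .2, .1))
  mg <- merge_pair(ni, nj)
  expect_equal(mg$k$presence, c(1L, 0L, 0L))
  expect_equal(mg$i_residual$presence, c(0L, 1L, 0L))
  expect_equal(mg$j_residual$presence, c(0L, 0L, 1L))
  expect_equal(mg$k$prob[1], .5 * .4)
  expect_equal(mg$i_residual$prob[1], .5 * (1 - .4))
  expect_equal(mg$k$taxa, c("A", "B"))
  expect_true(mg$i_residual$is_residual)

  # conservation identity over random vectors
  set.seed(51)
  for (r in 1:200) {
    m <- sample(3:30, 1)
    xi <- rbinom(m, 1L, .5); xj <- rbinom(m, 1L, .5)
    if (sum(xi * xj) == 0) next
    mg <- merge_pair(list(taxa = "A", presence = xi, prob = runif(m)),
                     list(taxa = "B", presence = xj, prob = runif(m)))
    expect_identical(mg$k$presence + mg$i_residual$presence, xi)
    expect_identical(mg$k$presence + mg$j_residual$presence, xj)
  }

  expect_error(merge_pair(list(taxa = "A", presence = c(1L, 0L),
                               prob = c(.5, .5)),
                          list(taxa = "B", presence = c(0L, 1L),
                               prob = c(.5, .5))),
               "non-co-occurring")
})

test_that("without significant pairs the network stays all singletons", {
  tab <- random_table(10, 40, fill = 0.3, seed = 52)
  pi <- fit_null_probabilities(tab)
  cal <- flat_calibration(z_cutoff = 1e9)
  net <- cluster_environment(tab, pi, cal, seed = 1)
  expect_equal(nrow(net$edges), 0)
  expect_true(all(vapply(net$nodes, function(nd) length(nd$taxa), 1L) == 1))
})

test_that("a strongly planted pair is recovered with its residuals", {
  sim <- generate_null_occurrences(20, 60, seed = 53)
  X <- unclass(sim$table)
  # perfectly correlated pair occupying half the samples: far more joint
  # presence than the margin model expects
  X["g0001", ] <- rep(c(1L, 0L), each = 30)
  X["g0002", ] <- X["g0001", ]
  tab <- occurrence_table(X)
  pi <- fit_null_probabilities(tab)
  ens <- sample_null_matrices(tab, n = 40, seed = 54)
  cal <- calibrate_scores(tab, pi, ens, target_fpr = 1e-3,
                          min_pairs_per_bin = 10)
  net <- cluster_environment(tab, pi, cal, seed = 55)
  expect_true("g0001|g0002" %in% names(net$nodes))
  expect_true(all(c("g0001 -> g0001|g0002" %in%
                      paste(net$edges$from, "->", net$edges$to))))
  # merged node's taxa strictly contain each parent's
  for (e in seq_len(nrow(net$edges))) {
    pt <- strsplit(net$edges$from[e], "|", fixed = TRUE)[[1]]
    ct <- strsplit(net$edges$to[e], "|", fixed = TRUE)[[1]]
    expect_true(all(pt %in% ct))
    expect_gt(length(ct), length(pt))
  }
  # acyclic: edges always point from smaller to larger taxa sets
  expect_true(all(nchar(net$edges$from) < nchar(net$edges$to)))
})

test_that("ensembles are reproducible under a fixed base seed", {
  sim <- generate_null_occurrences(15, 50, seed = 56)
  pi <- fit_null_probabilities(sim$table)
  cal <- flat_calibration(z_cutoff = 2)
  r1 <- run_ensemble(sim$table, pi, cal, n_runs = 5, base_seed = 99)
  r2 <- run_ensemble(sim$table, pi, cal, n_runs = 5, base_seed = 99)
  expect_identical(lapply(r1, function(n) names(n$nodes)),
                   lapply(r2, function(n) names(n$nodes)))
  expect_identical(lapply(r1, `[[`, "edges"), lapply(r2, `[[`, "edges"))
})

test_that("combining runs counts support and environments", {
  mknet <- function(env, keys, edges = NULL) {
    nodes <- lapply(keys, function(k)
      list(taxa = strsplit(k, "|", fixed = TRUE)[[1]]))
    names(nodes) <- keys
    structure(list(nodes = nodes,
                   edges = if (is.null(edges))
                     data.frame(from = character(0), to = character(0))
                   else edges,
                   environment = env, run_seed = 1),
              class = "assembly_network")
  }
  ed <- data.frame(from = "A", to = "A|B")
  runs <- c(replicate(12, mknet("marine", c("A", "B", "A|B"), ed),
                      simplify = FALSE),
            replicate(9, mknet("soil", c("A", "B", "A|B"), ed),
                      simplify = FALSE),
            replicate(9, mknet("soil", c("A", "C"), NULL),
                      simplify = FALSE))
  net <- combine_runs(runs, min_support = 10)
  nd <- net$nodes
  expect_equal(nd$support[nd$key == "A"], 30)
  expect_equal(nd$support[nd$key == "A|B"], 21)
  expect_false("C" %in% nd$key)  # support 9 < 10
  expect_true(nd$multi_env[nd$key == "A|B"])   # marine + soil, size 2
  expect_false(nd$multi_env[nd$key == "A"])    # singleton never flagged
  expect_equal(net$edges$support[net$edges$from == "A"], 21)

  # identical runs: support equals the run count everywhere
  same <- replicate(30, mknet("soil", c("A", "B", "A|B"), ed),
                    simplify = FALSE)
  net2 <- combine_runs(same, min_support = 10)
  expect_true(all(net2$nodes$support == 30))
  expect_true(all(net2$edges$support == 30))
})

test_that("consensus terminals are the sinks of the supported subgraph", {
  net <- structure(list(
    nodes = data.frame(key = c("A", "A|B", "A|B|C", "D|E"),
                       size = c(1, 2, 3, 2), support = c(100, 100, 100, 90),
                       environments = "e", multi_env = FALSE),
    edges = data.frame(from = c("A", "A|B"), to = c("A|B", "A|B|C"),
                       support = c(100, 100)),
    taxa = list(A = "A", `A|B` = c("A", "B"), `A|B|C` = c("A", "B", "C"),
                `D|E` = c("D", "E"))), class = "combined_network")
  expect_setequal(consensus_terminals(net, 70), c("A|B|C", "D|E"))
  # dropping the second edge below the cutoff makes A|B terminal too
  net$edges$support[2] <- 50
  expect_setequal(consensus_terminals(net, 70), c("A|B", "A|B|C", "D|E"))

  # random DAG vs brute-force out-degree scan
  set.seed(57)
  keys <- vapply(1:15, function(i)
    paste(sort(sample(LETTERS[1:8], sample(2:4, 1))), collapse = "|"), "")
  keys <- unique(keys)
  ed <- data.frame(from = sample(keys, 20, TRUE),
                   to = sample(keys, 20, TRUE),
                   support = sample(50:100, 20, TRUE))
  net2 <- structure(list(
    nodes = data.frame(key = keys, size = 2, support = 100,
                       environments = "e", multi_env = FALSE),
    edges = ed, taxa = setNames(strsplit(keys, "|", fixed = TRUE), keys)),
    class = "combined_network")
  brute <- keys[!(keys %in% ed$from[ed$support > 70])]
  expect_setequal(consensus_terminals(net2, 70), brute)
})

test_that("network export writes GraphML and TSV", {
  net <- structure(list(
    nodes = data.frame(key = c("A", "B", "A|B"), size = c(1, 1, 2),
                       support = c(10, 10, 10), environments = "e",
                       multi_env = FALSE),
    edges = data.frame(from = c("A", "B"), to = c("A|B", "A|B"),
                       support = c(10, 10)),
    taxa = list(A = "A", B = "B", `A|B` = c("A", "B"))),
    class = "combined_network")
  gml <- withr::local_tempfile(fileext = ".graphml")
  nod <- withr::local_tempfile(fileext = ".tsv")
  g <- export_network(net, gml, nod)
  expect_true(file.exists(gml))
  expect_equal(igraph::vcount(g), 3)
  expect_equal(nrow(read.delim(nod)), 3)
})
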