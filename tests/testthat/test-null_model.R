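test_that("margin model reproduces observed row and column totals", {
  # saturated table: probabilities pinned at 1
  ones <- occurrence_table(matrix(1L, 4, 5,
                                  dimnames = list(paste0("g", 1:4),
                                                  paste0("s", 1:5))))
  expect_true(all(fit_null_probabilities(ones) == 1))

  # a genus never observed gets a zero probability row
  X <- unclass(random_table(10, 12, fill = 0.5, seed = 21))
  X[3, ] <- 0L
  pi <- fit_null_probabilities(occurrence_table(X))
  expect_true(all(pi[3, ] == 0))

  # random table: expected margins match observations
  tab <- random_table(30, 40, fill = 0.3, seed = 22)
  pi2 <- fit_null_probabilities(tab)
  r <- rowSums(unclass(tab)); s <- colSums(unclass(tab))
  expect_lt(max(abs(rowSums(pi2) - r) / pmax(r, 1)), 1e-4)
  expect_lt(max(abs(colSums(pi2) - s) / pmax(s, 1)), 1e-4)
  expect_true(all(pi2 >= 0 & pi2 <= 1))
})

test_that("subtype-wise fit matches margins within each subtype block", {
  sim <- generate_null_occurrences(25, env_layout = list(
    e1 = c(a = 30, b = 25), e2 = c(c = 20)), seed = 23)
  pi <- fit_null_by_subtype(sim$table, sim$annotation)
  for (st in c("a", "b", "c")) {
    cols <- sim$annotation$sample_id[sim$annotation$env_subtype == st]
    blk <- unclass(sim$table)[, cols]
    expect_lt(max(abs(colSums(pi[, cols]) - colSums(blk))), 1e-3)
  }
})

test_that("curveball ensembles preserve margins exactly", {
  ens0 <- sample_null_matrices(random_table(5, 5, seed = 1), n = 0)
  expect_length(ens0$matrices, 0)

  tab <- random_table(20, 30, fill = 0.3, seed = 31)
  ens <- sample_null_matrices(tab, n = 25, seed = 32)
  for (M in ens$matrices) {
    expect_identical(rowSums(M), ens$row_totals)
    expect_identical(colSums(M), ens$col_totals)
  }
})

test_that("curveball sampling matches vegan's on cell occupancy", {
  # independent implementation of the same Markov chain: per-cell occupancy
  # frequencies over the ensemble must agree
  tab <- random_table(10, 14, fill = 0.35, seed = 36)
  ours <- sample_null_matrices(tab, n = 400, seed = 37)
  freq_ours <- Reduce(`+`, ours$matrices) / 400
  nm <- vegan::nullmodel(unclass(tab), "curveball")
  sim <- stats::simulate(nm, nsim = 400, thin = 100, burnin = 1000,
                         seed = 38)
  freq_vegan <- apply(sim, c(1, 2), mean)
  expect_lt(max(abs(freq_ours - freq_vegan)), 0.12)
  expect_gt(cor(as.vector(freq_ours), as.vector(freq_vegan)), 0.98)
})

test_that("the 2x2 two-state chain mixes to equal frequencies", {
  X <- occurrence_table(matrix(c(1L, 0L, 0L, 1L), 2,
                               dimnames = list(c("g1", "g2"),
                                               c("s1", "s2"))))
  ens <- sample_null_matrices(X, n = 2000, seed = 33, burn_in = 20,
                              thin = 4)
  state1 <- vapply(ens$matrices, function(M) M[1, 1] == 1L, TRUE)
  expect_gt(mean(state1), 0.45)
  expect_lt(mean(state1), 0.55)
})

test_that("co-occurrence tails agree with exhaustive enumeration", {
  expect_equal(cooccurrence_tail(runif(7), 0), 1)
  expect_equal(cooccurrence_tail(rep(0, 5), 1), 0)
  expect_equal(cooccurrence_tail(c(0.5, 0.5), 1), 0.75)
  expect_error(cooccurrence_tail(c(0.5, 1.2), 1), "\\[0,1\\]")

  set.seed(34)
  for (k in 1:40) {
    m <- sample(1:10, 1)
    p <- runif(m)
    n <- sample(0:m, 1)
    expect_equal(cooccurrence_tail(p, n), pb_tail_enum(p, n),
                 tolerance = 1e-12)
  }
  # monotone non-increasing in the observed count
  p <- runif(9)
  tails <- vapply(0:9, function(n) cooccurrence_tail(p, n), 1)
  expect_true(all(diff(tails) <= 1e-15))
})

test_that("aggregation scores are non-negative and track the tail", {
  tab <- occurrence_table(matrix(c(1L, 1L, 0L, 1L, 0L, 1L), 2, 3,
                                 byrow = TRUE,
                                 dimnames = list(c("a", "b"),
                                                 paste0("s", 1:3))))
  pi <- matrix(0.5, 2, 3, dimnames = dimnames(tab))
  s <- aggregation_score(tab, pi, "a", "b")  # N = 1, probs 0.25^3
  expect_equal(exp(-s), pb_tail_enum(rep(0.25, 3), 1), tolerance = 1e-12)

  # zero co-occurrence: tail 1, score 0
  tab0 <- occurrence_table(matrix(c(1L, 0L, 0L, 1L), 2, 2,
                                  dimnames = list(c("a", "b"),
                                                  c("s1", "s2"))))
  expect_equal(aggregation_score(tab0, matrix(.3, 2, 2), 1, 2), 0)

  # more observed co-occurrence never lowers the score
  set.seed(35)
  p <- runif(12, 0.1, 0.9)
  scores <- vapply(1:12, function(n) -log(cooccurrence_tail(p, n)), 1)
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("z-scores standardize against the calibrated bins", {
  cal <- flat_calibration(mean = 2, sd = 0.5, z_cutoff = 3)
  expect_equal(pair_zscore(2, 10, 10, cal)$z, 0)
  expect_equal(pair_zscore(3, 10, 10, cal)$z, 2)
  expect_false(pair_zscore(3, 10, 10, cal)$significant)
  expect_true(pair_zscore(4, 10, 10, cal)$significant)
})

test_that("calibration controls the null false-positive rate", {
  sim <- generate_null_occurrences(60, 120, seed = 41)
  tab <- sim$table
  pi <- fit_null_probabilities(tab)
  ens <- sample_null_matrices(tab, n = 60, seed = 42)
  cal <- calibrate_scores(tab, pi, ens, target_fpr = 1e-3)
  # on the calibration ensemble itself the exceedance rate is bounded
  occ <- rowSums(unclass(tab))
  exceed <- 0; total <- 0
  for (M in ens$matrices) {
    res <- assemblnet:::pair_score_table(M, unclass(pi))
    z <- pair_zscore(res$score, occ[res$i], occ[res$j], cal)
    exceed <- exceed + sum(z$significant); total <- total + nrow(res)
  }
  expect_lte(exceed / total, 1e-3)
  # and approximately holds on fresh draws
  f <- empirical_fpr(tab, pi, cal, n_fresh = 40, seed = 43)
  expect_lte(f$fpr, 2e-3)
  # per-bin standardization: null Z-scores are centered
  expect_lt(abs(mean((res$score - cal$mean[
    assemblnet:::calibration_bin(cal, log(occ[res$i] * occ[res$j] + 1))]) /
      cal$sd[assemblnet:::calibration_bin(
        cal, log(occ[res$i] * occ[res$j] + 1))])), 0.2)
})

test_that("degenerate null ensembles are caught", {
  # a 2x2 checkerboard has no co-occurrence anywhere: all null scores are
  # zero and no usable bin variance exists
  X <- occurrence_table(matrix(c(1L, 0L, 0L, 1L), 2,
                               dimnames = list(c("g1", "g2"),
                                               c("s1", "s2"))))
  pi <- fit_null_probabilities(X)
  ens <- sample_null_matrices(X, n = 10, seed = 44)
  expect_error(calibrate_scores(X, pi, ens, n_bins = 2,
                                min_pairs_per_bin = 1),
               "degenerate")
})

test_that("a permissive target keeps every pair significant", {
  tab <- random_table(12, 30, fill = 0.4, seed = 45)
  pi <- fit_null_probabilities(tab)
  ens <- sample_null_matrices(tab, n = 20, seed = 46)
  cal <- calibrate_scores(tab, pi, ens, target_fpr = 1,
                          min_pairs_per_bin = 5, n_bins = 4)
  # cutoff at the minimum null Z: everything above it
  occ <- rowSums(unclass(tab))
  res <- assemblnet:::pair_score_table(unclass(tab), unclass(pi))
  z <- pair_zscore(res$score, occ[res$i], occ[res$j], cal)
  expect_gte(mean(z$z >= cal$z_cutoff), 0.99)
})
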