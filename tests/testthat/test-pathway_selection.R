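test_that("pathway calls follow the one-sided 95% empirical rules", {
  # missing: absent from the assemblage, present in nearly all randoms
  expect_equal(classify_pathway(0, 5, rep(c(1, 0), c(97, 3))), "Missing")
  # redundant: P = S = 5, prevalence above 96% of randoms
  rnd <- rep(c(2, 5), c(96, 4))
  expect_equal(classify_pathway(5, 5, rnd), "Redundant")
  # specific: P = 1 while 97% of randoms have 3+
  rnd2 <- rep(c(3, 1), c(97, 3))
  expect_equal(classify_pathway(1, 5, rnd2), "Specific")
  # ties favor Unclassified: equality is not "higher"
  expect_equal(classify_pathway(2, 5, rep(2, 100)), "Unclassified")
  # redundancy needs two carriers no matter how extreme the null
  expect_equal(classify_pathway(1, 5, rep(0, 100)), "Unclassified")
  expect_error(classify_pathway(1, 5, integer(0)), "empty")
})

test_that("calls agree with brute-force percentile checks and are exclusive", {
  set.seed(81)
  for (r in 1:300) {
    S <- sample(2:10, 1)
    P <- sample(0:S, 1)
    rnd <- sample(0:S, 200, replace = TRUE)
    call <- classify_pathway(P, S, rnd)
    expected <- if (P >= 2 && sum(P > rnd) >= 0.95 * 200) "Redundant"
      else if (P >= 1 && sum(P < rnd) >= 0.95 * 200) "Specific"
      else if (P == 0 && sum(rnd >= 1) >= 0.95 * 200) "Missing"
      else "Unclassified"
    expect_identical(call, expected)
  }
})

test_that("auxotroph fractions are 1 - P/S", {
  expect_equal(auxotroph_fraction(5, 5), 0)
  expect_equal(auxotroph_fraction(0, 5), 1)
  expect_equal(auxotroph_fraction(1, 5), 0.8)
  expect_error(auxotroph_fraction(6, 5), "\\[0, S\\]")
})

test_that("planted pathway roles are recovered across a network", {
  set.seed(82)
  genera <- sprintf("g%03d", 1:50)
  ph <- generate_phylo_distances(genera, seed = 83)
  D <- genus_distances(ph$D, ph$species_to_genus)
  asm <- split(genera[1:15], rep(1:3, each = 5))
  planted <- list()
  for (k in seq_along(asm)) {
    planted <- c(planted, list(
      list(taxa = asm[[k]], pathway = sprintf("red%02d", k),
           role = "redundant"),
      list(taxa = asm[[k]], pathway = sprintf("spec%02d", k),
           role = "specific"),
      list(taxa = asm[[k]], pathway = sprintf("miss%02d", k),
           role = "missing")))
  }
  pu <- generate_pathway_universe(genera, n_pathways = 60,
                                  planted = planted, seed = 84)
  pool <- data.frame(genus = genera, env_subtype = "sub1")
  terms <- setNames(asm, vapply(asm, function(t)
    paste(sort(t), collapse = "|"), ""))
  subs <- setNames(rep("sub1", 3), names(terms))
  cls <- classify_network(terms, pu$core, D, pool, subs, n_random = 300,
                          phylo_tolerance = 0.1, seed = 85)
  role2call <- c(redundant = "Redundant", specific = "Specific",
                 missing = "Missing")
  gt <- pu$ground_truth
  for (r in seq_len(nrow(gt))) {
    got <- cls$call[cls$assemblage == gt$assemblage[r] &
                      cls$pathway == gt$pathway[r]]
    expect_identical(got, unname(role2call[gt$role[r]]))
  }
  # every (assemblage, pathway) pair got exactly one call
  expect_true(all(cls$call %in% c("Redundant", "Specific", "Missing",
                                  "Unclassified")))
  expect_equal(nrow(cls), 3 * length(unique(cls$pathway)))
})

test_that("size classes split and compare pathway loads", {
  cls <- rbind(
    data.frame(assemblage = "a1", pathway = paste0("p", 1:4), P = c(2, 1, 0, 3),
               S = 3, call = c("Redundant", "Specific", "Missing",
                               "Unclassified")),
    data.frame(assemblage = "a2", pathway = paste0("p", 1:4), P = c(3, 1, 0, 2),
               S = 6, call = c("Redundant", "Specific", "Missing",
                               "Unclassified")))
  out <- size_class_comparison(cls, size_threshold = 5)
  expect_equal(out$n_small, rep(1, 4))
  expect_equal(out$n_large, rep(1, 4))
  expect_true(all(is.na(out$p)))  # single assemblage per class: not testable
  tot <- out[out$class == "total", ]
  expect_equal(tot$mean_small, 6 / 3)
  expect_equal(tot$mean_large, 6 / 6)

  # planted: large assemblages carry systematically more specific pathways
  set.seed(86)
  mk <- function(id, S, n_spec) {
    data.frame(assemblage = id, pathway = sprintf("p%02d", 1:20),
               P = 1, S = S,
               call = rep(c("Specific", "Unclassified"),
                          c(n_spec, 20 - n_spec)))
  }
  big <- do.call(rbind, c(
    lapply(1:8, function(i) mk(paste0("s", i), 3, sample(1:3, 1))),
    lapply(1:8, function(i) mk(paste0("l", i), 6, sample(8:12, 1)))))
  out2 <- size_class_comparison(big, size_threshold = 5)
  expect_lt(out2$p[out2$class == "Specific"], 0.05)
})

test_that("auxotrophy records average over large assemblages only", {
  cls <- rbind(
    data.frame(assemblage = "big1", pathway = c("trpPath", "alaPath"),
               P = c(1, 5), S = 5, call = "Specific"),
    data.frame(assemblage = "big2", pathway = c("trpPath", "alaPath"),
               P = c(2, 4), S = 8, call = "Specific"),
    data.frame(assemblage = "small", pathway = "trpPath", P = 0, S = 2,
               call = "Missing"))
  aa_map <- data.frame(pathway = c("trpPath", "alaPath"),
                       amino_acid = c("Trp", "Ala"))
  costs <- data.frame(amino_acid = c("Trp", "Ala"), cost = c(74.3, 11.7))
  rec <- auxotrophy_records(cls, aa_map, costs, size_threshold = 5)
  trp <- rec[rec$amino_acid == "Trp", ]
  expect_equal(trp$mean_auxotroph_fraction, mean(c(1 - 1 / 5, 1 - 2 / 8)))
  expect_equal(trp$n_assemblages, 2)  # the size-2 assemblage is excluded
  expect_equal(rec$cost[rec$amino_acid == "Ala"], 11.7)
})

test_that("the cost regression recovers linear auxotrophy patterns", {
  costs <- read_aa_costs(system.file("extdata", "aa_costs.tsv",
                                     package = "assemblnet"))
  expect_equal(nrow(costs), 20)

  # exact linear input: perfect fit
  rec <- data.frame(amino_acid = costs$amino_acid,
                    mean_auxotroph_fraction = 0.01 * costs$cost + 0.1,
                    cost = costs$cost)
  fit <- cost_regression(rec)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$slope, 0.01, tolerance = 1e-10)

  # noisy synthetic fractions: slope recovered within 3 standard errors
  set.seed(87)
  sub <- costs[costs$amino_acid != "Trp", ]
  rec2 <- data.frame(amino_acid = sub$amino_acid,
                     mean_auxotroph_fraction =
                       0.02 * sub$cost + rnorm(19, 0, 0.05),
                     cost = sub$cost)
  fit2 <- cost_regression(rec2)
  expect_equal(fit2$n, 19)
  expect_lt(abs(fit2$slope - 0.02), 3 * fit2$slope_se)

  # exclusion shrinks the data; too much exclusion errors
  fit3 <- cost_regression(rec2, exclude = "Phe")
  expect_equal(fit3$n, 18)
  expect_error(cost_regression(rec2, exclude = sub$amino_acid[1:17]),
               "at least 3")
})
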