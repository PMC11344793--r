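#' Fit per-environment null occurrence probabilities
#'
#' Fits the maximum-entropy margin model pi_ia = logistic(alpha_i + beta_a)
#' to one environmental subtype's binary occurrence table, so that the
#' expected row and column totals match the observed totals. Rows or columns
#' with all-zero (all-one) observations are assigned probability 0 (1)
#' exactly and excluded from the interior fit.
#'
#' Fitting alternates Newton updates of the row and column offsets until the
#' worst relative margin residual falls below `tol`.
#'
#' @param table an [occurrence_table()] restricted to one environmental
#'   subtype.
#' @param tol relative tolerance on margin matching.
#' @param max_iter maximum alternating sweeps.
#' @return A `probability_matrix`: numeric matrix of occurrence probabilities
#'   with the same dimnames as `table`.
#' @export
fit_null_probabilities <- function(table, tol = 1e-6, max_iter = 1000L) {
  X <- unclass(table)
  n <- nrow(X); m <- ncol(X)
  P <- matrix(0, n, m, dimnames = dimnames(X))
  live_r <- rep(TRUE, n); live_c <- rep(TRUE, m)
  # peel structurally determined rows/columns (empty or saturated margins)
  repeat {
    changed <- FALSE
    rs <- rowSums(X[, live_c, drop = FALSE])[live_r]
    mm <- sum(live_c)
    full_r <- names(rs)[rs == mm]; zero_r <- names(rs)[rs == 0]
    if (length(full_r)) { P[full_r, live_c] <- 1; live_r[rownames(X) %in% full_r] <- FALSE; changed <- TRUE }
    if (length(zero_r)) { live_r[rownames(X) %in% zero_r] <- FALSE; changed <- TRUE }
    cs <- colSums(X[live_r, , drop = FALSE])[live_c]
    nn <- sum(live_r)
    full_c <- names(cs)[cs == nn & nn > 0]; zero_c <- names(cs)[cs == 0]
    if (length(full_c)) { P[live_r, full_c] <- 1; live_c[colnames(X) %in% full_c] <- FALSE; changed <- TRUE }
    if (length(zero_c)) { live_c[colnames(X) %in% zero_c] <- FALSE; changed <- TRUE }
    if (!changed || !any(live_r) || !any(live_c)) break
  }
  if (any(live_r) && any(live_c)) {
    Xi <- X[live_r, live_c, drop = FALSE]
    r <- rowSums(Xi); s <- colSums(Xi)
    ni <- nrow(Xi); mi <- ncol(Xi)
    alpha <- stats::qlogis(pmin(pmax(r / mi, 1e-8), 1 - 1e-8))
    beta <- rep(0, mi)
    worst <- Inf
    for (it in seq_len(max_iter)) {
      E <- plogis(outer(alpha, beta, "+"))
      V <- E * (1 - E)
      alpha <- alpha + (r - rowSums(E)) / pmax(rowSums(V), 1e-12)
      alpha <- pmin(pmax(alpha, -35), 35)
      E <- plogis(outer(alpha, beta, "+"))
      V <- E * (1 - E)
      beta <- beta + (s - colSums(E)) / pmax(colSums(V), 1e-12)
      beta <- pmin(pmax(beta, -35), 35)
      E <- plogis(outer(alpha, beta, "+"))
      worst <- max(abs(rowSums(E) - r) / pmax(r, 1),
                   abs(colSums(E) - s) / pmax(s, 1))
      if (worst < tol) break
    }
    if (worst >= tol)
      stop(sprintf("margin fit did not converge: worst relative residual %.3g",
                   worst))
    P[live_r, live_c] <- E
  }
  P <- pmin(pmax(P, 0), 1)
  dim(P) <- dim(X); dimnames(P) <- dimnames(X)
  class(P) <- c("probability_matrix", class(P))
  P
}

#' Fit subtype-wise null probabilities across a whole environment
#'
#' Samples are grouped by `env_subtype`; a separate margin model is fitted to
#' each subtype block and the blocks are reassembled in the original sample
#' order. Samples without annotation are dropped with a warning.
#'
#' @param table an [occurrence_table()].
#' @param annotation sample annotation (columns `sample_id`, `env_type`,
#'   `env_subtype`).
#' @inheritParams fit_null_probabilities
#' @return A `probability_matrix` over the annotated samples of `table`.
#' @export
fit_null_by_subtype <- function(table, annotation, tol = 1e-6,
                                max_iter = 1000L) {
  keep <- colnames(table) %in% annotation$sample_id
  if (!all(keep)) {
    warning(sum(!keep), " unannotated samples dropped")
    table <- occurrence_table(unclass(table)[, keep, drop = FALSE])
  }
  sub <- annotation$env_subtype[match(colnames(table), annotation$sample_id)]
  P <- matrix(0, nrow(table), ncol(table), dimnames = dimnames(table))
  for (s in unique(sub)) {
    cols <- which(sub == s)
    blk <- occurrence_table(unclass(table)[, cols, drop = FALSE])
    P[, cols] <- fit_null_probabilities(blk, tol = tol, max_iter = max_iter)
  }
  class(P) <- c("probability_matrix", class(P))
  P
}

#' Sample fixed-margin null matrices by curveball randomization
#'
#' Draws binary matrices with exactly the row and column totals of `table`
#' using curveball trades (random redistribution of the columns held by
#' exactly one of two rows). The chain is burnt in for `burn_in` trades and
#' thinned by `thin` trades between consecutive draws.
#'
#' @param table an [occurrence_table()].
#' @param n number of matrices (>= 0).
#' @param seed integer seed.
#' @param burn_in trades before the first draw; default 5x the number of
#'   ones.
#' @param thin trades between draws; default 1x the number of ones.
#' @return A `null_ensemble`: list with `matrices` (list of 0/1 integer
#'   matrices), `row_totals`, `col_totals`.
#' @export
sample_null_matrices <- function(table, n = 1000, seed = 1L,
                                 burn_in = NULL, thin = NULL) {
  stopifnot(n >= 0)
  X <- unclass(table)
  ones <- sum(X)
  if (is.null(burn_in)) burn_in <- 5L * ones
  if (is.null(thin)) thin <- ones
  out <- vector("list", n)
  set.seed(seed)
  cur <- X
  if (n > 0) {
    cur <- .curveball_cpp(cur, as.integer(burn_in))
    for (k in seq_len(n)) {
      out[[k]] <- cur
      if (k < n) cur <- .curveball_cpp(cur, as.integer(thin))
    }
  }
  structure(list(matrices = out, row_totals = rowSums(X),
                 col_totals = colSums(X)),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: %d fixed-margin matrices (%d x %d)\n",
              length(x$matrices), length(x$row_totals),
              length(x$col_totals)))
  invisible(x)
}

#' Poisson-binomial upper tail probability
#'
#' Probability that a sum of independent Bernoulli trials with success
#' probabilities `pair_probs` is at least `n_obs`, computed by exact dynamic
#' programming. This is the null probability that a pair of taxa co-occurs in
#' at least the observed number of samples when the per-sample co-occurrence
#' probability is the product of the two occurrence probabilities.
#'
#' @param pair_probs per-sample success probabilities in \[0, 1\].
#' @param n_obs observed count (0 .. length of `pair_probs`).
#' @return P(X >= n_obs).
#' @export
cooccurrence_tail <- function(pair_probs, n_obs) {
  if (any(pair_probs < 0 | pair_probs > 1))
    stop("probabilities must lie in [0,1]")
  stopifnot(n_obs >= 0, n_obs <= length(pair_probs))
  .pb_tail_cpp(as.numeric(pair_probs), as.integer(n_obs))
}

#' Aggregation score of a pair of taxa or nodes
#'
#' S = -log P(X >= N), where N is the observed co-occurrence count of the
#' pair and X is Poisson-binomial with per-sample success probability
#' pi_i * pi_j. Tail probabilities below `floor_eps` are clamped so the score
#' stays finite.
#'
#' @param table an [occurrence_table()] (or binary matrix of node presences).
#' @param pi matching probability matrix.
#' @param i,j row labels or indices of the pair.
#' @param floor_eps clamping floor for the tail probability.
#' @return Non-negative score (larger = more surprising co-occurrence).
#' @export
aggregation_score <- function(table, pi, i, j, floor_eps = 1e-300) {
  if (is.character(i)) i <- match(i, rownames(table))
  if (is.character(j)) j <- match(j, rownames(table))
  stopifnot(i != j, !is.na(i), !is.na(j))
  res <- .pair_scores_cpp(unclass(table), unclass(pi),
                          as.integer(i), as.integer(j), floor_eps)
  res$score[1]
}

# all-pairs co-occurrence counts and aggregation scores; internal workhorse
pair_score_table <- function(X, Pi, floor_eps = 1e-300) {
  res <- .all_pair_scores_cpp(unclass(X), unclass(Pi), floor_eps)
  data.frame(i = res$i, j = res$j, n_co = res$n_co, score = res$score)
}

#' Calibrate aggregation scores against a fixed-margin null ensemble
#'
#' Null aggregation scores are computed for every pair in every ensemble
#' matrix (against the same fitted probabilities), binned by pair
#' cosmopolitanism (quantiles of log(n_i * n_j + 1), where n is the
#' occurrence count), and standardized to Z-scores with the per-bin null
#' mean and standard deviation. The Z cutoff is the smallest value such that
#' the fraction of null Z-scores strictly above it does not exceed
#' `target_fpr`.
#'
#' Bins with fewer than `min_pairs_per_bin` pairs or with zero score
#' variance are merged with their neighbor.
#'
#' @param real_table the observed [occurrence_table()].
#' @param pi fitted `probability_matrix` for the same table.
#' @param ensemble a `null_ensemble` from [sample_null_matrices()].
#' @param target_fpr tolerated rate of significant pairs under the null.
#' @param n_bins number of cosmopolitanism bins.
#' @param min_pairs_per_bin minimum distinct pairs per bin before merging.
#' @param floor_eps tail clamping floor.
#' @return A `score_calibration`: list with bin `breaks`, per-bin `mean` and
#'   `sd`, `z_cutoff`, `target_fpr` and the number of null scores used.
#' @export
calibrate_scores <- function(real_table, pi, ensemble, target_fpr = 1e-4,
                             n_bins = 20, min_pairs_per_bin = 50,
                             floor_eps = 1e-300) {
  if (length(ensemble$matrices) == 0) stop("empty null ensemble")
  X <- unclass(real_table); Pi <- unclass(pi)
  n <- nrow(X)
  occ <- rowSums(X)
  pr <- pair_score_table(X, Pi, floor_eps)  # fixes the pair order
  cosmo <- log(occ[pr$i] * occ[pr$j] + 1)
  breaks <- unique(quantile(cosmo, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(breaks) < 2) breaks <- c(-Inf, Inf)
  breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  bin <- findInterval(cosmo, breaks, rightmost.closed = TRUE)
  nb <- length(breaks) - 1L
  # merge undersized bins into their left neighbor (leftmost merges right)
  counts <- tabulate(bin, nb)
  scores <- lapply(ensemble$matrices, function(M) {
    res <- .all_pair_scores_cpp(M, Pi, floor_eps)
    res$score
  })
  S <- unlist(scores, use.names = FALSE)
  binrep <- rep(bin, times = length(scores))
  repeat {
    mu <- tapply(S, binrep, mean)
    sdev <- tapply(S, binrep, sd)
    counts <- tabulate(bin, nb)
    bad <- which(counts > 0 &
                   (counts < min_pairs_per_bin |
                      is.na(sdev[as.character(seq_len(nb))]) |
                      sdev[as.character(seq_len(nb))] <= 0))
    live <- which(counts > 0)
    if (!length(bad)) break
    if (length(live) <= 1)
      stop("degenerate calibration: null scores have zero variance")
    b <- bad[1]
    nb_target <- if (any(live < b)) max(live[live < b]) else min(live[live > b])
    # collapse b into its neighbor by removing the separating break
    drop_break <- if (nb_target < b) b else b + 1L
    breaks <- breaks[-drop_break]
    nb <- length(breaks) - 1L
    bin <- findInterval(cosmo, breaks, rightmost.closed = TRUE)
    binrep <- rep(bin, times = length(scores))
  }
  mu_full <- as.numeric(mu[as.character(seq_len(nb))])
  sd_full <- as.numeric(sdev[as.character(seq_len(nb))])
  Z <- (S - mu_full[binrep]) / sd_full[binrep]
  K <- length(Z)
  m_allow <- floor(target_fpr * K)
  Zs <- sort(Z, decreasing = TRUE)
  z_cutoff <- if (m_allow >= K) Zs[K]
    else if (m_allow >= 1) Zs[m_allow + 1] else Zs[1]
  structure(list(breaks = breaks, mean = mu_full, sd = sd_full,
                 z_cutoff = z_cutoff, target_fpr = target_fpr,
                 n_null_scores = K),
            class = "score_calibration")
}

#' @export
print.score_calibration <- function(x, ...) {
  cat(sprintf(
    "score_calibration: %d bins, z_cutoff %.3f (target FPR %g, %d null scores)\n",
    length(x$mean), x$z_cutoff, x$target_fpr, x$n_null_scores))
  invisible(x)
}

# map cosmopolitanism values to calibration bins
calibration_bin <- function(calibration, cosmo) {
  b <- findInterval(cosmo, calibration$breaks, rightmost.closed = TRUE)
  b[b < 1] <- 1L
  nb <- length(calibration$mean)
  b[b > nb] <- nb
  b
}

#' Standardize an aggregation score to its calibrated Z-score
#'
#' @param score aggregation score(s).
#' @param n_i,n_j occurrence counts (cosmopolitanism) of the two nodes.
#' @param calibration a `score_calibration`.
#' @return List with `z` and logical `significant` (z strictly above the
#'   calibrated cutoff).
#' @export
pair_zscore <- function(score, n_i, n_j, calibration) {
  b <- calibration_bin(calibration, log(n_i * n_j + 1))
  if (any(is.na(calibration$mean[b])))
    stop("uncovered cosmopolitanism bin: ", paste(unique(b), collapse = ", "))
  z <- (score - calibration$mean[b]) / calibration$sd[b]
  list(z = z, significant = z > calibration$z_cutoff)
}

#' Empirical false-positive rate of a calibration on fresh null matrices
#'
#' Draws `n_fresh` additional fixed-margin matrices, scores every pair
#' against the fitted probabilities and reports the fraction flagged
#' significant under the calibrated cutoff.
#'
#' @param table observed [occurrence_table()] (margins source).
#' @param pi fitted `probability_matrix`.
#' @param calibration a `score_calibration`.
#' @param n_fresh number of fresh null matrices.
#' @param seed integer seed (distinct from the calibration ensemble seed).
#' @return List with `fpr`, `n_pairs_evaluated`, `n_significant`.
#' @export
empirical_fpr <- function(table, pi, calibration, n_fresh = 100, seed = 2L) {
  fresh <- sample_null_matrices(table, n = n_fresh, seed = seed)
  occ <- rowSums(unclass(table))
  Pi <- unclass(pi)
  total <- 0; sig <- 0
  first <- TRUE; bins <- NULL
  for (M in fresh$matrices) {
    res <- .all_pair_scores_cpp(M, Pi, 1e-300)
    if (first) {
      bins <- calibration_bin(calibration, log(occ[res$i] * occ[res$j] + 1))
      first <- FALSE
    }
    z <- (res$score - calibration$mean[bins]) / calibration$sd[bins]
    sig <- sig + sum(z > calibration$z_cutoff)
    total <- total + length(z)
  }
  list(fpr = sig / total, n_pairs_evaluated = total, n_significant = sig)
}
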