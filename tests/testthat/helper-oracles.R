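# Independent oracles and fixture builders shared across test files.

# random binary occurrence table with labels
random_table <- function(n_genera, n_samples, fill = 0.3, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n_genera * n_samples, 1L, fill), n_genera,
              dimnames = list(sprintf("g%03d", seq_len(n_genera)),
                              sprintf("s%03d", seq_len(n_samples))))
  occurrence_table(X)
}

# Poisson-binomial upper tail by exhaustive outcome enumeration (n <= 16)
pb_tail_enum <- function(p, n_obs) {
  m <- length(p)
  stopifnot(m <= 16)
  outcomes <- as.matrix(expand.grid(rep(list(0:1), m)))
  logp <- outcomes %*% log(p) + (1 - outcomes) %*% log1p(-p)
  sum(exp(logp)[rowSums(outcomes) >= n_obs])
}

# fixed-point filtering by exhaustive re-checking, independent of the
# implementation's loop structure
filter_brute <- function(X, min_g, min_s) {
  keep_r <- rep(TRUE, nrow(X)); keep_c <- rep(TRUE, ncol(X))
  repeat {
    sub <- X[keep_r, keep_c, drop = FALSE]
    bad_r <- keep_r & (rowSums(X[, keep_c, drop = FALSE]) < min_s)
    bad_c <- keep_c & (colSums(X[keep_r, , drop = FALSE]) < min_g)
    if (!any(bad_r) && !any(bad_c)) break
    keep_r <- keep_r & !bad_r
    keep_c <- keep_c & !bad_c
    if (!any(keep_r) || !any(keep_c)) return(NULL)
  }
  X[keep_r, keep_c, drop = FALSE]
}

# genus distance by explicit loop over all cross species pairs
genus_dist_brute <- function(D, s2g, g, h) {
  si <- names(s2g)[s2g == g]; sj <- names(s2g)[s2g == h]
  median(as.vector(D[si, sj, drop = FALSE]))
}

# flat score calibration covering all cosmopolitanism values
flat_calibration <- function(mean = 0, sd = 1, z_cutoff = 3,
                             target_fpr = 1e-4) {
  structure(list(breaks = c(-Inf, Inf), mean = mean, sd = sd,
                 z_cutoff = z_cutoff, target_fpr = target_fpr,
                 n_null_scores = 0L),
            class = "score_calibration")
}
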