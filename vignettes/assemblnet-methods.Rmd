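---
title: "Agglomerative co-occurrence networks: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agglomerative co-occurrence networks: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assemblnet)
```

## The problem

Cross-study surveys of microbial 16S rRNA data can be reduced to a binary
genus × sample occurrence matrix: abundance information does not survive the
heterogeneity of protocols, but presence/absence does. `assemblnet` infers
which sets of genera ("assemblages") co-occur across such samples more often
than an environment-aware null model predicts, builds a directed
agglomeration network out of those associations, and then asks what the
member genomes tell us about functional redundancy, pathway-level selection,
and amino-acid auxotrophy.

Two features distinguish the approach from ordinary pairwise correlation
networks:

1. **Significance is calibrated per environment.** Taxa co-occur trivially
   because they share habitat preferences. A separate occurrence null model
   is fitted to every environmental subtype, and score significance is
   judged against ensembles of margin-preserving random matrices, so the
   network aims at associations beyond what habitat and prevalence explain.
2. **Co-occurrence is conditional.** When nodes $i$ and $j$ merge, the new
   node keeps only the samples where both occur, and *residual* nodes $i'$,
   $j'$ keep each parent's remaining samples. The same genus can therefore
   join one partner in one habitat and a different partner in another — the
   two associations become different nodes of the network.

## The occurrence null model

For one environmental subtype with binary occurrence matrix $X_{ia}$
(genus $i$, sample $a$), the null model is the maximum-entropy model with
the observed row and column totals as sufficient statistics:

$$\pi_{ia} = \mathrm{logistic}(\alpha_i + \beta_a),$$

fitted by alternating Newton sweeps on $\alpha$ and $\beta$ until every
expected margin matches its observation to a relative tolerance of $10^{-6}$
(`fit_null_probabilities()`). Genera never observed get $\pi = 0$ exactly;
saturated rows or columns are pinned at 1 and peeled off before the interior
fit, which keeps the optimization well posed. The model deliberately
contains no taxon–taxon interaction term: it is the "no interaction"
baseline the aggregation scores are measured against.
`fit_null_by_subtype()` applies the fit blockwise over the subtypes of an
environment and reassembles the full probability matrix.

## Aggregation scores and their calibration

For a pair observed to co-occur in $N$ of $M$ samples, the aggregation score
is

$$S_{ij} = -\log P(X \ge N), \qquad
X \sim \mathrm{PoissonBinomial}(\pi_{i1}\pi_{j1}, \dots, \pi_{iM}\pi_{jM}),$$

i.e. the surprise of seeing at least the observed co-occurrence count when
per-sample joint presence is the product of the two null probabilities
(independence). The tail is computed by an exact truncated dynamic program
(`cooccurrence_tail()`); for deep upper tails the DP runs over the failure
count instead, which avoids the catastrophic cancellation of computing
$1 - P(X < N)$ and keeps relative accuracy near machine precision. The tail
is read *inclusively* ($\ge N$) so the observed configuration always has
positive probability; tails below $10^{-300}$ are clamped so scores stay
finite.

Raw scores depend strongly on how cosmopolitan the two taxa are. Calibration
(`calibrate_scores()`) therefore:

1. draws an ensemble of random matrices with exactly the observed row and
   column totals, using seeded curveball trades (burn-in $5\times$ the
   number of ones, thinning $1\times$ by default);
2. scores every pair in every ensemble matrix against the same fitted
   $\pi$;
3. bins pairs by quantiles of $\log(n_i n_j + 1)$ (occurrence-count
   products; 20 bins by default, bins with fewer than 50 pairs or zero
   variance merged with a neighbor), and standardizes scores to Z-values
   with the per-bin null mean and standard deviation;
4. sets the significance cutoff at the smallest value such that the
   fraction of null Z-values strictly above it does not exceed the target
   false-positive rate ($10^{-4}$ by default).

Because the cutoff is an empirical quantile of the same null process the
fresh data are drawn from, the FPR guarantee is distribution-free; the
package checks it on fresh null matrices with `empirical_fpr()`.

## The clustering recursion

`cluster_environment()` starts from one node per genus and repeats:

* among pairs with calibrated $Z$ above the cutoff **and** co-occurring in
  strictly more than 5 samples, select one at random with probability
  proportional to its $Z$;
* merge it: $X_k = X_i X_j$, $\pi_k = \pi_i \pi_j$ (elementwise), residuals
  $X_{i'} = X_i(1 - X_j)$, $\pi_{i'} = \pi_i(1-\pi_j)$ and symmetrically for
  $j'$; record edges $i \to k$, $j \to k$;
* rescore the affected nodes and iterate until no eligible pair remains.

The merge arithmetic guarantees $X_k + X_{i'} = X_i$: the three children
partition each parent's samples exactly, which is what lets residual nodes
carry conditional associations. Residuals left with no samples are dropped.
Bin statistics from the initial calibration are reused throughout the run
(merged and residual nodes are assigned to bins by their current occurrence
counts); re-simulating a null ensemble at every iteration would be
computationally prohibitive and the reuse is conservative in practice — the
pure-null end-to-end test shows no surviving multi-genus structure.

The weighted random selection makes runs stochastic, so `run_ensemble()`
repeats the clustering (100 runs by default) and `combine_runs()` collapses
nodes with identical taxa sets across runs, counting **support** — the
number of runs containing a node or edge. Nodes and edges with support below
10 are discarded; a node found in runs of more than one environment and
containing at least two genera is flagged multi-environment. A residual node
carries the same taxa as its parent and is collapsed with it on combining.
`consensus_terminals()` keeps edges with support above 70 and returns the
multi-genus sink nodes of that restricted graph — the terminal assemblages,
the final products of agglomeration.

## Functional and phylogenetic annotation

A pathway belongs to a genus when it is predicted in **every** genome
available for the genus (`core_pathways()`: the core-genome reading
insulates the annotation from strain-level accessory noise). Assemblage
summaries (`summarize_assemblage()`) average, over all unordered member
pairs, the Jaccard dissimilarity between core pathway sets and the
phylogenetic distance (genus distances are cross-pair medians of
species-level distances, `genus_distances()`), and record the mean pathways
per genus — a genome-size proxy — and the pathway union.

Real assemblages are compared with four classes of constrained random
assemblages (`random_assemblage_constraint()`): fully random (1000
replicates), same environmental subtype (100), same subtype + mean pairwise
phylogenetic distance within 0.05 substitutions/site (100), and same
subtype + mean pathways per genus within 20% (100). Replicates are produced
by rejection sampling without replacement, with 10,000 attempts before a
replicate is declared infeasible — infeasible draws are dropped with a
warning rather than silently relaxing the constraint, which would bias the
comparison. `redundancy_report()` runs two-sided Mann-Whitney U tests
between every pair of groups, per metric and assemblage size (2–12), with
Benjamini-Hochberg correction within each (metric, size) family.

## Pathway-level selection and auxotrophy

For each terminal assemblage, 1000 environmentally and phylogenetically
equivalent random assemblages are drawn (tolerance widened to 0.1
substitutions/site so enough replicates exist) and each pathway's prevalence
$P$ among the $S$ members is compared with its random prevalence
distribution (`classify_pathway()`):

* **Redundant** — $P \ge 2$ and $P$ strictly exceeds the random prevalence
  in at least 95% of replicates;
* **Specific** — $P \ge 1$ and $P$ is strictly below the random prevalence
  in at least 95% of replicates;
* **Missing** — $P = 0$ while the random prevalence is at least 1 in at
  least 95% of replicates;
* otherwise **Unclassified**. Ties count against classification, the
  conservative reading of a one-sided empirical test.

`size_class_comparison()` contrasts small ($< 5$ members) and large
($\ge 5$) assemblages on per-assemblage pathway loads per class with
rank-sum tests (alternative cutoffs are a parameter). For amino-acid
biosynthesis pathways, the auxotroph fraction of an assemblage is $1 - P/S$;
`auxotrophy_records()` averages it per amino acid over large assemblages and
`cost_regression()` regresses it on biosynthetic cost, with and without
exclusions (tryptophan is the canonical outlier: expensive but tightly
regulated and rarely leaked, so auxotrophy for it is rarer than its cost
alone suggests).

## What the synthetic generators emulate — and what they do not

The generators exist so that every stage can be validated against known
ground truth without any external download.

* `generate_null_occurrences()` draws genus occupancies from
  Beta(0.8, 5) — mean occupancy ≈ 0.14 with a heavy right tail, echoing the
  prevalence skew of environmental surveys — and per-sample richness
  multipliers from $2\,\mathrm{Beta}(2, 2)$, a deliberately broad spread so
  that realized margins track the drawn targets; cells are independent
  Bernoulli draws of the clipped product. This is a genuine co-occurrence
  null.
* `plant_assemblages()` re-draws member presences inside one subtype from a
  shared-indicator mixture: with probability $w$ the whole planted set is
  present, otherwise members are independent with probabilities reduced so
  each marginal occupancy is preserved in expectation. $w$ solves for the
  requested pairwise joint-presence boost; when the boost is unattainable
  (the joint probability cannot exceed the smallest marginal) the achievable
  maximum is used and reported. Margins are preserved in expectation, not
  exactly — sufficient because calibration is refit on the planted matrix.
* `conditional_plants()` additionally localizes each partner to its subtype
  (background presence 0.02 outside). This is a modelling statement, not a
  convenience: when all partners are ubiquitous, the *correct* inference is
  a single joint assemblage, and only habitat-restricted partners make the
  two conditional pairs the right answer.
* `generate_pathway_universe()` plants Redundant/Specific/Missing roles into
  genus cores (rare in the background ≈ 5% for redundant plants, common
  ≈ 85% for specific/missing plants) and emits per-genus genome sets whose
  accessory pathways always miss at least one genome, so the core is exactly
  recoverable by intersection.
* `generate_phylo_distances()` builds coalescent-style ultrametric
  hierarchies at two scales (between-genus 0.05, within-genus 0.004), giving
  distances in a realistic substitutions/site range with within-genus <
  between-genus structure.

What passing tests on these data do **not** show: robustness to study-level
batch structure within a subtype, to misannotated environments, to
phylogenetically correlated occupancy, or to abundance-driven detection
thresholds. The generators make no attempt at read-level realism, and real
occurrence matrices have margin structure (e.g. sequencing-depth artifacts)
richer than a two-factor product.

## Numerical and degenerate-input choices

* Margin fit: Newton steps clipped to offsets $|\alpha|, |\beta| \le 35$;
  non-convergence raises an error reporting the worst relative residual.
* Calibration bins: quantile bins on $\log(n_i n_j + 1)$; undersized or
  zero-variance bins merge leftward (leftmost merges right); if a single
  degenerate bin remains, calibration fails loudly rather than emitting
  meaningless Z-values.
* Cutoff: the $(m{+}1)$-th largest null Z where $m = \lfloor \mathrm{FPR}
  \cdot K \rfloor$; significance is *strict* exceedance.
* Merges require at least one shared sample; pairs of nodes sharing a taxon
  are never eligible (their supports are disjoint by construction, so the
  guard is belt-and-braces).
* Empty-presence residuals are dropped; a clustering run with no eligible
  pairs returns an all-singleton network, which is a valid result, not an
  error.
* Assemblages containing a genus without a pathway profile or distance
  entry are skipped with a warning wherever summaries are needed, mirroring
  how unannotatable assemblages are ignored rather than imputed.

## Problem sizes used in the validation suite

The package's own validation runs at what a desk check can afford while
keeping every printed pipeline constant at its default: the
false-positive-rate check uses a 200-genus × 300-sample matrix, a
200-matrix calibration ensemble and 100 fresh matrices (≈ 2 × 10⁶ pair
evaluations); the planted-recovery and null-specificity checks use
100-genus × 300-sample matrices, 100-matrix calibration ensembles and
100-run clustering ensembles; classification recovery uses 1000 random
assemblages per terminal; the type-I calibration of the redundancy report
uses 200 simulated datasets. Calibration-ensemble sizes below the 1000-
matrix default trade Monte-Carlo resolution of the cutoff for runtime; the
FPR guarantee is checked empirically at the sizes used.

## Known limitations

* The Z-bin statistics are frozen at the initial calibration; late-stage
  merged nodes with unusual cosmopolitanism inherit the nearest bin's
  moments rather than a bespoke null.
* Support thresholds (10, 70) are counted over all runs of all
  environments; for assemblages reachable in several environments the
  consensus threshold is therefore global, and per-environment support is
  not separately enforced.
* Rejection sampling for heavily constrained random assemblages can be
  infeasible for outlying reference assemblages; those assemblages are
  skipped and reported, so downstream statistics describe the feasible
  subset.
* The method is strictly presence/absence; no compositional or
  abundance-based correction is attempted.
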