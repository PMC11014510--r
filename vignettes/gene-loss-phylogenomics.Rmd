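---
title: "Dollo parsimony analysis of gene presence/absence data"
author: "dolloloss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dollo parsimony analysis of gene presence/absence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dolloloss)
```

## The problem

Comparative genome annotation pipelines such as TOGA classify, for every
gene of a reference genome, whether an ortholog in a query genome is
intact, lost, or something in between. Coding those calls as a binary
species-by-gene matrix (1 = present, 0 = lost) turns gene loss into a
discrete phylogenetic character: a gene can be lost independently in
different lineages, but once a gene has pseudogenized it does not
re-evolve. That irreversibility is exactly the Dollo assumption — a
character may be gained once (0 → 1) and lost arbitrarily often
(1 → 0), never regained — and the Dollo parsimony score of a tree is the
minimum number of 1 → 0 losses needed to explain the observed states.

`dolloloss` implements the full downstream analysis of such a matrix:

1. parsing and conservative binary coding of TOGA loss summaries,
2. exploratory clustering (is there phylogenetic signal at all?),
3. most-parsimonious tree inference under the Dollo criterion with
   bootstrap support,
4. branch tests with a parsimony variant of the Shimodaira–Hasegawa test,
5. ancestral loss reconstruction on a fixed species tree with a
   branch-length regression and outlier flagging, and
6. hypergeometric over-representation analysis of the lost genes.

Because the real inputs are large external downloads, the package ships a
seeded simulator whose output has the same statistical structure and full
ground truth; every stage is validated against it.

## The Dollo engine

For a rooted tree and a binary character the minimum-loss explanation has
a closed combinatorial form. With the gene enforced present at the root
(the right model when the reference species is an outgroup to the clade,
so every annotated gene existed in its common ancestor), the optimal
losses sit exactly on the *maximal clades whose observed leaves are all
absent*: nested all-absent clades are explained by their outermost branch,
and clades containing only unknown states (`?`) stay present, contributing
nothing. With a free gain, the gain sits on the branch above the most
recent common ancestor of the present leaves and the same counting applies
strictly inside that subtree. `dollo_fit()` evaluates this rule; the test
suite proves it equal to brute-force enumeration over all single-gain /
any-loss placements on hundreds of random trees and characters, including
missing data.

Two consequences deserve emphasis:

* **All-absent genes.** Under a forced-present root a gene absent from
  every species costs one loss per root child. Such genes are
  reference-private artifacts (annotated in the reference but absent from
  the whole study clade), so `reconstruct_losses()` tallies them but also
  reports them separately.
* **Polytomies are hard.** Multifurcations are scored by direct counting
  on the multifurcating tree, not as a minimum over resolutions —
  matching classic discrete-parsimony program behaviour and keeping the
  branch-collapse scan cheap.

Scoring a matrix collapses identical gene columns into weighted unique
patterns first, so cost scales with the number of distinct patterns
(a few thousand for a 17-species, 20000-gene matrix) rather than genes.

## Exact search and a corrected lower bound

`branch_and_bound()` enumerates rooted binary topologies by stepwise taxon
addition and prunes partial trees against an incumbent from greedy
addition. The textbook bound — a character's score on an induced subtree
never exceeds its score on the full tree — is *not* valid here in
root-present mode: a character with no present leaf in the current taxon
subset is all-absent on the partial tree and costs one loss per root
child, which can exceed its full-tree cost once the present witness taxon
is added. The package therefore bounds a partial tree by the Dollo score
of the subset-present characters (for which the restriction argument is
sound) plus a topology-independent floor for the rest: 2 for characters
absent in every species, 1 for characters with any observed absence, 0
otherwise. With this bound the search is provably exhaustive-equivalent,
and the tests confirm score *and* full co-optimal tree sets against
unpruned enumeration on random instances. Taxa are added in decreasing
order of their effect on the greedy tree's score, which tightens the
bound early.

Beyond ~12 taxa, `heuristic_search()` uses seeded random-addition starts
refined by nearest-neighbour-interchange hill climbing; on instances where
exact search is feasible it attains the optimum in effectively every run
with 10 starts. `bootstrap_consensus()` resamples gene columns with
replacement (the character analogue of sequence bootstrapping), reruns the
configured search, and assembles a strict-majority consensus from clade
frequencies. Columns are resampled in a canonical pattern-sorted order, so
supports are invariant to the order genes happen to appear in the matrix.

## Branch tests

`branch_sh_scan()` collapses each internal branch of the MP tree to a
polytomy and asks whether the collapsed tree is significantly worse, using
the per-gene score differences `d_i`:

* **Templeton (winning-sites)**: a two-sided Wilcoxon signed-rank test on
  the nonzero `d_i`, with exact sign-assignment enumeration up to 12
  informative genes and a tie-robust normal approximation beyond
  (variance `sum(r_i^2)/4`, which is exact for randomly signed tied
  ranks). Under exchangeable-null differences its 5% rejection rate is
  calibrated to within the acceptance band.
* **RELL**: gene contributions are resampled with replacement, sums are
  centered at their expectation (the SH convention — the uncentered
  variant is the KH convention; centering is the conservative headline
  choice), and the one-sided p is add-one smoothed so it is never exactly
  zero. Reported "p < 0.0001" therefore means "worse than every one of
  10000 resamples".

Collapsing a branch can only raise the Dollo score (refinement
monotonicity, asserted in tests), so all deltas are nonnegative. When the
root is bifurcating, its two child branches describe the same bipartition;
that split is tested once, using the better-scoring of the two collapses.

## Ancestral losses and the branch regression

`reconstruct_losses()` fixes the species tree (with any unresolved nodes,
e.g. the Paenungulata polytomy, left as hard polytomies), reconstructs
each gene's losses under the root-present Dollo rule, and tallies per
branch. The total always equals the matrix's tree score (conservation,
asserted on every fixture), the reconstruction never infers more events
than the simulated truth, and it is exact for genes lost at most once.

`branch_regression()` regresses per-branch loss counts on branch lengths
in millions of years: Pearson correlation, two-sided t test on n − 2
degrees of freedom, ordinary least squares, and outlier flagging at
|standardized residual| > 2. The threshold is a reporting convention, not
a hypothesis test, and is exposed as a parameter; terminal branches are
included by default (species-specific bursts are often assembly artifacts
and are worth seeing), with exclusion available. On simulations with a 5×
loss burst on one stem branch the burst branch is flagged as the sole
outlier in ≥ 95% of seeded replicates.

## Over-representation analysis

`ora()` restricts each gene set to the background universe, size-filters
on the restricted size `K` (defaults 10–200, sized for large foregrounds),
computes the hypergeometric upper tail in log space (log-sum-exp over
`lchoose` terms; agreement with exact rational arithmetic to 1e-12
relative error is part of the acceptance suite), and applies
Benjamini–Hochberg control. Blacklist patterns can be applied to both
foreground and background before testing so the universe size matches the
tested genes. The default significance filter is FDR q ≤ 0.10.

`ap_reduce()` de-redundantizes significant terms by affinity propagation
on the Jaccard similarity of set memberships. Preferences default to the
median off-diagonal similarity, nudged up by 1e-6 so exact ties between
"join a cluster" and "be an exemplar" resolve toward more exemplars
(two disjoint sets then yield two exemplars, as they should), and a tiny
deterministic jitter breaks symmetric ties, as is standard for this
algorithm. Damping defaults to 0.9.

## Exploratory clustering

`fuzzy_cluster()` implements the distance-based fuzzy criterion of
Kaufman & Rousseeuw (the `fanny` objective)
`sum_v (sum_ij u_iv^m u_jv^m d_ij) / (2 sum_j u_jv^m)` with alternating
membership updates. Two numerical choices matter. First, the closed-form
update is not guaranteed monotone for every fuzzifier, so a step-halving
safeguard backs off toward the previous memberships until the objective
does not increase — the per-iteration trace is asserted non-increasing in
the tests. Second, the criterion has local optima: the default runs five
starts, the first initialized from a k-means partition of the classical
MDS embedding and the rest random, keeping the best final objective.
The fuzzifier default is m = 1.2: the update degenerates to hard
assignment as m → 1 (a genuinely fuzzy m must exceed 1), and values near
1 keep memberships crisp enough to compare with hard partitions while
still quantifying uncertainty. `fuzzy_cluster()` rejects m ≤ 1 with a
pointer to k-means.

Ordination uses classical (Torgerson) metric MDS — deterministic and
exactly invertible on Euclidean input, which gives the tests a sharp
oracle — rather than a stress-minimizing variant; `reduce_and_partition()`
then applies seeded multi-start k-means (10 restarts, best within-cluster
sum of squares, ties to the lowest restart index). `cluster_diagnostics()`
reports the within-cluster sum of squares per K (the elbow rule) and the
adjusted Rand index between successive-K partitions as a scalar stability
summary standing in for a full cluster-flow visualization.

## The simulator and what passing tests do (and do not) show

`simulate_losses()` draws, per gene and per branch in root-to-tip order, a
loss with probability `1 − exp(−rate · multiplier · length)` conditional
on presence at the parent; a loss terminates the gene in that subtree, but
independent losses in disjoint subtrees (homoplasy) remain possible and
are what makes reconstruction and tree search non-trivial. Defaults are
calibrated to the study conditions: a 17-species Atlantogenata-shaped tree
with synthetic branch lengths scaled to plausible divergence times, 20000
genes, base rate 0.002 losses/gene/My (≈ 16–25% of genes lost per species
along ≈ 90 My root-to-tip paths, comparable to genome-wide loss-call
counts), and a 5× burst on the Afrotherian stem. The clustering fixture
(`clade_structured_config()`) instead multiplies the four major clade
stems by 5 so shared derived losses dominate species-private noise.

The simulator emulates irreversible loss with branch-specific rates and
rate bursts, and set fixtures with designated enriched categories. It does
**not** emulate correlated annotation errors, assembly-quality gradients
between genomes, lineage-biased ascertainment of the reference gene set,
or gene-family structure (duplications masking losses). Passing the
recovery tests therefore shows the machinery is correct and well
calibrated under the stated generative model — not that real TOGA calls
are free of systematic error. The analysis itself contains the tools for
that question (clustering artifacts, regression outliers on terminal
branches, SH-discordant placements), which is how the workflow narrates
its results.

Problem sizes in the shipped tests and acceptance script (matrices of
2000–20000 genes, 25–100 simulation replicates, 100 bootstrap replicates,
2000 null draws) were chosen to estimate each reported rate with a
standard error comfortably inside its acceptance band.

## Degenerate inputs and tie-breaking

* Missing states (`?`) resolve to whichever assignment minimizes losses;
  all-`?` characters contribute zero.
* All-absent characters cost one loss per root child in root-present mode
  and zero under free gain (the gene simply never arises).
* Co-optimal trees are all retained; the headline tree is the first by
  canonical topology sort (children ordered by smallest leaf label).
* Identical points in ordination space are partitioned exactly (k-means
  would refuse to seed); a fully degenerate distance matrix yields a
  single zero axis.
* Constant loss counts give r = 0, p = 1 by convention; a perfect linear
  fit gives r² = 1 with no outliers (zero residual variance is treated as
  "no outliers", not division by zero).
* PHYLIP export truncates names to 10 characters and refuses colliding
  truncations rather than silently renaming.

## Known limitations

* Exact search is limited to ~12 taxa by design; the heuristic carries no
  optimality guarantee beyond its empirical hit rate.
* The SH scan tests branches pairwise against the MP tree; a joint
  max-statistic correction across all collapsed alternatives is not the
  default report.
* Branch lengths for the regression are taken as given (a dated tree is
  an input, not an inference); the packaged lengths are synthetic and
  labeled as such.
* Non-metric MDS is out of scope; ordination is classical metric MDS.
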