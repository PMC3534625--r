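---
title: "Reconstructing gene-content evolution: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing gene-content evolution: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogevo)
```

This vignette is the package's own account of its methods: the gain/loss
model and its assumptions, the numerical choices behind the fitting
machinery, what the synthetic-data generator does and does not emulate,
and the design decisions that were genuinely open.

## The gain/loss model

A gene family's history on a rooted species tree is modelled as a
two-state Markov chain over {absent, present}. Every node, the root
included, owns the branch connecting it to its parent; the root's branch
descends from an implicit *origin* whose state is fixed absent. On branch
$b$ the transition matrix is

$$
T_b = \begin{pmatrix} 1-g_b & g_b \\ l_b & 1-l_b \end{pmatrix},
$$

rows indexed by the parent state. Fixing the origin absent means presence
anywhere must be explained by at least one gain, and a gain in the last
common ancestor is an ordinary event on the root's branch — so the tree
has exactly as many branches as nodes ($2n-1$ for a bifurcating tree with
$n$ leaves), and "ancestral content at the root" and "gains at the root"
are two readings of the same branch posterior.

Rate heterogeneity across families uses a two-point mixture: category $c$
rescales branch intensities, $g_b^{(c)} = 1 - e^{-m_c \gamma_b}$ with
$\gamma_b = -\log(1-g_b)$ and $m_1 \equiv 1$, likewise for losses. This
is one reading of a "two-category model" — the categories could instead
scale only losses; we scale both because family-level rate variation
(mobile elements versus core machinery) plausibly affects both processes,
and the choice is confined to one helper so a loss-only variant is a
small change.

Branch parameters are free probabilities, not rate-by-length products:
the guide tree's branch lengths are metadata here, since trees inferred
from sequence divergence need not predict gene-content flux per branch.

**Observability.** A family absent from every genome cannot appear in the
matrix, so by default every family likelihood is conditioned:
$L(x)/(1 - L(\varnothing))$. Without this correction, fitting data that
was filtered to non-empty patterns systematically inflates presence
probabilities near the root. The flag is exposed
(`condition_on_observed`) and recorded with every fit.

Assumptions worth stating plainly: families evolve independently;
paralogs are collapsed to binary presence (no copy-number or duplication
model); transfers are represented only as independent gains — donors are
not modelled, and the direction of an exchange is not inferable from
phyletic patterns alone.

## Likelihood, posteriors, and the oracle

The per-family likelihood is computed by the pruning algorithm over the
two states; the outward ("up") pass then yields, on every branch, the
joint posterior of the parent and child states, from which
$P(\text{gain}) = P(\text{parent}=0, \text{child}=1 \mid x)$ and the loss
analogue are read off, and node presence posteriors follow by
marginalization. Category posteriors come from Bayes' rule on the
per-category likelihoods, and event posteriors are mixed with those
weights. Per-node rescaling keeps the pass stable; sibling products are
assembled with prefix/suffix products rather than division, so
deterministic branches (probabilities at the clipping bounds) cannot
produce 0/0.

`brute_force_posteriors()` implements the identical contract by summing
over every complete ancestral state assignment (refusing trees above 14
nodes). It shares no code path with the up-down pass and serves as the
test oracle: on 200 random (tree ≤ 6 leaves, model, pattern) triples the
two agree to well below $10^{-10}$.

## Fitting: truncated EM plus analytic-gradient L-BFGS

The model has $2B + 2$ free parameters ($B$ branches). Two findings from
this package's development shaped the optimizer:

* **Initialization matters.** Starting branch gains at the presence
  frequency of the clade below each branch — a natural-looking choice —
  parks the optimizer in a "gains everywhere" basin whose likelihood is
  tens of units below the optimum on benchmark data. The default start is
  therefore sparse: secondary gains 0.02, root gain 0.5, losses 0.3.
* **The surface has a flat ridge.** Data generated with a high root gain
  and subsequent losses can be nearly as well explained by slightly less
  root presence and slightly more secondary gain. Along this ridge plain
  EM crawls and numerically-differentiated quasi-Newton stalls; both stop
  "converged" at materially different ancestral sizes.

The fitter therefore runs monotone EM as a warm-up and finishes with
L-BFGS using *analytic* gradients. The E-step (one up-down pass per
category) produces expected per-branch gains, losses and parent-state
occupancies; by the expected-score identity these same statistics are the
exact gradient of the observed-data log-likelihood, so each L-BFGS
iteration costs one E-pass. Conditioning on observability is handled as
truncated-data EM: each iteration augments the sample with
$n P_\varnothing / (1 - P_\varnothing)$ fractional families carrying the
all-absent pattern, which also makes the gradient of the conditioning
term come out for free. The convergence tolerance is deliberately tight
($10^{-8}$ log-likelihood units per family): on the ridge, the last few
hundredths of a unit move ancestral-size estimates by percents.
Parameters are optimized as log-intensities (logit for $w_2$) and clipped
to $[10^{-6}, 1-10^{-6}]$; identical phyletic patterns are collapsed with
weights, so cost scales with distinct patterns, not families.

Degenerate inputs: an all-ubiquitous matrix fits (with a warning) but
drives losses to the lower clip; the root branch's loss parameter is
never identifiable (its parent is always absent) and simply retains its
value; fits with fewer than 50 families warn that branch-specific rates
will be noisy.

## Ortholog clustering

Clustering follows the classical COG construction: genome-wise best hits
(score ties broken toward the lexicographically smaller subject id, for
determinism), symmetric best-hit pairs, triangles spanning three distinct
genomes, and transitive merging of triangles that share an *edge* —
vertex-sharing merges would chain promiscuous genes into superclusters.
Components of the triangle-overlap graph can still share a vertex; to
keep clusters disjoint, a gene claimed by several components is assigned
to the one where it participates in most triangles (ties to the lowest
cluster id). Two triangles sharing only a vertex therefore still yield
two clusters.

Cluster merging by complementary phyletic patterns uses two gates: shared
genomes as a fraction of the smaller cluster's genome set at most
`overlap_max` (default 0.2), and mean cross-cluster best-hit score at
least `link_score_min` (default: the 90th percentile of non-best-hit
scores, i.e. the background similarity level). Both defaults are
conventions, not estimates — "approximately complementary" and "high
similarity" are qualitative notions — and both are exposed.

A caveat established empirically: exact recovery of planted groups is
only guaranteed when each group has a member in every genome. A
background gene in a genome a group does not cover can become the mutual
best hit of two group members and join the cluster through a mixed
triangle. This is correct behaviour of the stated algorithm, not a bug;
the tests assert exactness for full-span groups and group-cohesion (all
members end up together) for partial-span groups.

## Commonality decomposition

The commonality histogram counts families present in exactly $k$ genomes.
It is decomposed into $\sum_i a_i e^{b_i k}$ by minimizing the Poisson
deviance — counts are counts, and least squares on log-counts breaks on
zero bins. Exponents are bounded to $|b| \le 2$ (decay steeper than
$e^2$-fold per genome is not identifiable from integer $k$), components
are reported ordered by exponent, and the cloud/shell/core labels attach
in that order. Optimization is multistart (default 20 seeded starts)
L-BFGS from log-linear fits anchored on contiguous thirds of the support;
component sizes are the sums $S_i = \sum_{k=1}^G a_i e^{b_i k}$, reported
exactly and at the two-significant-figure convention. Whether the
original decomposition used this objective is unknown; Poisson deviance
on the raw $k$ grid is this package's documented choice.

## Gain patterns and exchange statistics

A branch enters a family's gain pattern when its gain posterior strictly
exceeds 0.5; families are zero-, single- or multi-gain by the size of
that set, while "multi-gain" in the branch-correlation statistics is
decided on the *posterior sum* exceeding 1.5, not the thresholded count —
thresholds are strict everywhere (0.5, 0.9, 1.5). The gains-per-family
histogram gets an exponential decay fitted by least squares on log counts
over non-zero bins ≥ 1, plus a Gaussian-kernel density (Silverman's
bandwidth) of the posterior totals.

The two-gain analysis takes families with exactly two likely gains not
involving the root branch, and compares observed unordered pair counts to
a null where pair $(i,j)$ is proportional to the product of the branches'
total gains, normalized so expected counts sum to the observed family
count $N_2$ — the proportionality is inherent to the null, the
normalization is this package's choice and p-values depend on it.
Pair-level surprise uses exact upper-tail Poisson probabilities
(regularized gamma, not a normal approximation); raw p-values are
reported with a Benjamini–Hochberg column alongside, uncorrected values
being the convention for this analysis. Spearman correlations use average
ranks with the large-sample t approximation for p-values (adequate at
hundreds of branches).

## The synthetic generator and the recovery benchmark

`simulate_presence()` runs the generative process forward (category draw,
then state propagation from the absent origin), recording true states and
events per branch — leaf rows reproduce the emitted matrix exactly, and
every recorded gain has parent 0 and child 1. Conditioning on
observability uses rejection with logged rejection counts, which the
observability-bias tests reuse. Hit-table simulation plants ortholog
groups whose cross-genome scores come from a floored Gaussian
(`pmax(min_high, N(mu, sd))`) over a capped-exponential background, so
`min_high > bg_cap` gives provably disjoint supports. Commonality
histograms draw each bin from its Poisson mean independently.

The recovery benchmark (`recovery_benchmark()`) fixes the study
conditions for the simulate-and-refit experiment: a balanced 16-leaf
tree; root gain 0.7; secondary gains cycling 0.001/0.002/0.004; losses
depth-structured — 0.05 on internal branches, 0.155/0.205/0.255 on
terminal branches; mixture $w_2 = 0.3$, $m_2 = 2$. The loss levels were
calibrated once, at 40,000 simulated families, so the expected loss/gain
event ratio of observable families is 4.0 — the canonical four-fold
excess of losses over gains — and then frozen. The depth structure is
deliberate: an earlier design with uniformly heavy losses also met the
ratio but left root presence statistically unidentified (the maximum
likelihood estimate sat 19% from the simulated truth even when the
optimizer was started at the generating parameters, because heavy deep
losses let secondary-gain explanations mimic the data). Concentrating
loss near the tips keeps deep transmission reliable, so root content is
strongly identified while the event ratio stays at 4. At 5,000 families
the refit recovers the event-total ratio within a few percent and the
root's expected size within ~2–4% across seeds.

Problem sizes used throughout the tests — 200 oracle triples on trees of
up to 6 leaves, 5,000 families for recovery, 50 planted groups over 10
genomes, $G = 50$ commonality bins — are the package's chosen working
points: large enough for stable stochastic assertions, small enough to
rerun casually.

## What passing tests do and do not show

The generator emulates the model's own assumptions, so recovery tests
certify the estimation machinery, not the model's fit to real genomes.
Real data violate independence across families (operons travel together),
contain annotation noise in the input matrix, and have gene exchange with
direction and donors — none of which the two-state process represents.
Tree errors are likewise out of scope: the topology is taken as given,
and nothing here tests robustness to a misplaced clade. The pipeline also
deliberately stops short of sequence space: no alignment, no profile
searches, no tree inference — the similarity table and the guide tree are
inputs.
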