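---
title: "Penalized least-squares complex detection: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Penalized least-squares complex detection: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsmc)
```

## The model

A PPI network is an undirected simple graph over proteins. The premise of
the method is minimal: proteins in a common complex are likely to
interact, and conversely an interaction supported by many shared partners
is more trustworthy than an isolated one. Both halves enter the model
separately.

**Interaction weights.** Raw edges are replaced by neighborhood-overlap
weights. With $N(i)$ the closed neighborhood of protein $i$ (the protein
and its interaction partners),

$$S_{ij} = \frac{|N(i) \cap N(j)|}{|N(i)|\,|N(j)|} \quad \text{if } i \sim j,
\qquad S_{ij} = 0 \text{ otherwise.}$$

Both endpoints of an edge belong to both closed neighborhoods, so
$S_{ij} > 0$ exactly on the edge set. The denominator is also offered as
the geometric mean $\sqrt{|N(i)||N(j)|}$ (`variant = "geometric"`), which
normalizes the weight into $(0, 1]$; the literature that introduced this
weighting admits either reading, and the two variants only change the
scale that $\lambda$ and $\tau$ live on. The product form is the default.

**Propensities.** Protein $i$ carries a nonnegative propensity
$\theta_{iz}$ for each of $K$ candidate complexes. The cocomplex
coefficient $C_{ij} = \sum_z \theta_{iz}\theta_{jz}$ is fitted to
$S_{ij}$:

$$\min_{\Theta \ge 0}\; L(\Theta) = \sum_{i,j} \tfrac12\left(\sum_z
\theta_{iz}\theta_{jz} - S_{ij}\right)^2 + \lambda \sum_{i,z}
\theta_{iz}^2 .$$

This is a symmetric nonnegative matrix factorization of $S$ with a ridge
penalty. Without the penalty a protein can accumulate many large
propensities and be assigned to many complexes; $\lambda$ controls the
overlap rate.

The first sum runs over all *ordered* pairs including $i = j$. That
convention is what makes the gradient
$\partial L/\partial\theta_{ik} = 2(\Theta\Theta^\top\Theta - S\Theta +
\lambda\Theta)_{ik}$ exact, and it has a visible consequence: because
$S_{ii} = 0$, the diagonal terms $\tfrac12(\sum_z \theta_{iz}^2)^2$ act as
an extra, implicit shrinkage. On a 3-clique with unit geometric weights
the fitted off-diagonal $C_{ij}$ converges to $\approx 2/3$, not $1$ —
membership thresholding is unaffected (the propensities are still
$\approx 0.8$), but reconstruction residuals should not be expected to
vanish. The unit tests assert exactly this biased value rather than a
perfect fit.

## The optimizer

The constrained problem is solved with a multiplicative update applied to
all entries simultaneously:

$$\theta_{ik} \leftarrow \frac{\theta_{ik}}{2} + \frac{\theta_{ik}}{2}
\cdot \frac{(S\Theta)_{ik}}{(\Theta\Theta^\top\Theta)_{ik} +
\lambda\theta_{ik} + \epsilon}.$$

The averaged form is a gradient step with an adaptive, entrywise step
length: it preserves nonnegativity, leaves exact zeros at zero (zero is a
fixed point, which is why initialization is strictly positive), and never
increases $L$. At a fixed point the complementary-slackness condition
$\theta_{ik}\,\partial L/\partial\theta_{ik} = 0$ holds, so the iterate
approaches a KKT point of the constrained problem. The test suite checks
monotonicity on every trajectory, agreement of the vectorized update with
a naive loop transcription to $10^{-10}$, the analytic gradient against
central finite differences, and a relative KKT residual below
$10^{-4}(1 + L)$ after convergence at tight tolerance.

Numerical details, all chosen once:

* **Stopping.** $|L_t - L_{t-1}|/(1 + L_{t-1}) < 10^{-6}$ (relative
  change), capped at 1000 iterations. Stationarity diagnostics use the
  tighter $10^{-9}$/5000 so the KKT property is actually exhibited.
* **Guard.** $\epsilon = 10^{-12}$ in the denominator protects columns
  that have decayed to zero; it is orders of magnitude below any
  propensity of interest.
* **Initialization.** Entries uniform on $(0, s]$ with
  $s = \sqrt{\overline{S}/K}$, which puts the initial $\Theta\Theta^\top$
  on the scale of $S$; a floor of $10^{-3}$ covers edgeless inputs.
* **Restarts.** The objective is non-convex, so the optimizer restarts
  from independent random initializations (library default 100, the
  standard protocol; the command line defaults to a desk-friendly 10) and
  keeps the smallest final $L$, ties to the lowest restart index. Each
  restart's seed is derived arithmetically from `(seed, restart index)`,
  so results are reproducible and independent of execution order.

## From propensities to complexes

Protein $i$ joins complex $k$ when $\theta_{ik} \ge \tau$ (default
$\tau = 0.2$; the customary scan is $0.05$–$0.5$ in steps of $0.05$).
Empty columns are dropped, exact duplicates collapse to one, and
complexes with fewer than 3 proteins are removed — the same size rule is
applied to gold standards before evaluation. $\tau$ is a single global
threshold; near-duplicate (highly overlapping but not identical)
complexes are *not* merged, because no principled merge rule is part of
the model. Overlap between complexes is permitted by construction.

$K$ is the one structural parameter the model cannot infer: the default
rule $K = \lceil n/3 \rceil$ per subnetwork is the loosest bound
consistent with the size rule (no more than $n/3$ disjoint complexes of
size $\ge 3$ fit among $n$ proteins). Superfluous columns shrink to zero
under the penalty and are discarded by thresholding, so overestimating
$K$ is cheap; underestimating it forces complexes to share columns.

## Decomposition

Estimating $\Theta$ directly on a genome-scale network is prohibitively
expensive ($O(N^2K)$ per iteration), so the network is recursively split
by greedy agglomerative modularity maximization (Clauset–Newman–Moore,
via igraph) until every part has at most $N_s = 200$ proteins — a cap
consistent with the largest curated yeast complexes. Choices worth
stating:

* Clustering runs on the **unweighted** graph; weights are computed per
  subnetwork afterwards, from the subnetwork's own topology.
* Connected components are separated before clustering.
* The dendrogram is cut at its modularity maximum by the package itself:
  igraph's `membership()` can return a worse cut when the maximum is
  numerically indistinguishable from zero (e.g. complete graphs), and a
  complete graph must *not* be split.
* A part that greedy modularity refuses to split (a single community) is
  processed whole, with a warning, even above $N_s$; forced bisection
  would invent structure.
* Cross-subnetwork edges are discarded, so complexes spanning subnetworks
  are undetectable. This is inherent to the speed-up, not a bug to fix;
  with the default $N_s$ it affects only networks larger than 200
  proteins.

## Evaluation metrics

For predictions $P$ and gold standard $B$: the overlap score
$os(p,b) = |p \cap b|^2/(|p||b|)$; f-measure at matching threshold
$ov = 0.25$ (match when $os \ge ov$ — the inclusive comparison is the
conventional one, a `strict` switch is provided); protein-level Sn and
PPV from the confusion matrix $T_{ij}$, combined as
$\mathrm{Acc} = \sqrt{\mathrm{Sn}\cdot\mathrm{PPV}}$ (the geometric mean,
as defined by the metric's originators; `accVariant = "product"` gives
the plain product); the maximum matching ratio
$\mathrm{MMR} = |B|^{-1}\sum_i \max_j os(p_j, b_i)$; and the composite
score f-measure + Acc + MMR used for model selection. "Perfect matching"
is exact set equality — the only way $os = 1$ can occur. Empty
prediction sets evaluate to zeros with a warning; an empty reference set
is an error. Every metric is cross-checked in the tests against an
independent brute-force recomputation on random instances.

`paramGrid()` implements the selection protocol: per $\lambda$ in
$\{2^{-5},\dots,2^5\}$ fit once with restarts, then scan $\tau$ over
$0.05$–$0.5$ and keep the composite-maximizing pair. The library default
$\lambda = 1$ is the center of that grid, a neutral starting point; on
sparse weight matrices (where $S_{ij}$ is on the order of one over the
complex size) the fit term cannot support $\lambda$ near 1 and grid
selection lands on small values. When no gold standard exists, users
should scan $\lambda$ downwards until predictions appear and inspect
stability.

## The synthetic generator

`simulateComplexNetwork()` is a planted-partition (stochastic block)
construction: proteins are allocated to complexes (optionally reusing
proteins from earlier complexes with probability `overlapProb`), every
co-complex pair is wired with probability `pIn`, every other pair with
`pOut`, and `nBackground` proteins belong to no complex. The defaults —
10 complexes of 5–10 proteins, `pIn = 0.9`, `pOut = 0.005`, no overlap,
no background — give compact dense modules of the size range typical of
curated catalogues inside weak noise, which is precisely the density
premise the model is built on.

What it does **not** emulate: the heavy-tailed degree distributions of
real PPI networks, the spoke/matrix artifacts and systematic false
negatives of AP-MS screens, correlated noise around sticky proteins, and
complexes embedded in dense non-complex neighborhoods. Passing the
planted-complex tests therefore shows the estimator recovers the
structure its own model class generates — a necessary internal
consistency check — and says nothing about performance on a specific
experimental network, which additionally depends on how well the density
premise holds there.

Problem sizes in the tests and the acceptance script (planted benchmarks
of ~75 proteins, oracle instances with $N \le 30$, 10 restarts, 5
generator seeds) were chosen as the smallest instances that exercise
every code path and leave the stochastic checks comfortable margins.

## Known limitations

* Complexes spanning decomposition boundaries cannot be found.
* $\lambda$ and $\tau$ selection requires a gold standard; without one
  the defaults are heuristics.
* The $K = \lceil n/3 \rceil$ rule wastes columns on large sparse
  subnetworks (harmless but slower than a tuned $K$).
* Exact-duplicate predictions are collapsed, near-duplicates are kept.
* The objective's diagonal terms bias reconstruction downward (see
  above); $\tau$ should be chosen on propensities, not on reconstructed
  weights.
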