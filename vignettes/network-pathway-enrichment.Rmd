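---
title: "Topology-based pathway enrichment: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-based pathway enrichment: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netenrich)
```

## The model and its assumptions

netenrich tests pathways for coordinated differential behavior between
two conditions while accounting for the interaction structure among the
measured genes (or proteins, or metabolites). Expression of the $p$
genes in a sample from condition $k$ is modeled as

$$ y = \Lambda_k \beta_k + \Lambda_k \gamma + \varepsilon, \qquad
   \gamma \sim N(0, \sigma^2_g I), \quad
   \varepsilon \sim N(0, \sigma^2_\varepsilon I), $$

where $\Lambda_k = (I - A_k)^{-1}$ is the influence matrix of the
condition-specific weighted adjacency $A_k$. $\beta_k$ is the vector of
baseline gene effects, and the influence matrix propagates both these
effects and the shared random effect $\gamma$ along network paths, so
the implied covariance is
$\Sigma_k = \sigma^2_g \Lambda_k \Lambda_k^\top + \sigma^2_\varepsilon I$.
The assumptions worth keeping in mind:

* Gaussian errors with homoscedastic variance components shared across
  conditions. We estimate one $(\sigma^2_g, \sigma^2_\varepsilon)$ pair
  jointly from all conditions; per-condition components would double the
  parameter count for little gain at typical sample sizes, and the joint
  method-of-moments objective identifies the shared pair cleanly.
* The interaction knowledge is a support constraint, not truth: weights
  on known edges are re-estimated from the data per condition, and a
  finite non-edge penalty (`nonedge_penalty`) lets strong data-supported
  edges enter even when the knowledge base missed them.
* $I - A_k$ must be invertible. We verify this (reciprocal condition
  number $> 10^{-12}$, residual $\|(I-A_k)\Lambda_k - I\|_\infty \le
  10^{-8}$) rather than rescaling estimates, so a genuinely degenerate
  fit errors instead of silently shrinking.

For pathway indicator $b$ the hypothesis is that the propagated mean
$b^\top \Lambda_k \beta_k$ is equal across the two contrasted
conditions. The statistic applies the contrast
$\ell = (-b^\top\Lambda_1, \, b^\top\Lambda_2)$ to the stacked
generalized-least-squares means $\hat\beta_k = \Lambda_k^{-1}\bar y_k$:

$$ T_b = \frac{\ell \hat\beta}{\sqrt{\ell C \ell^\top}}, \qquad
   \mathrm{Cov}(\hat\beta_k) = \Lambda_k^{-1} \Sigma_k
   \Lambda_k^{-\top} / n_k, $$

so that $\ell C \ell^\top = \sum_k b^\top \Sigma_k b / n_k$ — the exact
quadratic-form value of the defining expression, which is how the code
computes it.

## Parameters that matter

| Parameter | Default | Units / range | Why this default |
|---|---|---|---|
| `max_size` | 1000 genes | component size | components above this are split; gene-scale knowledge bases produce one giant component, and ~1000 keeps dense-matrix algebra cheap |
| `penalty` | `"auto"` = $c\sqrt{\log p / n}$ | lasso scale | the usual neighborhood-selection rate; deterministic, no cross-validation randomness |
| `nonedge_penalty` | `Inf` | penalty factor | with curated edges, discovery off; set finite (e.g. 1) to admit missing edges |
| `estimator` | `"rehe"` | — | closed-form method of moments; orders of magnitude cheaper than REML with near-identical estimates (tested agreement < 0.05) |
| `fdr` | 0.05 | level | conventional FDR cut-off used throughout the power design |
| `scale` | `TRUE` | — | genes standardized within condition before adjacency estimation, matching the simulation protocol's standardization |

## Variance-component estimation

**REHE** minimizes
$\sum_k (n_k-1)\,\| S_k - \sigma^2_g \Lambda_k\Lambda_k^\top -
\sigma^2_\varepsilon I \|_F^2$
over the nonnegative quadrant, where $S_k$ is the within-condition
sample covariance (equivalently the covariance of residuals
$y - \Lambda_k\hat\beta_k$, since $\Lambda_k\hat\beta_k = \bar y_k$).
The unconstrained $2\times2$ normal equations are solved first; a
negative component triggers evaluation of both clamped boundary
solutions, and the feasible minimizer is returned. When every
$\Lambda_k\Lambda_k^\top$ is numerically proportional to $I$ only the
sum of the components is identified, and the fit errors explicitly
rather than returning an arbitrary split.

**REML** maximizes the restricted log-likelihood
$-\tfrac12 \sum_k (n_k-1)\left[\log|\Sigma_k| +
\mathrm{tr}(\Sigma_k^{-1} S_k)\right]$
by Newton iterations on $(\log\sigma^2_g, \log\sigma^2_\varepsilon)$
with analytic gradient and Hessian obtained from the eigendecomposition
of $\Lambda_k\Lambda_k^\top$ (each evaluation is then $O(p)$).
Numerical choices: REHE provides the starting point (pushed off the
boundary by $10^{-4}\times$ the covariance scale); steps that are not
ascent directions fall back to normalized gradient ascent; step halving
guarantees monotone likelihood; convergence at relative parameter
change $< 10^{-8}$ or 100 iterations, after which non-convergence is an
error reporting the last iterate and gradient norm. The tests verify
agreement with a derivative-free Nelder–Mead optimum to $10^{-4}$.

**Degrees of freedom.** No df formula is canonical for this plug-in
statistic. Under REHE we use the pooled two-sample default
$n_1 + n_2 - 2$; under REML a Satterthwaite-style
$\nu = 2(\ell C\ell^\top)^2 / \widehat{\mathrm{Var}}(\ell C\ell^\top)$,
with the variance from the delta method and the inverse observed
information (and clamped to $[1, n_1+n_2-2]$). The choice is validated
empirically rather than derived: under the null the pipeline's p-values
are uniform to Kolmogorov–Smirnov distance $\approx 0.02$ at 500
pathways (the suite enforces $< 0.1$).

Under `estimator = "reml"` the components are re-estimated per pathway
on the submatrices restricted to the pathway members plus their direct
network neighbors. The restriction set is a design choice — it keeps
the local topology that drives the contrast while making per-pathway
REML affordable; the whole-network alternative is available via
`reml_scope = "network"`.

## Clustering rule

Community detection uses igraph's walktrap, leading eigenvector, fast
greedy, label propagation, infomap and louvain on the undirected view
of each oversized component. Candidates whose largest cluster still
exceeds `max_size` are discarded; among survivors the smallest *edge
loss* wins. Further choices the rule needs but that are genuinely open:

* **Edge loss** is the unweighted count of distinct cross-cluster edges
  of the 0–1 adjacency (a reciprocal directed pair counts once): the
  rule operates before weights exist, so a weighted loss has nothing to
  weight by.
* **Ties** break by the fixed algorithm order listed above, making runs
  deterministic; the stochastic algorithms (label propagation, infomap,
  louvain) run under a caller-supplied seed recorded in the run log.
* **All candidates discarded:** the minimum-loss candidate is refined by
  re-clustering its oversized clusters recursively (at most 3 rounds);
  if that still fails the component is kept whole with a warning —
  a slow exact answer beats a mangled partition.
* Clustering is computed once on the condition-independent 0–1
  structure, not per condition.

Estimation then proceeds per cluster and the blocks are reassembled
with cross-cluster entries exactly zero; the influence matrix is
inverted blockwise (identical to the full inverse for a block-diagonal
$I - A$, asserted to $10^{-8}$ in the tests).

## Adjacency estimation details

Undirected: each gene is regressed on its allowed partners (OLS when
non-edges are excluded; lasso via glmnet with penalty factor 0 on known
edges otherwise), then the two directional coefficients are symmetrized
by the signed geometric mean — $w_{ij} = \mathrm{sign}\cdot\sqrt{|b_{ij}
b_{ji}|}$ when the signs agree, else 0. This is the standard
partial-correlation scaling, is symmetric by construction, and maps
sign-inconsistent (noise) pairs to zero. Directed acyclic structures
use OLS of each child on its parents; cycles are an error naming the
offending strongly connected component. Rank-deficient neighborhoods
(more neighbors than samples) resolve by pivoted QR with aliased
coefficients set to zero. Constant genes are an error naming the gene.
Isolated genes keep zero rows, contributing only through
$\sigma^2_\varepsilon$.

## What the simulator emulates — and what it does not

`generate_network()` builds components of planted Erdős–Rényi modules
(default: 150 genes, two 75-gene components, ~15-gene modules, edge
probability 0.25 within and 0.02 between modules plus a spanning chain
for connectivity), mirroring the modular, multi-component topology of
curated interaction networks. Weights are uniform on
$\pm[0.3, 0.7]$ and rescaled to spectral radius $\le 0.9$ so
$\Lambda$ always exists. `generate_expression()` samples exactly from
the latent-variable model; `standardize_and_dysregulate()` reproduces
the power protocol — per-gene standardization across *all* samples
first, then the mean signal $\mu \in \{0.2, 0.3, 0.4\}$ added to the
dysregulated genes in one condition (this order matters: the injected
signal is in post-standardization units). Dysregulated genes come from
three seedable stand-in frameworks (uniform-random, betweenness-ranked,
neighborhood-seeded), with 30% of genes dysregulated by default so that
all three non-null pathway groups — (0,5], (5,10], >10 dysregulated
members — are populated at 10–40-gene pathways.

Because the generator samples from the analysis model itself, passing
tests demonstrate internal consistency (calibration, power ordering,
estimator correctness), *not* robustness to real-data features the
model lacks: heavy tails, batch effects, count noise, weight structure
that violates the partial-correlation parameterization, or interaction
knowledge that is wrong rather than merely incomplete. The
`perturb_weights` option and finite `nonedge_penalty` probe mild
versions of the last two, nothing more.

Problem sizes in the tests and the acceptance script are the package's
desk-scale study design: 150 genes, 15 pathways, 40 samples per
condition, 50 replicates for type-I calibration, 20 replicates (common
random numbers) for the power grid, and 10 seeded datasets for the
clustered/unclustered comparison at `max_size = 50` — the cap is set
below the 75-gene component size precisely so the comparison exercises
real splitting (edge loss ~20%) instead of a vacuous no-op.

## Known limitations

* Two-condition contrasts only; multi-condition data require selecting
  a pair per run. No covariates, no permutation alternative.
* The pathway statistic uses plug-in variance components; severe
  misspecification of the network model propagates into the test.
* Directed networks must be acyclic within clusters; feedback loops are
  rejected rather than approximated.
* GraphML export is static; interactive exploration is delegated to
  external viewers.
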