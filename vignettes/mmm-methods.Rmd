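---
title: "Methods: collapsed mixture clustering of mixed-type tables and cluster-wise synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collapsed mixture clustering of mixed-type tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette describes the statistical model behind `mmmclust`, the
algorithmic and numerical choices made where the design was genuinely open,
what the built-in simulators do and do not emulate, and the package's known
limitations.

## The model

A table has $N$ rows and $L$ columns, each column declared categorical (with
a fixed level set) or numeric. Rows are assumed to come from $K$ latent
clusters; a clustering is a label vector $A$ with $A_i \in 1..K$. Within a
cluster, columns are modeled independently:

* a categorical column with $k$ levels follows an unknown categorical
  distribution with a Dirichlet prior (pseudo-counts $c_1..c_k$). With
  counts $N_1..N_k$ observed in the cluster, the posterior predictive for a
  new value $i$ is $(N_i + c_i)/(N + C)$, $C = \sum_i c_i$;
* a numeric column follows an unknown Gaussian whose mean/precision pair
  carries a normal-gamma prior $N(\mu \mid \mu_0, (\beta_0\lambda)^{-1})\,
  \mathrm{Gam}(\lambda \mid a_0, b_0)$. The posterior hyperparameters are
  the standard conjugate updates, the predictive is a Student-$t$ with
  $2a_n$ degrees of freedom, and the marginal likelihood of a cluster's
  values has the closed gamma-function form.

Nothing is ever estimated for these within-cluster parameters: they are
integrated out exactly (collapsed inference), so a clustering is scored by
the joint collapsed likelihood
$P(D \mid A, K) = \prod_{j=1}^{K}\prod_{\ell} P(d_{\ell j})$, the product of
column marginals over the rows assigned to each cluster. Both column models
support $O(1)$ add/remove of a row, which makes leave-one-out predictive
scores cheap.

### Default hyperparameters

Defaults are empirical-Bayes and overridable through `mmm_priors()`:
pseudo-counts $c_i = 1$ (uniform Dirichlet) for every categorical column;
$\mu_0$ = whole-column mean, $\beta_0 = 1$, $a_0 = 1$, $b_0$ = whole-column
variance for every numeric column. Setting $b_0$ to the column variance
makes the prior match the column's scale, which is why the package does
**not** standardize numeric columns — the prior plays that role. A constant
numeric column would give $b_0 = 0$; the implementation falls back to
$b_0 = 1$ in that degenerate case. Categorical level sets come from the
schema, not from the observed rows, so a cluster missing a level still
assigns it positive predictive mass.

## The clustering loop

`fit_k()` is a hard-assignment EM analogue. Each pass scores every row
against every cluster — the score $L_{ij}$ is the sum over columns of the
log posterior predictive of row $i$ under cluster $j$'s current members,
with row $i$ first *removed* from its own cluster — and reassigns rows to
their best-scoring cluster. Two modes are provided:

* **batch** (default): all rows move simultaneously. This is the plain
  reading of the algorithm but is not provably monotone, so the loop keeps
  the best assignment seen and stops after `max_iters` (default 100) passes
  if no fixed point is reached — this also protects against reassignment
  cycles.
* **sequential**: rows move one at a time with immediate state update. Each
  accepted move strictly increases the joint collapsed likelihood, so the
  objective trace (returned as `trace`) is monotone and convergence needs no
  safeguard.

Ties keep the row's current cluster, otherwise the lowest cluster index
wins, which makes results deterministic. Clusters that empty out are
dropped and the surviving count reported.

**Initialization.** The fit for $K$ clusters starts from the fitted
$K - 1$ solution with the $\lfloor N/K \rfloor$ worst-fitting rows (by their
own-cluster leave-one-out predictive) split off as a new cluster. This
incremental path is cheap and usually good, but on data with several
similar-sized clusters it can stall in a local optimum; `fit_k()` and
`mmm_cluster()` therefore also try `n_restarts` (default 2) seeded random
initializations at each $K$ and keep the fit with the highest joint
likelihood. Rounding of $N/(K+1)$ in the split is downward; score ties in
the split are broken by row index.

## Choosing K: the marginal likelihood

The number of clusters is chosen by the model evidence
$ML_K = \sum_A P(D \mid A, K)\, P(A \mid K)$, with $P(A \mid K)$ uniform
over label vectors with no empty cluster (a table of 20 rows at $K = 2$
therefore sums $2^{20} - 2 = 1{,}048{,}574$ terms). Estimators provided:

* **exact** — feasible only when $K^N$ is small (default bound $2\times
  10^6$). Implemented as a subset-sum dynamic program over bitmask-indexed
  sufficient statistics rather than a literal loop, so the 20-row case takes
  seconds; the sum is over exactly the same assignments.
* **AM** — the arithmetic mean of $P(D|A,K)$ over prior draws. Biased low
  on the log scale (Jensen; the high-likelihood region is tiny).
* **HM** — the harmonic mean over posterior samples. Biased high, opposite
  to AM.
* **HMβ** — a tempered harmonic mean: two chains, one targeting
  $P(D|A,K)^\beta$ and one the posterior, combined as
  $\log ML = -\log\langle P^{-\beta}\rangle_{\tilde P}
  -\log\langle P^{\beta-1}\rangle_{P}$. The default $\beta = 0.5$ splits
  the tempering between the two averages. At $\beta = 1$ the second term
  vanishes and the estimator *is* the harmonic mean. At $\beta = 0$ the
  first term vanishes identically and the generic formula degenerates (the
  remaining term is again a harmonic mean); since the tempered chain at
  $\beta = 0$ samples the assignment prior — exactly the AM's sampling
  distribution — the package closes the family at that end by defining the
  $\beta = 0$ member as the AM estimator. This keeps the family a true
  AM-to-HM interpolation, which is its design intent, and both endpoint
  reductions are exact on shared sample streams.
* **TI** — thermodynamic integration: $\log ML = \int_0^1
  E_\beta[\log P(D|A,K)]\,d\beta$, with $E_\beta$ estimated by tempered
  sampling on a uniform grid of inverse temperatures (default 11, odd so
  Simpson's rule applies) and chains warm-started up the ladder. The
  $\beta = 0$ anchor is the normalized prior, so no extra constant is
  needed. $E_\beta$ is non-decreasing in $\beta$ (its derivative is a
  variance), which is checked in the tests up to Monte-Carlo noise.
* **BIC** — the classification-likelihood BIC on the $-BIC/2$ scale, as a
  baseline. It is provided because it is ubiquitous, not because it works
  well here: on the planted-cluster benchmarks its K recovery is clearly
  worse than TI/HMβ, and on unclustered data it is the most conservative.

**The sampler.** All sampling estimators share a single-site Metropolis
chain over labels: pick a row uniformly, propose one of the other $K - 1$
labels uniformly, accept with probability $\min(1, r^\beta)$ where $r$ is
the collapsed predictive ratio; moves that would empty a cluster are
rejected (keeping the chain on the support of the assignment prior).
Defaults: burn-in $10N$ proposals, thinning $N$ proposals between samples,
$M = 200$ samples per chain. The chain core is compiled code driven by R's
RNG, so every estimate is reproducible from a seed. Monte-Carlo standard
errors are batch-means errors (10 batches) on the log scale; HMβ combines
its two chain errors in quadrature, TI propagates per-temperature errors
through the Simpson weights. For $K = 1$ there is exactly one assignment
and every estimator returns the exact value.

In practice TI is the most accurate and the most expensive; HMβ(0.5) tracks
it well on clearly clustered data but retains some of the harmonic mean's
upward bias, which grows with $K$ — on weakly structured data it tends to
overestimate $K$, where TI does not. That behaviour is visible in the
package's own tests (the homogeneous-data selection test uses TI for this
reason).

## The benchmark simulators

`make_categorical()`, `make_numeric()`, `make_mixed()` and `make_k_series()`
generate tables with planted clusters and return the ground-truth labels
and true parameters alongside the data.

* Categorical columns: per-cluster probabilities proportional to
  $v_0 + \Delta v_j$ with a shared base $v_0 \sim U[1,2]^k$ and cluster
  perturbations $v_j \sim U[-0.5, 0.5]^k$, floored at $0.05$ and
  normalized. Larger $\Delta$ (0.5–4.5) gives more distinct clusters,
  monotonically.
* Numeric columns: cluster $j$ has mean $j \cdot \texttt{mean\_gap}$
  (gap 1.0 by default) and sd $1.0 + (j-1)\,\delta\sigma$; `same_mean`
  forces equal means so only dispersion separates clusters.
* Mixed tables couple the two knobs as $\delta\sigma = 5 - \Delta$, so one
  parameter moves every column type together; the default shape is five
  numeric plus five 4-valued categorical columns, clusters in ratio
  5:4:3:2:1 (largest-remainder apportionment).
* `make_outcome()` adds a binary output column from a cluster-specific
  noisy linear rule over the numeric block, for the synthetic-data utility
  harness.

Because base and perturbation vectors are random, cluster separation at a
given $\Delta$ varies from draw to draw, and adjacent clusters overlap
substantially even at the most-separated settings — two clusters can draw
similar perturbations, and the upper clusters' sds (up to $1 + 4\,
\delta\sigma$) are large relative to the unit mean gap. Passing recovery
tests on these tables therefore demonstrates that the fitter reaches the
likelihood ceiling the data admit, not that real data of the same shape
would be recovered perfectly. The simulators also idealize in other ways
real tables do not: columns are exactly independent within cluster, numeric
columns are exactly Gaussian, and labels are mutually exclusive hard
memberships.

## MMMSynth

`mmmsynth()` generates a synthetic table in four steps: cluster the real
table on its *input* columns (the declared output column never influences
the clustering); select $K$ by the configured evidence estimator (default
HMβ(0.5)); fit, per cluster, maximum-likelihood categorical frequencies and
Gaussian mean/sd per input column plus an ordinary least-squares model of
the output on the one-hot-expanded inputs (reference level dropped per
categorical column to avoid collinearity), recording the residual sd; then
sample synthetic clusters of the same sizes and pool them, shuffled.

Open choices, resolved as follows:

* **Binary outputs.** The output model is "a noisy linear function"; for a
  binary output the package fits OLS on the 0/1 indicator and thresholds
  the noisy prediction at 0.5 — the most literal reading. A
  logistic-sampling alternative (`output_model = "logistic"`) is provided
  for users who prefer calibrated probabilities.
* **Degenerate clusters** (fewer than 2 rows) are merged into their
  nearest cluster by predictive score before fitting.
* **No range clipping.** Numeric sampling is unbounded Gaussian; users who
  need values inside the observed range should post-process.

## Evaluation

`adjusted_rand_index()` implements the Hubert–Arabie chance-corrected form
from the pair-count contingency table; the tests verify it against explicit
all-pairs counting and an established implementation.
`utility_benchmark()` trains a classifier (logistic regression, or random
forests via `ranger`) on synthetic data and reports AUC on the real data
over repeated synthetic draws (default 20), next to a real-trained
reference. The default protocol is resubstitution (test set = the real
table itself), matching the "predict on the same dataset" reading; pass a
held-out `real_test` for a split protocol.

## Numerical choices

All likelihood arithmetic is in log space with `lgamma`; marginals are
never exponentiated. Gaussian sufficient statistics use streaming
(Welford) updates; removal restores statistics to $10^{-9}$ relative
tolerance and the sum of squared deviations is floored at 0. Log-sum-exp
underlies every average. Enumeration and sampling share the uniform
no-empty-cluster assignment prior, so all evidence numbers are directly
comparable.

## Problem sizes used by the test suite

The tests exercise the exact/sampling agreement on 12-row tables (where
enumeration is exact), the full enumeration count on a 20-row table,
planted-cluster recovery at 500 rows, K recovery on 400-row equal-size
tables for $K = 2..5$ against a $K_{\max}$ of 7, and the MMMSynth utility
protocol on 1000-row two-cluster tables with 10 replicate seeds and 20
synthetic draws each. These sizes were chosen so the whole suite completes
in a few minutes while every check still has the power to fail.

## Limitations

Columns are independent within a cluster — correlated numeric columns
would need a multivariate model, which this package deliberately does not
include. Numeric columns are Gaussian; heavy-tailed data will be
approximated by extra clusters. Missing values are rejected, not imputed.
The samplers are single-site and can mix slowly on large tables with many
near-equivalent clusters; HMβ inherits part of the harmonic mean's upward
bias and is best treated as a fast cross-check on TI rather than a
replacement when the evidence gaps are small.
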