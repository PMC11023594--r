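# mmmclust

Clustering of heterogeneous tabular data — tables mixing categorical and
numeric columns, as ubiquitous in clinical and epidemiological datasets —
and generation of synthetic tables that preserve the cluster structure and
predictive utility of the original. For analysts who need to (a) find
latent row structure in mixed-type tables without inventing a distance
metric, (b) decide *how many* clusters the data actually support, and
(c) share a synthetic stand-in for a table they cannot release.

## The model

Each column is modeled per cluster with a conjugate prior and its
parameters are integrated out exactly (collapsed inference):

* categorical column, $k$ levels, Dirichlet prior: posterior predictive
  $P(x{=}i \mid D) = (N_i + c_i)/(N + C)$;
* numeric column, normal-gamma prior on (mean, precision): Student-$t$
  posterior predictive and the closed-form marginal
  $p(D) = \frac{\Gamma(a_n)}{\Gamma(a_0)} \frac{b_0^{a_0}}{b_n^{a_n}}
  \big(\tfrac{\beta_0}{\beta_n}\big)^{1/2} (2\pi)^{-n/2}$.

A clustering (label vector $A$, $A_i \in 1..K$) is scored by the joint
collapsed likelihood $P(D \mid A, K) = \prod_j \prod_\ell P(d_{\ell j})$ and
optimized by a hard-assignment EM: score every row against every cluster by
its leave-one-out posterior predictive, reassign, repeat. The number of
clusters is chosen by the marginal likelihood ("Bayesian Occam's razor")
$ML_K = \sum_A P(D \mid A, K) P(A \mid K)$, estimated by exact enumeration
(tiny tables), thermodynamic integration, a tempered harmonic-mean
estimator HMβ interpolating the arithmetic (β=0) and harmonic (β=1) means,
or BIC. MMMSynth then fits per-cluster column distributions plus a noisy
linear output model and samples a synthetic table cluster by cluster.

See `vignettes/mmm-methods.Rmd` for the full account.

## Worked example

```r
library(mmmclust)

sim <- make_mixed(n_rows = 300, delta = 4, ratio = c(2, 2, 1), seed = 8)
fit <- mmm_cluster(sim$data, sim$schema, K_max = 5, method = "hmbeta", seed = 1)
fit
#> MMM clustering fit (hmbeta evidence)
#>   best K: 3
#>  K method    log_ml mc_error   log_lik
#>  1 HMbeta -5045.591    0.000 -5045.591
#>  2 HMbeta -4642.199    1.662 -4574.679
#>  3 HMbeta -4610.364    1.811 -4451.553
#>  4 HMbeta -4626.588    2.951 -4412.215
#>  5 HMbeta -4650.177    4.467 -4372.111

adjusted_rand_index(fit$labels, sim$labels)
#> [1] 0.8339343
```

The table plants three clusters (sizes 120/120/60) in five numeric and five
categorical columns. `log_lik` — the collapsed likelihood of the fitted
assignment — keeps rising with K, as it must; the evidence `log_ml`
penalizes the extra assignment freedom and peaks at the planted K = 3. The
recovered partition agrees with the planted one at ARI 0.83 (the planted
clusters overlap, so perfect recovery is not attainable here).

On a tiny table the evidence can be computed exactly, which is how the
sampling estimators are validated:

```r
exact_log_ml(sim$data[1:15, ], sim$schema, 2)
#> log ML (K = 2, exact): -212.0155  [mc se 0.0000]  (32,766 assignments)
```

Synthetic data from a table with a declared binary output column:

```r
real <- make_outcome(n_rows = 1000, seed = 3)          # simulated "real" table
syn  <- mmmsynth(real$data, real$schema, seed = 1)      # cluster, fit, sample
utility_benchmark(real$data, synth = syn$data, schema = real$schema,
                  model = "logistic", n_runs = 20, seed = 1)
```

A command-line surface is installed as `exec/mmm`
(`mmm cluster`, `mmm evidence`, `mmm simulate`, `mmm synth`,
`mmm evaluate ari`, `mmm infer-schema`).

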