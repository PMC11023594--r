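# Shared fixture builders (everything is generated in code, seeded).

# Small mixed table with a handful of numeric and categorical columns.
tiny_mixed <- function(n = 20, seed = 1, K = 2, delta = 3,
                       n_numeric = 2, n_cat = 2) {
  make_mixed(n_rows = n, n_numeric = n_numeric, n_cat = n_cat,
             delta = delta, ratio = rep(1, K), seed = seed)
}

# Brute-force log marginal likelihood: direct enumeration of every label
# vector with no empty cluster, averaging P(D|A) uniformly. Independent of
# the subset-DP path used by exact_log_ml().
brute_force_log_ml <- function(data, schema, K) {
  N <- nrow(data)
  lls <- c()
  for (code in 0:(K^N - 1)) {
    lab <- integer(N); c2 <- code
    for (i in seq_len(N)) { lab[i] <- c2 %% K + 1; c2 <- c2 %/% K }
    if (length(unique(lab)) == K)
      lls <- c(lls, joint_log_likelihood(data, schema, lab))
  }
  m <- max(lls)
  list(log_ml = m + log(mean(exp(lls - m))), n = length(lls))
}

# Adjusted Rand index by explicit counting over all N(N-1)/2 element pairs.
brute_force_ari <- function(a, b) {
  N <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  total <- choose(N, 2)
  index <- s11
  exp_index <- (s11 + s10) * (s11 + s01) / total
  max_index <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_index == exp_index) return(if (index == exp_index) 1 else 0)
  (index - exp_index) / (max_index - exp_index)
}

# Batch recomputation of the joint likelihood from scratch with the
# column-model objects (oracle for the vectorized engine path).
model_based_joint_ll <- function(data, schema, labels) {
  d <- mmmclust:::new_mmm_data(data, schema)
  ll <- 0
  for (j in sort(unique(labels))) {
    for (nm in colnames(d$cat)) {
      m <- categorical_model(length(d$cat_levels[[nm]]),
                             d$priors$cat[[nm]])
      for (x in d$cat[labels == j, nm]) m <- add_row(m, x)
      ll <- ll + categorical_log_marginal(m)
    }
    for (nm in colnames(d$num)) {
      hy <- d$priors$num[[nm]]
      m <- gaussian_model(hy$mu0, hy$beta0, hy$a0, hy$b0)
      for (x in d$num[labels == j, nm]) m <- add_row(m, x)
      ll <- ll + gaussian_log_marginal(m)
    }
  }
  ll
}
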