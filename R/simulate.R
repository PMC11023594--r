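# Planted-cluster benchmark simulators. Each generator returns the data, the
# ground-truth labels (row-aligned) and the matching schema, and is
# byte-reproducible given a seed.

#' @keywords internal
sim_result <- function(data, labels, schema, params = NULL) {
  structure(list(data = data, labels = as.integer(labels), schema = schema,
                 params = params),
            class = "mmm_sim")
}

#' @export
print.mmm_sim <- function(x, ...) {
  cat("mmm_sim:", nrow(x$data), "rows,", ncol(x$data), "columns,",
      max(x$labels), "planted clusters (sizes:",
      paste(tabulate(x$labels), collapse = ", "), ")\n")
  invisible(x)
}

# Category probabilities for cluster j: proportional to v0 + delta * v_j with
# v0 ~ U[1,2]^k shared across clusters and v_j ~ U[-0.5,0.5]^k per cluster,
# floored at 0.05 and normalized. Larger delta = more distinct clusters.
#' @keywords internal
cat_cluster_probs <- function(k, K, delta) {
  v0 <- stats::runif(k, 1, 2)
  t(vapply(seq_len(K), function(j) {
    vj <- stats::runif(k, -0.5, 0.5)
    p <- pmax(v0 + delta * vj, 0.05)
    p / sum(p)
  }, numeric(k)))
}

#' @keywords internal
level_names <- function(k) letters[seq_len(k)]

#' Synthetic categorical benchmark data with planted clusters
#'
#' Each categorical column draws, per cluster, from probabilities
#' proportional to a shared base weight vector plus `delta` times a
#' cluster-specific perturbation; small `delta` makes the clusters nearly
#' indistinguishable. The default plan is the benchmark shape: five binary
#' and five 4-valued columns, 5000 rows, five clusters in ratio 5:4:3:2:1.
#'
#' @param n_rows Number of rows.
#' @param n_binary,n_cat4 Number of binary / 4-valued columns.
#' @param delta Categorical separation (> 0), typically 0.5–4.5.
#' @param ratio Cluster-size ratio (length = number of clusters); sizes are
#'   apportioned by largest remainder.
#' @param seed Optional integer seed.
#' @return An `mmm_sim`: list with `data`, `labels`, `schema`.
#' @export
make_categorical <- function(n_rows = 5000L, n_binary = 5L, n_cat4 = 5L,
                             delta = 2.5, ratio = c(5, 4, 3, 2, 1),
                             seed = NULL) {
  stopifnot(delta > 0, n_binary + n_cat4 >= 1L)
  if (!is.null(seed)) set.seed(seed)
  K <- length(ratio)
  sizes <- sizes_from_ratio(n_rows, ratio)
  labels <- rep(seq_len(K), sizes)
  ks <- c(rep(2L, n_binary), rep(4L, n_cat4))
  nms <- sprintf("c%02d", seq_along(ks))
  probs <- list()
  data <- as.data.frame(lapply(seq_along(ks), function(l) {
    pr <- cat_cluster_probs(ks[l], K, delta)
    probs[[nms[l]]] <<- pr
    unlist(lapply(seq_len(K), function(j)
      sample(level_names(ks[l]), sizes[j], replace = TRUE, prob = pr[j, ])))
  }), col.names = nms)
  lev <- stats::setNames(lapply(ks, level_names), nms)
  schema <- mmm_schema(stats::setNames(rep("categorical", length(ks)), nms),
                       levels = lev)
  sim_result(data, labels, schema, params = list(probs = probs))
}

#' Synthetic numeric benchmark data with planted clusters
#'
#' Gaussian columns whose cluster means are an arithmetic progression with
#' gap `mean_gap` (default 1.0) and whose standard deviations are separated
#' by `dsigma`: cluster j has mean `j * mean_gap` and sd
#' `base_sd + (j - 1) * dsigma`. With `same_mean = TRUE` all cluster means
#' coincide and only the variances differ, so clusters are separable by
#' dispersion alone.
#'
#' @inheritParams make_categorical
#' @param n_cols Number of numeric columns.
#' @param dsigma Standard-deviation separation (> 0).
#' @param mean_gap Mean separation between consecutive clusters. Default 1.0.
#' @param base_sd Standard deviation of the first cluster. Default 1.0.
#' @param same_mean If `TRUE`, all clusters share one mean.
#' @return An `mmm_sim`.
#' @export
make_numeric <- function(n_rows = 5000L, n_cols = 10L, dsigma = 1,
                         mean_gap = 1, base_sd = 1, same_mean = FALSE,
                         ratio = c(5, 4, 3, 2, 1), seed = NULL) {
  stopifnot(dsigma > 0, n_cols >= 1L)
  if (!is.null(seed)) set.seed(seed)
  K <- length(ratio)
  sizes <- sizes_from_ratio(n_rows, ratio)
  labels <- rep(seq_len(K), sizes)
  means <- if (same_mean) rep(0, K) else seq_len(K) * mean_gap
  sds <- base_sd + (seq_len(K) - 1) * dsigma
  nms <- sprintf("x%02d", seq_len(n_cols))
  data <- as.data.frame(lapply(seq_len(n_cols), function(l)
    unlist(lapply(seq_len(K), function(j)
      stats::rnorm(sizes[j], means[j], sds[j])))), col.names = nms)
  schema <- mmm_schema(stats::setNames(rep("numeric", n_cols), nms))
  sim_result(data, labels, schema, params = list(means = means, sds = sds))
}

#' Synthetic mixed benchmark data with planted clusters
#'
#' Concatenates a numeric block and a categorical (4-valued) block with
#' shared planted labels. By default the separations are coupled as
#' `dsigma = 5.0 - delta`, so increasing `delta` makes every column type more
#' cluster-distinct simultaneously.
#'
#' @inheritParams make_categorical
#' @inheritParams make_numeric
#' @param n_numeric,n_cat Number of numeric / 4-valued categorical columns.
#' @param dsigma Numeric sd separation; default `5.0 - delta`.
#' @return An `mmm_sim`.
#' @export
make_mixed <- function(n_rows = 5000L, n_numeric = 5L, n_cat = 5L,
                       delta = 2.5, dsigma = 5.0 - delta, mean_gap = 1,
                       base_sd = 1, ratio = c(5, 4, 3, 2, 1), seed = NULL) {
  stopifnot(delta > 0, dsigma > 0)
  if (!is.null(seed)) set.seed(seed)
  K <- length(ratio)
  sizes <- sizes_from_ratio(n_rows, ratio)
  labels <- rep(seq_len(K), sizes)

  means <- seq_len(K) * mean_gap
  sds <- base_sd + (seq_len(K) - 1) * dsigma
  num_nms <- sprintf("x%02d", seq_len(n_numeric))
  num <- lapply(seq_len(n_numeric), function(l)
    unlist(lapply(seq_len(K), function(j)
      stats::rnorm(sizes[j], means[j], sds[j]))))

  cat_nms <- sprintf("c%02d", seq_len(n_cat))
  probs <- list()
  cat <- lapply(seq_len(n_cat), function(l) {
    pr <- cat_cluster_probs(4L, K, delta)
    probs[[cat_nms[l]]] <<- pr
    unlist(lapply(seq_len(K), function(j)
      sample(level_names(4L), sizes[j], replace = TRUE, prob = pr[j, ])))
  })

  data <- as.data.frame(c(num, cat),
                        col.names = c(num_nms, cat_nms))
  kinds <- stats::setNames(c(rep("numeric", n_numeric),
                             rep("categorical", n_cat)),
                           c(num_nms, cat_nms))
  lev <- stats::setNames(rep(list(level_names(4L)), n_cat), cat_nms)
  schema <- mmm_schema(kinds, levels = lev)
  sim_result(data, labels, schema,
             params = list(means = means, sds = sds, probs = probs))
}

#' Simulated clustered table with a binary outcome column
#'
#' Builds a mixed two-block table with [make_mixed()] and adds a binary
#' output column generated by a cluster-specific noisy linear rule: within
#' each planted cluster, a random coefficient vector over the centered
#' numeric columns produces a linear score, Gaussian noise of sd `noise_sd`
#' is added, and the sign is thresholded to the levels `"no"`/`"yes"`.
#' Because the outcome rule differs per cluster, a generator that models the
#' table cluster-wise (like MMMSynth) is required to preserve its utility.
#'
#' @inheritParams make_mixed
#' @param noise_sd Noise standard deviation on the linear score. Default 1.
#' @return An `mmm_sim` whose schema flags the `out` column as output.
#' @export
make_outcome <- function(n_rows = 1000L, delta = 4.5, ratio = c(1, 1),
                         noise_sd = 1, seed = NULL) {
  sim <- make_mixed(n_rows = n_rows, delta = delta, ratio = ratio,
                    seed = seed)
  num_cols <- names(Filter(function(c) c$kind == "numeric", sim$schema))
  X <- as.matrix(sim$data[, num_cols, drop = FALSE])
  eta <- numeric(n_rows)
  weights <- list()
  for (j in seq_len(max(sim$labels))) {
    rows <- sim$labels == j
    w <- stats::rnorm(ncol(X))
    weights[[j]] <- w
    ctr <- colMeans(X[rows, , drop = FALSE])
    eta[rows] <- scale(X[rows, , drop = FALSE], center = ctr,
                       scale = FALSE) %*% w
  }
  out <- ifelse(eta + stats::rnorm(n_rows, 0, noise_sd) > 0, "yes", "no")
  data <- sim$data
  data$out <- out
  kinds <- c(stats::setNames(vapply(sim$schema, `[[`, "", "kind"),
                             schema_names(sim$schema)),
             out = "categorical")
  lev <- Filter(Negate(is.null),
                stats::setNames(lapply(sim$schema, `[[`, "levels"),
                                schema_names(sim$schema)))
  lev$out <- c("no", "yes")
  schema <- mmm_schema(kinds, levels = lev, output = "out")
  sim_result(data, sim$labels, schema,
             params = c(sim$params, list(weights = weights)))
}

#' Series of mixed datasets with equal-sized clusters, K = 2..10
#'
#' One mixed dataset per K with clusters of (near-)equal size (largest
#' remainder rule), for benchmarking cluster-number recovery.
#'
#' @inheritParams make_mixed
#' @param k_range Cluster numbers to generate (default `2:10`).
#' @return Named list of `mmm_sim` objects (`"K2"`, `"K3"`, ...).
#' @export
make_k_series <- function(n_rows = 5000L, k_range = 2:10, delta = 4.5,
                          seed = NULL) {
  stopifnot(all(k_range >= 2L))
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(k_range, function(K)
    make_mixed(n_rows = n_rows, delta = delta, ratio = rep(1, K)))
  names(out) <- paste0("K", k_range)
  out
}
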