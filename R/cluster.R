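# Cluster-state bookkeeping: per cluster j and column l we keep only the
# sufficient statistics of the rows assigned to j (counts for categorical
# columns; n, sum, sum of squares for numeric columns). Everything the engine
# does — joint likelihood, leave-one-out scores, reassignment — reads these.

#' @keywords internal
build_state <- function(d, labels, K = max(labels)) {
  n <- tabulate(labels, K)
  Z <- matrix(0, d$n, K)
  Z[cbind(seq_len(d$n), labels)] <- 1
  s1 <- crossprod(Z, d$num)        # K x Ln
  s2 <- crossprod(Z, d$num^2)
  cat <- lapply(colnames(d$cat) %||% character(0), function(nm) {
    k <- length(d$cat_levels[[nm]])
    t(vapply(seq_len(K), function(j)
      tabulate(d$cat[labels == j, nm], k), integer(k)))
  })
  names(cat) <- colnames(d$cat)
  list(K = K, n = n, s1 = s1, s2 = s2, cat = cat)
}

# Collapsed marginal of one categorical column, vectorized over clusters.
# cnt: K x k counts, alpha: pseudo-counts.
#' @keywords internal
cat_marg_vec <- function(cnt, alpha) {
  K <- nrow(cnt)
  C <- sum(alpha)
  rowSums(lgamma(sweep(cnt, 2, alpha, `+`))) - sum(lgamma(alpha)) +
    lgamma(C) - lgamma(rowSums(cnt) + C)
}

# Collapsed marginal of one numeric column, vectorized over clusters.
#' @keywords internal
num_marg_vec <- function(n, s1, s2, hy) {
  xbar <- ifelse(n > 0, s1 / pmax(n, 1), 0)
  S <- pmax(s2 - n * xbar^2, 0)
  beta_n <- hy$beta0 + n
  a_n <- hy$a0 + n / 2
  b_n <- hy$b0 + S / 2 + hy$beta0 * n * (xbar - hy$mu0)^2 / (2 * beta_n)
  out <- lgamma(a_n) - lgamma(hy$a0) + hy$a0 * log(hy$b0) - a_n * log(b_n) +
    0.5 * (log(hy$beta0) - log(beta_n)) - n / 2 * log(2 * pi)
  out[n == 0] <- 0
  out
}

#' @keywords internal
joint_ll_impl <- function(d, labels, K = max(labels), state = NULL) {
  st <- state %||% build_state(d, labels, K)
  ll <- 0
  for (nm in names(st$cat))
    ll <- ll + sum(cat_marg_vec(st$cat[[nm]], d$priors$cat[[nm]]))
  for (nm in colnames(d$num))
    ll <- ll + sum(num_marg_vec(st$n, st$s1[, nm], st$s2[, nm],
                                d$priors$num[[nm]]))
  ll
}

# Student-t predictive from posterior pieces, all arguments vectorized.
#' @keywords internal
student_vec <- function(x, mu_n, beta_n, a_n, b_n) {
  lam <- a_n * beta_n / (b_n * (beta_n + 1))
  -0.5 * log(pi) + lgamma(a_n + 0.5) - lgamma(a_n) +
    0.5 * (log(lam) - log(2 * a_n)) -
    (a_n + 0.5) * log1p(lam * (x - mu_n)^2 / (2 * a_n))
}

# N x K matrix of leave-one-out log posterior predictives: entry (i, j) is
# the log-probability of row i under cluster j's current members, with row i
# first removed from its own cluster.
#' @keywords internal
score_matrix_impl <- function(d, labels, K = max(labels), state = NULL) {
  st <- state %||% build_state(d, labels, K)
  N <- d$n
  L <- matrix(0, N, K)
  for (j in seq_len(K)) {
    own <- which(labels == j)
    for (nm in names(st$cat)) {
      alpha <- d$priors$cat[[nm]]
      C <- sum(alpha)
      x <- d$cat[, nm]
      numer <- st$cat[[nm]][j, x] + alpha[x]
      denom <- rep(st$n[j] + C, N)
      numer[own] <- numer[own] - 1
      denom[own] <- denom[own] - 1
      L[, j] <- L[, j] + log(numer) - log(denom)
    }
    for (nm in colnames(d$num)) {
      hy <- d$priors$num[[nm]]
      x <- d$num[, nm]
      n_j <- st$n[j]
      s1 <- st$s1[j, nm]; s2 <- st$s2[j, nm]
      m_j <- if (n_j > 0) s1 / n_j else 0
      S_j <- max(s2 - n_j * m_j^2, 0)
      post <- function(n, m, S) {
        beta_n <- hy$beta0 + n
        list(mu_n = (hy$beta0 * hy$mu0 + n * m) / beta_n,
             beta_n = beta_n, a_n = hy$a0 + n / 2,
             b_n = hy$b0 + S / 2 +
               hy$beta0 * n * (m - hy$mu0)^2 / (2 * beta_n))
      }
      p <- post(n_j, m_j, S_j)
      L[, j] <- L[, j] + student_vec(x, p$mu_n, p$beta_n, p$a_n, p$b_n)
      if (length(own)) {
        xo <- x[own]
        if (n_j == 1L) {
          p0 <- post(0, 0, 0)
          L[own, j] <- L[own, j] -
            student_vec(xo, p$mu_n, p$beta_n, p$a_n, p$b_n) +
            student_vec(xo, p0$mu_n, p0$beta_n, p0$a_n, p0$b_n)
        } else {
          n1 <- n_j - 1L
          m1 <- (n_j * m_j - xo) / n1
          S1 <- pmax(S_j - (xo - m1) * (xo - m_j), 0)
          p1 <- post(n1, m1, S1)
          L[own, j] <- L[own, j] -
            student_vec(xo, p$mu_n, p$beta_n, p$a_n, p$b_n) +
            student_vec(xo, p1$mu_n, p1$beta_n, p1$a_n, p1$b_n)
        }
      }
    }
  }
  L
}

#' Joint collapsed log-likelihood of a clustering
#'
#' The log of \eqn{\prod_{j=1}^K P(d : d \in j)}: for each cluster the product
#' over columns of the collapsed column marginals (Dirichlet-multinomial or
#' normal-gamma evidence) of the rows assigned to it. Columns are treated as
#' independent; empty clusters contribute 0.
#'
#' @param data Data frame.
#' @param schema An [mmm_schema()] (the output column, if flagged, is
#'   excluded).
#' @param labels Integer cluster labels in `1..K`.
#' @param priors Optional [mmm_priors()] override.
#' @return Log-likelihood (scalar).
#' @export
joint_log_likelihood <- function(data, schema, labels, priors = NULL) {
  d <- new_mmm_data(data, schema, priors)
  labels <- check_labels(labels, d$n)
  joint_ll_impl(d, labels, max(labels))
}

#' Leave-one-out cluster membership scores for one row
#'
#' Entry `j` is the sum over columns of the log posterior predictive of row
#' `i`'s values under cluster `j`'s current members, with row `i` removed from
#' its own cluster first. Equals the change in [joint_log_likelihood()] from
#' placing the removed row into cluster `j`, up to a constant shared by all
#' `j`.
#'
#' @inheritParams joint_log_likelihood
#' @param i Row index.
#' @return Numeric vector of length `K`.
#' @export
score_row <- function(data, schema, labels, i, priors = NULL) {
  d <- new_mmm_data(data, schema, priors)
  labels <- check_labels(labels, d$n)
  stopifnot(i >= 1, i <= d$n)
  score_matrix_impl(d, labels, max(labels))[i, ]
}

#' @keywords internal
check_labels <- function(labels, n) {
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels must have one entry per row")
  if (anyNA(labels) || any(labels < 1L)) stop("labels must be in 1..K")
  labels
}

# Relabel so cluster labels are 1..K' with no gaps; returns labels and K.
#' @keywords internal
compact_labels <- function(labels) {
  present <- sort(unique(labels))
  list(labels = match(labels, present), K = length(present))
}

#' @keywords internal
random_surjective_labels <- function(n, K) {
  if (K > n) stop("K must not exceed the number of rows")
  repeat {
    lab <- sample.int(K, n, replace = TRUE)
    if (length(unique(lab)) == K) return(lab)
  }
}

#' @keywords internal
fit_k_impl <- function(d, K, labels, mode = c("batch", "sequential"),
                       max_iters = 100L) {
  mode <- match.arg(mode)
  res <- compact_labels(labels)
  labels <- res$labels; K <- res$K
  if (mode == "batch") batch_fit(d, labels, K, max_iters)
  else sequential_fit(d, labels, K, max_iters)
}

#' @keywords internal
batch_fit <- function(d, labels, K, max_iters) {
  N <- d$n
  best_ll <- -Inf; best_labels <- labels; best_K <- K
  iter <- 0L; converged <- FALSE
  repeat {
    st <- build_state(d, labels, K)
    ll <- joint_ll_impl(d, labels, K, st)
    if (ll > best_ll) { best_ll <- ll; best_labels <- labels; best_K <- K }
    if (iter >= max_iters) break
    iter <- iter + 1L
    L <- score_matrix_impl(d, labels, K, st)
    cand <- max.col(L, ties.method = "first")     # lowest index among ties
    rowmax <- L[cbind(seq_len(N), cand)]
    keep <- L[cbind(seq_len(N), labels)] >= rowmax
    new_labels <- ifelse(keep, labels, cand)
    if (all(new_labels == labels)) { converged <- TRUE; break }
    res <- compact_labels(new_labels)
    labels <- res$labels; K <- res$K
  }
  list(labels = best_labels, K = best_K, log_lik = best_ll,
       iterations = iter, converged = converged, mode = "batch")
}

# One-row-at-a-time variant with immediate state update: each accepted move
# strictly increases the joint collapsed log-likelihood, so the objective
# trace is monotone and termination is guaranteed without cycle protection.
#' @keywords internal
sequential_fit <- function(d, labels, K, max_iters) {
  N <- d$n
  iter <- 0L; converged <- FALSE
  trace <- joint_ll_impl(d, labels, K)
  repeat {
    if (iter >= max_iters) break
    iter <- iter + 1L
    moves <- 0L
    st <- build_state(d, labels, K)
    for (i in seq_len(N)) {
      cur <- labels[i]
      st <- state_remove(st, d, i, cur)
      sc <- row_scores_from_state(st, d, i, K)
      best <- which.max(sc)
      if (sc[cur] >= sc[best]) best <- cur
      if (best != cur) moves <- moves + 1L
      labels[i] <- best
      st <- state_add(st, d, i, best)
    }
    res <- compact_labels(labels)
    labels <- res$labels; K <- res$K
    trace <- c(trace, joint_ll_impl(d, labels, K))
    if (moves == 0L) { converged <- TRUE; break }
  }
  list(labels = labels, K = K,
       log_lik = joint_ll_impl(d, labels, K),
       iterations = iter, converged = converged, mode = "sequential",
       trace = trace)
}

#' @keywords internal
state_add <- function(st, d, i, j) {
  st$n[j] <- st$n[j] + 1L
  if (ncol(d$num)) {
    x <- d$num[i, ]
    st$s1[j, ] <- st$s1[j, ] + x
    st$s2[j, ] <- st$s2[j, ] + x^2
  }
  for (nm in names(st$cat))
    st$cat[[nm]][j, d$cat[i, nm]] <- st$cat[[nm]][j, d$cat[i, nm]] + 1L
  st
}

#' @keywords internal
state_remove <- function(st, d, i, j) {
  st$n[j] <- st$n[j] - 1L
  if (ncol(d$num)) {
    x <- d$num[i, ]
    st$s1[j, ] <- st$s1[j, ] - x
    st$s2[j, ] <- pmax(st$s2[j, ] - x^2, 0)
  }
  for (nm in names(st$cat))
    st$cat[[nm]][j, d$cat[i, nm]] <- st$cat[[nm]][j, d$cat[i, nm]] - 1L
  st
}

# Scores of row i under every cluster given a state in which row i is not
# counted anywhere.
#' @keywords internal
row_scores_from_state <- function(st, d, i, K) {
  sc <- numeric(K)
  for (nm in names(st$cat)) {
    alpha <- d$priors$cat[[nm]]
    x <- d$cat[i, nm]
    sc <- sc + log(st$cat[[nm]][, x] + alpha[x]) - log(st$n + sum(alpha))
  }
  for (nm in colnames(d$num)) {
    hy <- d$priors$num[[nm]]
    n <- st$n
    m <- ifelse(n > 0, st$s1[, nm] / pmax(n, 1), 0)
    S <- pmax(st$s2[, nm] - n * m^2, 0)
    beta_n <- hy$beta0 + n
    a_n <- hy$a0 + n / 2
    b_n <- hy$b0 + S / 2 + hy$beta0 * n * (m - hy$mu0)^2 / (2 * beta_n)
    mu_n <- (hy$beta0 * hy$mu0 + n * m) / beta_n
    sc <- sc + student_vec(d$num[i, nm], mu_n, beta_n, a_n, b_n)
  }
  sc
}

#' Warm-start initialization for K+1 clusters
#'
#' Given a fitted K-cluster assignment, selects the
#' \eqn{\lfloor N/(K+1) \rfloor} rows with the lowest leave-one-out posterior
#' predictive under their current cluster and relabels them as cluster
#' \eqn{K+1}. Ties are broken by row index, so the split is deterministic.
#'
#' @inheritParams joint_log_likelihood
#' @return Integer label vector with `K + 1` clusters.
#' @export
warm_start_split <- function(data, schema, labels, priors = NULL) {
  d <- new_mmm_data(data, schema, priors)
  labels <- check_labels(labels, d$n)
  warm_start_impl(d, labels, max(labels))
}

#' @keywords internal
warm_start_impl <- function(d, labels, K) {
  L <- score_matrix_impl(d, labels, K)
  self_score <- L[cbind(seq_len(d$n), labels)]
  n_move <- floor(d$n / (K + 1))
  if (n_move < 1L) return(labels)
  worst <- order(self_score, seq_len(d$n))[seq_len(n_move)]
  labels[worst] <- K + 1L
  labels
}

#' Fit a K-cluster assignment by hard-assignment EM
#'
#' Alternates between scoring every row against every cluster (leave-one-out
#' collapsed posterior predictive, the E-step analogue) and reassigning rows
#' to their best-scoring cluster; distribution parameters are never estimated
#' — they are integrated out in closed form. Stops when a full pass makes no
#' reassignment, or after `max_iters` passes (batch mode then returns the
#' best assignment seen, which guards against reassignment cycles).
#'
#' Modes: `"batch"` moves all rows simultaneously each pass; `"sequential"`
#' moves one row at a time with immediate state update, which guarantees a
#' monotone non-decreasing objective. Ties keep the row's current cluster,
#' otherwise the lowest cluster index wins. Clusters that empty out mid-run
#' are dropped, and the surviving number of clusters is reported.
#'
#' @inheritParams joint_log_likelihood
#' @param K Number of clusters (`1 <= K <= N`).
#' @param mode `"batch"` (default) or `"sequential"`.
#' @param init `"warm"` (default) fits K = 1, 2, ... incrementally, each time
#'   splitting off the worst-fitting rows ([warm_start_split()]); `"random"`
#'   starts from a seeded random assignment.
#' @param n_restarts Number of additional random initializations tried at the
#'   target K when `init = "warm"`; the fit with the highest joint
#'   log-likelihood wins. The incremental split heuristic alone can stall in
#'   a local optimum when clusters are of similar size. Default 2.
#' @param seed Optional integer seed (used by random initializations).
#' @param max_iters Maximum reassignment passes per K. Default 100.
#' @return List with `labels`, `K` (surviving clusters), `log_lik`,
#'   `iterations`, `converged`, `mode`.
#' @examples
#' sim <- make_numeric(n_rows = 60, n_cols = 2, dsigma = 0.1,
#'                     mean_gap = 8, ratio = c(1, 1), seed = 1)
#' fit <- fit_k(sim$data, sim$schema, K = 2)
#' adjusted_rand_index(fit$labels, sim$labels)
#' @export
fit_k <- function(data, schema, K, mode = c("batch", "sequential"),
                  init = c("warm", "random"), n_restarts = 2L, seed = NULL,
                  max_iters = 100L, priors = NULL) {
  mode <- match.arg(mode); init <- match.arg(init)
  d <- new_mmm_data(data, schema, priors)
  K <- as.integer(K)
  if (K < 1L || K > d$n) stop("K must be between 1 and the number of rows")
  if (!is.null(seed)) set.seed(seed)
  if (init == "random" && K > 1L) {
    labels <- random_surjective_labels(d$n, K)
    return(fit_k_impl(d, K, labels, mode, max_iters))
  }
  fit <- fit_k_impl(d, 1L, rep(1L, d$n), mode, max_iters)
  while (fit$K < K) {
    labels <- warm_start_impl(d, fit$labels, fit$K)
    fit <- fit_k_impl(d, fit$K + 1L, labels, mode, max_iters)
    if (fit$K < max(labels)) break   # split collapsed back; K unreachable
  }
  best_of_restarts(d, K, fit, n_restarts, mode, max_iters)
}

# Take the better of an existing fit and `n_restarts` random-initialization
# fits at the same K (compared by joint log-likelihood; a restart that loses
# a cluster is only accepted if nothing reached K).
#' @keywords internal
best_of_restarts <- function(d, K, fit, n_restarts, mode, max_iters) {
  for (r in seq_len(max(n_restarts, 0L))) {
    if (K > d$n) break
    cand <- fit_k_impl(d, K, random_surjective_labels(d$n, K),
                       mode, max_iters)
    better_ll <- cand$log_lik > fit$log_lik
    if ((cand$K == K && (fit$K != K || better_ll)) ||
        (fit$K != K && cand$K != K && better_ll))
      fit <- cand
  }
  fit
}
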