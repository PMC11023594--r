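#' Cluster a mixed-type table and select the number of clusters
#'
#' Fits K = 1..`K_max` by hard-assignment EM with warm starts (each K + 1 fit
#' starts from the K fit with the worst-fitting rows split off), computes the
#' model evidence for every K with the chosen estimator, and returns the
#' evidence-maximizing K. The optimal K can be 1 — in that case the table is
#' best described as a single population.
#'
#' @inheritParams joint_log_likelihood
#' @param K_max Largest number of clusters to consider.
#' @param method Evidence estimator: `"hmbeta"` (tempered harmonic mean,
#'   default), `"ti"` (thermodynamic integration), `"bic"`, or `"exact"`
#'   (tiny tables only).
#' @param beta Inverse temperature for `"hmbeta"`. Default 0.5.
#' @param M Samples per chain for the sampling estimators.
#' @param n_beta Temperature-grid size for `"ti"` (odd).
#' @param burnin,thin Chain settings; defaults `10 * N` and `N` proposals.
#' @param mode EM reassignment mode, `"batch"` or `"sequential"`.
#' @param n_restarts Random-initialization restarts per K in addition to the
#'   warm start (best joint log-likelihood wins). Default 2.
#' @param seed Integer seed controlling all randomness.
#' @param max_iters Maximum EM passes per K.
#' @return An object of class `mmm_fit`: list with `best_k`, `labels` (the
#'   assignment at `best_k`), `evidence` (data frame over K), `assignments`,
#'   `log_liks`, and the call settings.
#' @examples
#' sim <- make_mixed(n_rows = 120, delta = 4.5, ratio = c(1, 1), seed = 1)
#' fit <- mmm_cluster(sim$data, sim$schema, K_max = 3, seed = 1)
#' fit$best_k
#' @export
mmm_cluster <- function(data, schema, K_max = 10L,
                        method = c("hmbeta", "ti", "bic", "exact"),
                        beta = 0.5, M = 200L, n_beta = 11L,
                        burnin = NULL, thin = NULL,
                        mode = c("batch", "sequential"), n_restarts = 2L,
                        seed = 1L, max_iters = 100L, priors = NULL) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  d <- new_mmm_data(data, schema, priors)
  K_max <- as.integer(K_max)
  stopifnot(K_max >= 1L, K_max <= d$n)
  set.seed(seed)

  assignments <- vector("list", K_max)
  log_liks <- numeric(K_max)
  ev <- vector("list", K_max)

  fit <- fit_k_impl(d, 1L, rep(1L, d$n), mode, max_iters)
  for (K in seq_len(K_max)) {
    if (K > 1L) {
      labels <- warm_start_impl(d, fit$labels, fit$K)
      fit <- fit_k_impl(d, K, labels, mode, max_iters)
      fit <- best_of_restarts(d, K, fit, n_restarts, mode, max_iters)
    }
    assignments[[K]] <- fit$labels
    log_liks[K] <- fit$log_lik
    seed_k <- seed + 17L * K
    ev[[K]] <- switch(method,
      hmbeta = hmbeta_log_ml(data, schema, fit$K, beta = beta, M = M,
                             burnin = burnin, thin = thin, seed = seed_k,
                             init = fit$labels, priors = priors),
      ti = ti_log_ml(data, schema, fit$K, n_beta = n_beta, M = M,
                     burnin = burnin, thin = thin, seed = seed_k,
                     init = fit$labels, priors = priors),
      bic = bic_log_ml(data, schema, fit$labels, priors = priors),
      exact = exact_log_ml(data, schema, fit$K, priors = priors))
    if (fit$K < K) {  # requested K unreachable (clusters kept collapsing)
      assignments <- assignments[seq_len(K)]
      log_liks <- log_liks[seq_len(K)]
      ev <- ev[seq_len(K)]
      break
    }
  }

  evidence <- data.frame(
    K = vapply(ev, `[[`, 0L, "K"),
    method = vapply(ev, `[[`, "", "method"),
    log_ml = vapply(ev, `[[`, 0, "log_ml"),
    mc_error = vapply(ev, `[[`, 0, "mc_error"),
    log_lik = log_liks[seq_along(ev)])
  best <- which.max(evidence$log_ml)
  structure(list(best_k = evidence$K[best],
                 labels = assignments[[best]],
                 evidence = evidence,
                 assignments = assignments,
                 log_liks = log_liks[seq_along(ev)],
                 method = method, beta = beta, M = M, seed = seed,
                 mode = mode),
            class = "mmm_fit")
}

#' @export
print.mmm_fit <- function(x, ...) {
  cat("MMM clustering fit (", x$method, " evidence)\n", sep = "")
  cat("  best K:", x$best_k, "\n")
  df <- x$evidence
  df$log_ml <- round(df$log_ml, 3)
  df$mc_error <- round(df$mc_error, 3)
  df$log_lik <- round(df$log_lik, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
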