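#' @keywords internal
log_sum_exp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @keywords internal
log_mean_exp <- function(x) log_sum_exp(x) - log(length(x))

# Standard error of a log-mean-exp statistic by batch means: split the
# (thinned) sample stream into `n_batches` contiguous batches, compute the
# statistic per batch, and take sd/sqrt(B). Captures residual autocorrelation
# that an iid formula would miss.
#' @keywords internal
batch_se_lme <- function(x, n_batches = 10L) {
  n <- length(x)
  n_batches <- max(2L, min(n_batches, n))
  idx <- cut(seq_len(n), breaks = n_batches, labels = FALSE)
  b <- vapply(split(x, idx), log_mean_exp, numeric(1))
  stats::sd(b) / sqrt(length(b))
}

# Largest-remainder apportionment of n into parts proportional to `ratio`.
#' @keywords internal
sizes_from_ratio <- function(n, ratio) {
  stopifnot(n >= length(ratio), all(ratio > 0))
  quota <- n * ratio / sum(ratio)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Number of surjective label vectors of length n onto 1..k (inclusion-exclusion).
#' @keywords internal
n_surjections <- function(n, k) {
  j <- 0:k
  sum((-1)^j * choose(k, j) * (k - j)^n)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
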