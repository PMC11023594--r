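#' Collapsed conjugate model for one categorical column in one cluster
#'
#' Holds the Dirichlet pseudo-counts \eqn{c_1..c_k} and the observed category
#' counts \eqn{N_1..N_k} of the rows currently assigned to a cluster. All
#' inference is collapsed: the categorical parameter vector is integrated out
#' analytically, so the model only ever carries sufficient statistics.
#'
#' @param k Number of categories (>= 2).
#' @param pseudo Positive Dirichlet pseudo-counts, recycled to length `k`.
#'   Default 1 (uniform prior).
#' @return An object of class `mmm_cat_model`.
#' @seealso [categorical_log_predictive()], [categorical_log_marginal()],
#'   [add_row()], [remove_row()]
#' @export
categorical_model <- function(k, pseudo = 1) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  pseudo <- rep_len(as.numeric(pseudo), k)
  if (any(pseudo <= 0)) stop("pseudo-counts must be strictly positive")
  structure(list(k = k, pseudo = pseudo, counts = integer(k)),
            class = "mmm_cat_model")
}

#' Collapsed normal-gamma model for one numeric column in one cluster
#'
#' The mean/precision pair \eqn{(\mu, \lambda)} of a Gaussian column carries a
#' normal-gamma prior \eqn{N(\mu | \mu_0, (\beta_0\lambda)^{-1})
#' \,\mathrm{Gam}(\lambda | a_0, b_0)} and is integrated out. The model keeps
#' only the streaming sufficient statistics: count `n`, mean `xbar` and sum of
#' squared deviations `S`, updated stably (Welford) on add/remove.
#'
#' @param mu0 Prior location.
#' @param beta0 Prior precision scale (dimensionless, > 0).
#' @param a0,b0 Gamma shape and rate for the precision (> 0).
#' @return An object of class `mmm_gauss_model`.
#' @seealso [gaussian_posterior()], [gaussian_log_predictive()],
#'   [gaussian_log_marginal()]
#' @export
gaussian_model <- function(mu0 = 0, beta0 = 1, a0 = 1, b0 = 1) {
  stopifnot(is.finite(mu0), beta0 > 0, a0 > 0, b0 > 0)
  structure(list(mu0 = mu0, beta0 = beta0, a0 = a0, b0 = b0,
                 n = 0L, xbar = 0, S = 0),
            class = "mmm_gauss_model")
}

#' Add or remove one observation from a column model
#'
#' Incremental sufficient-statistic updates enabling the leave-one-out scores
#' of the clustering loop. `remove_row()` after `add_row()` restores the state
#' (exactly for categorical counts; to floating-point tolerance for the
#' streaming Gaussian statistics).
#'
#' @param model A `mmm_cat_model` or `mmm_gauss_model`.
#' @param x A category index in `1..k`, or a finite numeric value.
#' @return The updated model.
#' @export
add_row <- function(model, x) UseMethod("add_row")

#' @rdname add_row
#' @export
remove_row <- function(model, x) UseMethod("remove_row")

#' @export
add_row.mmm_cat_model <- function(model, x) {
  x <- as.integer(x)
  if (is.na(x) || x < 1L || x > model$k)
    stop("category index out of range: ", x)
  model$counts[x] <- model$counts[x] + 1L
  model
}

#' @export
remove_row.mmm_cat_model <- function(model, x) {
  x <- as.integer(x)
  if (is.na(x) || x < 1L || x > model$k)
    stop("category index out of range: ", x)
  if (model$counts[x] < 1L)
    stop("cannot remove category ", x, ": not present in the model")
  model$counts[x] <- model$counts[x] - 1L
  model
}

#' @export
add_row.mmm_gauss_model <- function(model, x) {
  if (!is.numeric(x) || !is.finite(x)) stop("x must be a finite number")
  n1 <- model$n + 1L
  d <- x - model$xbar
  xbar1 <- model$xbar + d / n1
  model$S <- model$S + d * (x - xbar1)
  model$xbar <- xbar1
  model$n <- n1
  model
}

#' @export
remove_row.mmm_gauss_model <- function(model, x) {
  if (!is.numeric(x) || !is.finite(x)) stop("x must be a finite number")
  if (model$n == 0L) stop("cannot remove from an empty model")
  if (model$n == 1L) {
    model$n <- 0L; model$xbar <- 0; model$S <- 0
    return(model)
  }
  n1 <- model$n - 1L
  xbar1 <- (model$n * model$xbar - x) / n1
  model$S <- max(model$S - (x - xbar1) * (x - model$xbar), 0)
  model$xbar <- xbar1
  model$n <- n1
  model
}

#' Posterior predictive probability of a category
#'
#' \eqn{P(x = i \mid D) = (N_i + c_i) / (N + C)} with \eqn{C = \sum_i c_i},
#' returned on the log scale.
#'
#' @param model A [categorical_model()].
#' @param x Category index in `1..k`.
#' @return Log-probability.
#' @export
categorical_log_predictive <- function(model, x) {
  x <- as.integer(x)
  if (any(is.na(x)) || any(x < 1L) || any(x > model$k))
    stop("category index out of range")
  log(model$counts[x] + model$pseudo[x]) -
    log(sum(model$counts) + sum(model$pseudo))
}

#' Collapsed marginal likelihood of a categorical column
#'
#' The Dirichlet-multinomial evidence of the counts currently in the model:
#' the product of sequential posterior predictives in any insertion order
#' (exchangeability), evaluated in closed form with log-gamma functions.
#'
#' @param model A [categorical_model()].
#' @return Log marginal likelihood; 0 for an empty model.
#' @export
categorical_log_marginal <- function(model) {
  C <- sum(model$pseudo)
  N <- sum(model$counts)
  sum(lgamma(model$counts + model$pseudo) - lgamma(model$pseudo)) +
    lgamma(C) - lgamma(N + C)
}

#' Posterior hyperparameters of the normal-gamma model
#'
#' Conjugate update from the prior \eqn{(\mu_0, \beta_0, a_0, b_0)} and the
#' sufficient statistics \eqn{(n, \bar x, S)}:
#' \deqn{\mu_n = (\beta_0\mu_0 + n\bar x)/(\beta_0 + n),\quad
#'       \beta_n = \beta_0 + n,\quad a_n = a_0 + n/2,}
#' \deqn{b_n = b_0 + S/2 + \beta_0 n (\bar x - \mu_0)^2 / (2(\beta_0 + n)).}
#'
#' @param model A [gaussian_model()].
#' @return Named list `(mu_n, beta_n, a_n, b_n)`; equals the prior when n = 0.
#' @export
gaussian_posterior <- function(model) {
  n <- model$n
  beta_n <- model$beta0 + n
  list(mu_n = (model$beta0 * model$mu0 + n * model$xbar) / beta_n,
       beta_n = beta_n,
       a_n = model$a0 + n / 2,
       b_n = model$b0 + model$S / 2 +
         model$beta0 * n * (model$xbar - model$mu0)^2 / (2 * beta_n))
}

# Student-t log-density at x for posterior parameters p = (mu_n,beta_n,a_n,b_n).
#' @keywords internal
student_log_pdf <- function(x, p) {
  lam <- p$a_n * p$beta_n / (p$b_n * (p$beta_n + 1))
  -0.5 * log(pi) + lgamma(p$a_n + 0.5) - lgamma(p$a_n) +
    0.5 * (log(lam) - log(2 * p$a_n)) -
    (p$a_n + 0.5) * log1p(lam * (x - p$mu_n)^2 / (2 * p$a_n))
}

#' Posterior predictive density of a numeric value
#'
#' The Student-t predictive with \eqn{2a_n} degrees of freedom, location
#' \eqn{\mu_n} and precision parameter
#' \eqn{\Lambda = a_n\beta_n / (b_n(\beta_n + 1))}, evaluated in log space.
#'
#' @param model A [gaussian_model()].
#' @param x Finite numeric value (vectorized).
#' @return Log-density.
#' @export
gaussian_log_predictive <- function(model, x) {
  if (!is.numeric(x) || any(!is.finite(x))) stop("x must be finite")
  student_log_pdf(x, gaussian_posterior(model))
}

#' Collapsed marginal likelihood of a numeric column
#'
#' \deqn{p(D) = \frac{\Gamma(a_n)}{\Gamma(a_0)}
#'   \frac{b_0^{a_0}}{b_n^{a_n}}
#'   \left(\frac{\beta_0}{\beta_n}\right)^{1/2} (2\pi)^{-n/2},}
#' evaluated on the log scale; equals the chained sum of sequential
#' [gaussian_log_predictive()] terms in any insertion order.
#'
#' @param model A [gaussian_model()].
#' @return Log marginal likelihood; 0 for an empty model.
#' @export
gaussian_log_marginal <- function(model) {
  p <- gaussian_posterior(model)
  lgamma(p$a_n) - lgamma(model$a0) +
    model$a0 * log(model$b0) - p$a_n * log(p$b_n) +
    0.5 * (log(model$beta0) - log(p$beta_n)) -
    model$n / 2 * log(2 * pi)
}
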