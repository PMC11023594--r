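test_that("categorical predictive matches the closed form and normalizes", {
  m <- categorical_model(2, c(1, 1))
  expect_equal(categorical_log_predictive(m, 1), log(1 / 2))
  m <- add_row(add_row(add_row(add_row(m, 1), 1), 1), 2)  # counts (3, 1)
  expect_equal(categorical_log_predictive(m, 1), log(4 / 6))
  for (k in 2:5) {
    mm <- categorical_model(k, runif(k, 0.2, 3))
    for (x in sample(k, 7, replace = TRUE)) mm <- add_row(mm, x)
    p <- vapply(seq_len(k), function(x)
      exp(categorical_log_predictive(mm, x)), numeric(1))
    expect_equal(sum(p), 1)
  }
  expect_error(categorical_log_predictive(m, 3), "out of range")
  expect_error(categorical_log_predictive(m, 0), "out of range")
})

test_that("categorical marginal is the chained predictive, any order", {
  m <- categorical_model(2)
  expect_identical(categorical_log_marginal(m), 0)
  expect_equal(categorical_log_marginal(add_row(m, 1)), log(1 / 2))
  # counts (2, 1): all three insertion orders give the same value
  vals <- vapply(list(c(1, 1, 2), c(1, 2, 1), c(2, 1, 1)), function(ord) {
    mm <- categorical_model(2); lp <- 0
    for (x in ord) {
      lp <- lp + categorical_log_predictive(mm, x)
      mm <- add_row(mm, x)
    }
    lp
  }, numeric(1))
  expect_equal(max(vals) - min(vals), 0)
  mm <- categorical_model(2)
  for (x in c(1, 1, 2)) mm <- add_row(mm, x)
  expect_equal(categorical_log_marginal(mm), vals[1])
})

test_that("normal-gamma posterior updates follow the closed form", {
  m <- gaussian_model(mu0 = 0.7, beta0 = 2.5, a0 = 1.2, b0 = 0.4)
  expect_equal(gaussian_posterior(m),
               list(mu_n = 0.7, beta_n = 2.5, a_n = 1.2, b_n = 0.4))
  m1 <- add_row(gaussian_model(mu0 = 0, beta0 = 1, a0 = 1.5, b0 = 0.4), 2)
  p <- gaussian_posterior(m1)
  expect_equal(p$mu_n, 1)
  expect_equal(p$beta_n, 2)
  expect_equal(p$a_n, 1.5 + 0.5)
  expect_equal(p$b_n, 0.4 + 1)
  # two batches vs one batch: identical sufficient statistics and posterior
  set.seed(42)
  x <- rnorm(9, 3, 2)
  m_all <- gaussian_model(1, 2, 1, 1)
  for (xi in x) m_all <- add_row(m_all, xi)
  expect_equal(m_all$xbar, mean(x))
  expect_equal(m_all$S, sum((x - mean(x))^2))
})

test_that("Student-t predictive is symmetric, correct at n = 0, normalized", {
  m <- gaussian_model(mu0 = 1, beta0 = 2, a0 = 1.5, b0 = 0.8)
  for (xi in c(0.2, 1.8, 3)) m <- add_row(m, xi)
  p <- gaussian_posterior(m)
  expect_equal(gaussian_log_predictive(m, p$mu_n + 0.7),
               gaussian_log_predictive(m, p$mu_n - 0.7))
  # n = 0: Student-t with 2 a0 df, location mu0, Lambda = a0 b0^{-1} beta0/(beta0+1)
  m0 <- gaussian_model(mu0 = -1, beta0 = 3, a0 = 2, b0 = 1.5)
  lam <- 2 * 3 / (1.5 * 4)
  nu <- 2 * 2
  x <- 0.3
  ref <- stats::dt((x - -1) * sqrt(lam * nu / nu), df = nu, log = TRUE) +
    0.5 * log(lam)
  expect_equal(gaussian_log_predictive(m0, x), ref, tolerance = 1e-12)
  q <- integrate(Vectorize(function(x) exp(gaussian_log_predictive(m, x))),
                 -80, 80, rel.tol = 1e-9)
  expect_equal(q$value, 1, tolerance = 1e-4)
  expect_error(gaussian_log_predictive(m, Inf), "finite")
})

test_that("gaussian marginal agrees with 2-D quadrature over (mu, lambda)", {
  set.seed(3)
  mu0 <- 0.5; beta0 <- 2; a0 <- 1.5; b0 <- 0.8
  x <- rnorm(5, 1, 2)
  m <- gaussian_model(mu0, beta0, a0, b0)
  expect_identical(gaussian_log_marginal(m), 0)
  for (xi in x) m <- add_row(m, xi)
  lml <- gaussian_log_marginal(m)
  inner <- function(lam) vapply(lam, function(l) {
    f <- function(mu) {
      s <- rowSums(vapply(x, function(xi)
        dnorm(xi, mu, 1 / sqrt(l), log = TRUE), numeric(length(mu))))
      prior <- 0.5 * log(beta0 * l / (2 * pi)) -
        beta0 * l / 2 * (mu - mu0)^2 +
        a0 * log(b0) - lgamma(a0) + (a0 - 1) * log(l) - b0 * l
      exp(s + prior - lml)
    }
    integrate(f, -30, 30, rel.tol = 1e-12, abs.tol = 1e-14)$value
  }, numeric(1))
  q <- integrate(inner, 0, Inf, rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-5)
})

test_that("chain rule: marginal equals summed predictives for any order", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    # gaussian
    hy <- list(mu0 = rnorm(1), beta0 = runif(1, 0.3, 3),
               a0 = runif(1, 0.5, 3), b0 = runif(1, 0.3, 3))
    x <- rnorm(n, 2, 3)
    ref <- NULL
    for (perm in replicate(3, sample(n), simplify = FALSE)) {
      m <- gaussian_model(hy$mu0, hy$beta0, hy$a0, hy$b0); lp <- 0
      for (xi in x[perm]) {
        lp <- lp + gaussian_log_predictive(m, xi)
        m <- add_row(m, xi)
      }
      expect_equal(lp, gaussian_log_marginal(m), tolerance = 1e-8)
      if (is.null(ref)) ref <- lp else expect_equal(lp, ref, tolerance = 1e-8)
    }
    # categorical
    k <- sample(2:5, 1)
    xc <- sample(k, n, replace = TRUE)
    alpha <- runif(k, 0.2, 2)
    for (perm in replicate(3, sample(n), simplify = FALSE)) {
      m <- categorical_model(k, alpha); lp <- 0
      for (xi in xc[perm]) {
        lp <- lp + categorical_log_predictive(m, xi)
        m <- add_row(m, xi)
      }
      expect_equal(lp, categorical_log_marginal(m), tolerance = 1e-8)
    }
  }
})

test_that("add/remove round-trips restore the sufficient statistics", {
  m <- categorical_model(3)
  m <- add_row(m, 2)
  expect_identical(remove_row(add_row(m, 3), 3)$counts, m$counts)
  expect_error(remove_row(m, 1), "not present")
  expect_error(remove_row(categorical_model(2), 1), "not present")

  g <- gaussian_model(0, 1, 1, 1)
  set.seed(11)
  x <- rnorm(8, 5, 2)
  for (xi in x) g <- add_row(g, xi)
  g2 <- remove_row(add_row(g, 17.3), 17.3)
  expect_equal(g2$xbar, g$xbar, tolerance = 1e-9)
  expect_equal(g2$S, g$S, tolerance = 1e-9)
  expect_identical(g2$n, g$n)
  # incremental equals batch
  expect_equal(g$xbar, mean(x), tolerance = 1e-12)
  expect_equal(g$S, sum((x - mean(x))^2), tolerance = 1e-9)
  expect_error(remove_row(gaussian_model(), 1), "empty")
})

test_that("posterior concentrates on the truth for large samples", {
  set.seed(5)
  true_mean <- 2.5; true_sd <- 1.7
  x <- rnorm(1e4, true_mean, true_sd)
  m <- gaussian_model(mu0 = 0, beta0 = 1, a0 = 1, b0 = 1)
  m$n <- length(x); m$xbar <- mean(x); m$S <- sum((x - mean(x))^2)
  p <- gaussian_posterior(m)
  expect_lt(abs(p$mu_n - true_mean), 3 * true_sd / sqrt(1e4))
  # a_n / b_n estimates the precision
  prec_se <- (1 / true_sd^2) * sqrt(2 / 1e4)
  expect_lt(abs(p$a_n / p$b_n - 1 / true_sd^2), 3 * prec_se)
})
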