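test_that("exact enumeration matches brute force over all assignments", {
  sim <- make_mixed(n_rows = 8, n_numeric = 2, n_cat = 2, delta = 3,
                    ratio = c(1, 1), seed = 3)
  ex <- exact_log_ml(sim$data, sim$schema, 2)
  bf <- brute_force_log_ml(sim$data, sim$schema, 2)
  expect_equal(ex$log_ml, bf$log_ml, tolerance = 1e-9)
  expect_equal(ex$n_assignments, bf$n)

  sim3 <- make_mixed(n_rows = 7, n_numeric = 1, n_cat = 1, delta = 3,
                     ratio = c(1, 1, 1), seed = 5)
  ex3 <- exact_log_ml(sim3$data, sim3$schema, 3)
  bf3 <- brute_force_log_ml(sim3$data, sim3$schema, 3)
  expect_equal(ex3$log_ml, bf3$log_ml, tolerance = 1e-9)
  expect_equal(ex3$n_assignments, bf3$n)
})

test_that("exact enumeration counts and edge cases", {
  sim <- tiny_mixed(n = 3, seed = 6)
  ex <- exact_log_ml(sim$data, sim$schema, 2)
  expect_identical(ex$n_assignments, 6)      # 2^3 minus 2 empty labelings
  ex1 <- exact_log_ml(sim$data, sim$schema, 1)
  expect_equal(ex1$log_ml,
               joint_log_likelihood(sim$data, sim$schema, rep(1L, 3)))
  big <- tiny_mixed(n = 18, seed = 6)
  expect_error(exact_log_ml(big$data, big$schema, 3, max_assignments = 1e5),
               "enumeration bound exceeded")
})

test_that("AM is exact for trivial assignment spaces and deterministic", {
  one <- data.frame(x = 1.5)
  sch <- mmm_schema(c(x = "numeric"))
  est <- am_log_ml(one, sch, 1, M = 50, seed = 1)
  expect_equal(est$log_ml, joint_log_likelihood(one, sch, 1L))
  sim <- tiny_mixed(n = 10, seed = 7)
  a1 <- am_log_ml(sim$data, sim$schema, 2, M = 200, seed = 9)
  a2 <- am_log_ml(sim$data, sim$schema, 2, M = 200, seed = 9)
  expect_identical(a1$log_ml, a2$log_ml)
})

test_that("samplers are deterministic given a seed", {
  sim <- tiny_mixed(n = 12, seed = 8)
  h1 <- hm_log_ml(sim$data, sim$schema, 2, seed = 4)
  h2 <- hm_log_ml(sim$data, sim$schema, 2, seed = 4)
  expect_identical(h1$log_ml, h2$log_ml)
  t1 <- ti_log_ml(sim$data, sim$schema, 2, seed = 4)
  t2 <- ti_log_ml(sim$data, sim$schema, 2, seed = 4)
  expect_identical(t1$log_ml, t2$log_ml)
  b1 <- hmbeta_log_ml(sim$data, sim$schema, 2, seed = 4)
  b2 <- hmbeta_log_ml(sim$data, sim$schema, 2, seed = 4)
  expect_identical(b1$log_ml, b2$log_ml)
})

test_that("beta outside [0,1] and bad temperature grids are rejected", {
  sim <- tiny_mixed(n = 6, seed = 9)
  expect_error(hmbeta_log_ml(sim$data, sim$schema, 2, beta = 1.2), "beta")
  expect_error(hmbeta_log_ml(sim$data, sim$schema, 2, beta = -0.1), "beta")
  expect_error(ti_log_ml(sim$data, sim$schema, 2, n_beta = 4), "odd")
  expect_error(ti_log_ml(sim$data, sim$schema, 2, n_beta = 1), "odd")
})

test_that("TI expectations increase along the temperature ladder", {
  sim <- make_mixed(n_rows = 12, delta = 4.5, ratio = c(1, 1), seed = 201)
  ti <- ti_log_ml(sim$data, sim$schema, 2, seed = 3)
  E <- ti$settings$E_beta
  se <- ti$settings$se_beta
  slack <- 3 * (se[-1] + se[-length(se)])
  expect_true(all(diff(E) > -slack))
  # beta = 0 expectation is the prior average of the joint log-likelihood
  set.seed(99)
  labs <- mmmclust:::prior_assignments(12, 2, 400)
  prior_mean <- mean(apply(labs, 2, function(l)
    joint_log_likelihood(sim$data, sim$schema, l)))
  expect_lt(abs(E[1] - prior_mean), 3 * (se[1] + sd(apply(labs, 2, function(l)
    joint_log_likelihood(sim$data, sim$schema, l))) / 20))
})

test_that("evidence at K = 1 is the single-assignment likelihood", {
  sim <- tiny_mixed(n = 9, seed = 10)
  ll <- joint_log_likelihood(sim$data, sim$schema, rep(1L, 9))
  for (f in list(am_log_ml, hm_log_ml, ti_log_ml))
    expect_equal(f(sim$data, sim$schema, 1, seed = 1)$log_ml, ll)
  expect_equal(hmbeta_log_ml(sim$data, sim$schema, 1, seed = 1)$log_ml, ll)
})

test_that("BIC has the hand-computable closed form and a growing penalty", {
  set.seed(12)
  x <- rnorm(20, 1, 2)
  df <- data.frame(x = x)
  sch <- mmm_schema(c(x = "numeric"))
  est <- bic_log_ml(df, sch, rep(1L, 20))
  v <- mean((x - mean(x))^2)
  ll_hat <- -20 / 2 * (log(2 * pi * v) + 1)
  expect_equal(est$log_ml, ll_hat - (2 / 2) * log(20), tolerance = 1e-9)
  expect_identical(est$settings$n_params, 2)
  # penalty grows with K
  sim <- tiny_mixed(n = 30, seed = 13)
  p <- vapply(1:3, function(K) {
    f <- fit_k(sim$data, sim$schema, K, seed = 1)
    bic_log_ml(sim$data, sim$schema, f$labels)$settings$n_params
  }, numeric(1))
  expect_true(all(diff(p) > 0))
})

test_that("K selection prefers one cluster for homogeneous data", {
  # evidence gaps on unclustered data are small (a few nats), so this uses
  # thermodynamic integration, the most accurate estimator
  set.seed(14)
  df <- data.frame(x = rnorm(300), y = rnorm(300))
  sch <- mmm_schema(c(x = "numeric", y = "numeric"))
  fit <- mmm_cluster(df, sch, K_max = 3, method = "ti", seed = 2)
  expect_identical(fit$best_k, 1L)
  expect_identical(nrow(fit$evidence), 3L)
})

test_that("K selection recovers three well-separated planted clusters", {
  sim <- make_mixed(n_rows = 150, delta = 4.5, ratio = c(1, 1, 1), seed = 15)
  fit <- mmm_cluster(sim$data, sim$schema, K_max = 5, method = "hmbeta",
                     seed = 2)
  expect_identical(fit$best_k, 3L)
  expect_identical(fit$evidence$K, 1:5)
})
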