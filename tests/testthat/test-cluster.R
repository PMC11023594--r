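test_that("joint likelihood matches batch recomputation from the models", {
  sim <- make_mixed(n_rows = 30, n_numeric = 2, n_cat = 2, delta = 2,
                    ratio = c(1, 1, 1), seed = 4)
  set.seed(9)
  for (rep in 1:3) {
    lab <- sample(1:3, 30, replace = TRUE)
    expect_equal(joint_log_likelihood(sim$data, sim$schema, lab),
                 model_based_joint_ll(sim$data, sim$schema, lab),
                 tolerance = 1e-9)
  }
})

test_that("single-cluster likelihood is the sum of whole-column marginals", {
  sim <- tiny_mixed(n = 14, seed = 5)
  expect_equal(joint_log_likelihood(sim$data, sim$schema, rep(1L, 14)),
               model_based_joint_ll(sim$data, sim$schema, rep(1L, 14)))
})

test_that("empty clusters contribute nothing to the likelihood", {
  sim <- tiny_mixed(n = 10, seed = 6)
  lab_gap <- c(rep(1L, 5), rep(3L, 5))   # cluster 2 empty
  lab <- c(rep(1L, 5), rep(2L, 5))
  expect_equal(joint_log_likelihood(sim$data, sim$schema, lab_gap),
               joint_log_likelihood(sim$data, sim$schema, lab))
})

test_that("C++ joint likelihood agrees with the R implementation", {
  sim <- make_mixed(n_rows = 25, delta = 2, ratio = c(1, 1), seed = 7)
  d <- mmmclust:::new_mmm_data(sim$data, sim$schema)
  set.seed(2)
  for (K in 2:3) {
    lab <- mmmclust:::random_surjective_labels(25, K)
    expect_equal(mmmclust:::joint_ll_cpp(d, lab, K),
                 joint_log_likelihood(sim$data, sim$schema, lab),
                 tolerance = 1e-8)
  }
})

test_that("leave-one-out scores equal joint-likelihood differences", {
  sim <- make_mixed(n_rows = 24, n_numeric = 2, n_cat = 2, delta = 2,
                    ratio = c(1, 1, 1), seed = 8)
  lab <- rep(1:3, each = 8)
  for (i in c(1, 9, 20)) {
    sc <- score_row(sim$data, sim$schema, lab, i)
    ll <- vapply(1:3, function(j) {
      l2 <- lab; l2[i] <- j
      joint_log_likelihood(sim$data, sim$schema, l2)
    }, numeric(1))
    # identical up to the shared constant (likelihood with row i removed)
    expect_equal(diff(ll), diff(sc), tolerance = 1e-8)
  }
})

test_that("identical clusters give identical scores", {
  # clusters 2 and 3 hold exactly the same values; row 1 lives in cluster 1
  df <- data.frame(x = c(5, 5, 0, 0, 1, 1, 0, 0, 1, 1),
                   c = c("a", "a", "a", "b", "a", "b", "a", "b", "a", "b"))
  sch <- mmm_schema(c(x = "numeric", c = "categorical"),
                    levels = list(c = c("a", "b")))
  lab <- c(1, 1, 2, 2, 2, 2, 3, 3, 3, 3)
  sc <- score_row(df, sch, lab, 1)
  expect_equal(sc[2], sc[3])
})

test_that("fit_k recovers well-separated planted clusters", {
  sim <- make_numeric(n_rows = 200, n_cols = 1, dsigma = 1e-9, mean_gap = 10,
                      base_sd = 1, ratio = c(1, 1), seed = 2)
  f <- fit_k(sim$data, sim$schema, 2, seed = 1)
  expect_identical(f$K, 2L)
  expect_equal(adjusted_rand_index(f$labels, sim$labels), 1)
})

test_that("K = 1 is a one-pass fixed point and K > N errors", {
  sim <- tiny_mixed(n = 8, seed = 9)
  f <- fit_k(sim$data, sim$schema, 1)
  expect_identical(f$K, 1L)
  expect_identical(f$labels, rep(1L, 8))
  expect_true(f$converged)
  expect_error(fit_k(sim$data, sim$schema, 9), "between 1 and")
})

test_that("sequential mode has a monotone non-decreasing objective", {
  set.seed(10)
  for (rep in 1:20) {
    sim <- make_mixed(n_rows = 40, n_numeric = 2, n_cat = 2,
                      delta = runif(1, 0.5, 4), ratio = c(1, 1),
                      seed = 500 + rep)
    f <- fit_k(sim$data, sim$schema, 2, mode = "sequential",
               init = "random", n_restarts = 0, seed = rep)
    expect_true(all(diff(f$trace) >= -1e-8))
    expect_true(f$converged)
  }
})

test_that("batch and sequential modes reach valid assignments", {
  sim <- make_mixed(n_rows = 60, delta = 3.5, ratio = c(1, 1, 1), seed = 11)
  for (mode in c("batch", "sequential")) {
    f <- fit_k(sim$data, sim$schema, 3, mode = mode, seed = 3)
    expect_true(all(f$labels %in% seq_len(f$K)))
    expect_identical(length(unique(f$labels)), as.integer(f$K))
  }
})

test_that("row order does not change the likelihood of a fixed partition", {
  sim <- tiny_mixed(n = 16, seed = 12)
  lab <- rep(1:2, each = 8)
  perm <- sample(16)
  expect_equal(joint_log_likelihood(sim$data, sim$schema, lab),
               joint_log_likelihood(sim$data[perm, ], sim$schema, lab[perm]),
               tolerance = 1e-9)
})

test_that("warm-start split takes exactly the worst-scoring rows", {
  sim <- make_mixed(n_rows = 21, delta = 2, ratio = c(1, 1), seed = 13)
  f <- fit_k(sim$data, sim$schema, 2, seed = 1)
  lab2 <- warm_start_split(sim$data, sim$schema, f$labels)
  expect_identical(max(lab2), 3L)
  n_move <- 7L                              # floor(21 / 3)
  expect_identical(sum(lab2 == 3L), n_move)
  # moved rows are the bottom of the self-score ordering
  L <- mmmclust:::score_matrix_impl(
    mmmclust:::new_mmm_data(sim$data, sim$schema), f$labels, 2)
  self <- L[cbind(1:21, f$labels)]
  expect_setequal(which(lab2 == 3L), order(self, 1:21)[1:n_move])
})

test_that("warm-start split is deterministic under ties", {
  df <- data.frame(x = rep(1, 9))
  sch <- mmm_schema(c(x = "numeric"))
  lab <- rep(1L, 9)
  s1 <- warm_start_split(df, sch, lab)
  s2 <- warm_start_split(df, sch, lab)
  expect_identical(s1, s2)
  expect_identical(sum(s1 == 2L), 4L)   # floor(9/2)
})
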