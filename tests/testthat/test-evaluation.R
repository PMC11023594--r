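test_that("adjusted Rand index matches hand-computed cases", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})

test_that("ARI is invariant under relabeling either partition", {
  set.seed(20)
  a <- sample(1:4, 40, replace = TRUE)
  b <- sample(1:3, 40, replace = TRUE)
  ref <- adjusted_rand_index(a, b)
  perm <- sample(4)
  expect_equal(adjusted_rand_index(perm[a], b), ref)
  expect_equal(adjusted_rand_index(a, c("p", "q", "r")[b]), ref)
})

test_that("ARI equals explicit all-pairs counting on random partitions", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(5:25, 1)
    a <- sample(seq_len(sample(2:5, 1)), n, replace = TRUE)
    b <- sample(seq_len(sample(2:5, 1)), n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), brute_force_ari(a, b))
  }
})

test_that("ARI agrees with an established implementation", {
  skip_if_not_installed("mclust")
  set.seed(22)
  for (rep in 1:10) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:4, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 unname(mclust::adjustedRandIndex(a, b)))
  }
})

test_that("AUC is invariant under monotone score transformations", {
  set.seed(23)
  y <- sample(c("no", "yes"), 50, replace = TRUE)
  s <- rnorm(50) + (y == "yes")
  a1 <- mmmclust:::binary_auc(y, s, c("no", "yes"))
  a2 <- mmmclust:::binary_auc(y, exp(3 * s) + 5, c("no", "yes"))
  expect_equal(a1, a2)
})

test_that("utility harness hits the separable and chance endpoints", {
  set.seed(24)
  n <- 200
  df <- data.frame(x = rnorm(n), stringsAsFactors = FALSE)
  df$out <- ifelse(df$x > 0, "yes", "no")
  sch <- mmm_schema(c(x = "numeric", out = "categorical"),
                    levels = list(out = c("no", "yes")), output = "out")
  res <- utility_benchmark(df, df, synth = df, schema = sch,
                           model = "logistic", n_runs = 2, seed = 1)
  expect_equal(res$mean_synth, 1)
  expect_equal(res$mean_real, 1)

  df2 <- df
  df2$out <- sample(c("no", "yes"), n, replace = TRUE)   # labels independent
  res2 <- utility_benchmark(df2, df2, synth = df2, schema = sch,
                            model = "logistic", n_runs = 2, seed = 1)
  expect_lt(abs(res2$mean_synth - 0.5), 0.15)

  df3 <- df; df3$out <- "yes"
  expect_error(utility_benchmark(df3, df3, synth = df3, schema = sch,
                                 model = "logistic", n_runs = 1, seed = 1),
               "degenerate task")
})

test_that("the harness defaults to 20 runs and records versions", {
  set.seed(25)
  df <- data.frame(x = rnorm(60))
  df$out <- ifelse(df$x + rnorm(60) > 0, "yes", "no")
  sch <- mmm_schema(c(x = "numeric", out = "categorical"),
                    levels = list(out = c("no", "yes")), output = "out")
  res <- utility_benchmark(df, df, synth = function(s) df, schema = sch,
                           model = "logistic", seed = 2)
  expect_identical(res$n_runs, 20L)
  expect_length(res$auc_synth, 20L)
  expect_true("pROC" %in% names(res$versions))
})

test_that("the random-forest harness runs end to end", {
  skip_if_not_installed("ranger")
  set.seed(26)
  df <- data.frame(x = rnorm(80), g = sample(c("u", "v"), 80, TRUE))
  df$out <- ifelse(df$x + (df$g == "v") + rnorm(80, 0, 0.5) > 0.5,
                   "yes", "no")
  sch <- mmm_schema(c(x = "numeric", g = "categorical", out = "categorical"),
                    levels = list(g = c("u", "v"), out = c("no", "yes")),
                    output = "out")
  res <- utility_benchmark(df, df, synth = df, schema = sch,
                           model = "random_forest", n_runs = 2, seed = 3)
  expect_gt(res$mean_synth, 0.7)
})
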