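# MMMSynth: cluster the real table on its input columns, fit independent
# per-cluster column distributions plus a noisy linear model for the output
# column, then sample synthetic clusters of the same sizes and pool them.

# Design matrix for the per-cluster output model: numeric columns as-is,
# categorical columns one-hot with the first (reference) level dropped.
#' @keywords internal
synth_design <- function(data, schema_in) {
  cols <- list()
  for (col in schema_in) {
    x <- data[[col$name]]
    if (col$kind == "numeric") {
      cols[[col$name]] <- as.numeric(x)
    } else {
      lv <- col$levels
      xi <- match(as.character(x), lv)
      for (l in lv[-1])
        cols[[paste0(col$name, "=", l)]] <- as.numeric(lv[xi] == l)
    }
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(cols)
  mat
}

#' Fit per-cluster generative models for MMMSynth
#'
#' For each cluster: maximum-likelihood fits of every input column (observed
#' level frequencies for categorical columns; sample mean and ML standard
#' deviation for numeric columns) plus a least-squares linear model of the
#' output column on the one-hot-expanded inputs, with the residual standard
#' deviation recorded. Clusters with fewer than `min_size` (2) rows are first
#' merged into their nearest cluster by leave-one-out predictive score.
#'
#' @inheritParams joint_log_likelihood
#' @param labels Cluster labels from a clustering of the input columns.
#' @param output_model `"linear"` (default): ordinary least squares on the
#'   output (0/1 for a binary output); `"logistic"`: logistic regression for
#'   a binary output, sampled probabilistically.
#' @return An object of class `mmm_synth_models`.
#' @export
fit_cluster_models <- function(data, schema, labels,
                               output_model = c("linear", "logistic"),
                               priors = NULL) {
  output_model <- match.arg(output_model)
  out_name <- schema_output(schema)
  if (is.null(out_name)) stop("schema must flag an output column")
  schema_in <- schema_inputs(schema)
  labels <- check_labels(labels, nrow(data))

  # merge degenerate clusters (< 2 rows) into the nearest cluster by score
  repeat {
    K <- max(labels)
    sizes <- tabulate(labels, K)
    small <- which(sizes < 2L)
    if (length(small) == 0L || K - length(small) < 1L) break
    d <- new_mmm_data(data, schema_in, priors)
    L <- score_matrix_impl(d, labels, K)
    L[, small] <- -Inf
    for (i in which(labels %in% small)) labels[i] <- which.max(L[i, ])
    labels <- compact_labels(labels)$labels
  }
  K <- max(labels)

  out_col <- schema[[out_name]]
  binary <- out_col$kind == "categorical"
  if (binary && length(out_col$levels) != 2L)
    stop("a categorical output column must be binary")
  y_all <- if (binary)
    as.numeric(match(as.character(data[[out_name]]), out_col$levels) == 2L)
  else as.numeric(data[[out_name]])

  X_all <- synth_design(data, schema_in)
  models <- lapply(seq_len(K), function(j) {
    rows <- which(labels == j)
    cols <- lapply(schema_in, function(col) {
      x <- data[[col$name]][rows]
      if (col$kind == "categorical") {
        cnt <- table(factor(as.character(x), levels = col$levels))
        list(kind = "categorical", levels = col$levels,
             prob = as.numeric(cnt) / length(rows))
      } else {
        m <- mean(as.numeric(x))
        list(kind = "numeric", mean = m,
             sd = sqrt(mean((as.numeric(x) - m)^2)))
      }
    })
    names(cols) <- schema_names(schema_in)
    X <- cbind(`(Intercept)` = 1, X_all[rows, , drop = FALSE])
    y <- y_all[rows]
    if (output_model == "logistic" && binary) {
      fitg <- suppressWarnings(
        stats::glm.fit(X, y, family = stats::binomial()))
      coef <- ifelse(is.na(fitg$coefficients), 0, fitg$coefficients)
      out <- list(model = "logistic", coef = coef, sd = NA_real_)
    } else {
      fit <- stats::lm.fit(X, y)
      coef <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      res <- y - drop(X %*% coef)
      out <- list(model = "linear", coef = coef,
                  sd = sqrt(mean(res^2)))
    }
    list(size = length(rows), cols = cols, out = out)
  })
  structure(list(clusters = models, schema = schema, out_name = out_name,
                 binary = binary,
                 out_levels = if (binary) out_col$levels else NULL,
                 labels = labels),
            class = "mmm_synth_models")
}

#' Sample a synthetic table from fitted cluster models
#'
#' For each cluster, input columns are sampled independently from the fitted
#' per-cluster distributions (a synthetic cluster of the same size as the
#' real one); the output column is the linear prediction plus Gaussian noise
#' at the fitted residual sd — thresholded at 0.5 for a binary output — or a
#' Bernoulli draw for a logistic output model. Synthetic clusters are pooled
#' and rows shuffled; the result has the same schema and row count as the
#' original table. Numeric sampling is unbounded Gaussian (no clipping to the
#' observed range).
#'
#' @param models An [fit_cluster_models()] result.
#' @param seed Optional integer seed.
#' @return A data frame.
#' @export
sample_synthetic <- function(models, seed = NULL) {
  stopifnot(inherits(models, "mmm_synth_models"))
  if (!is.null(seed)) set.seed(seed)
  schema_in <- schema_inputs(models$schema)
  pieces <- lapply(models$clusters, function(cl) {
    n <- cl$size
    df <- as.data.frame(lapply(cl$cols, function(col) {
      if (col$kind == "categorical")
        sample(col$levels, n, replace = TRUE, prob = col$prob)
      else stats::rnorm(n, col$mean, col$sd)
    }), col.names = names(cl$cols), stringsAsFactors = FALSE)
    X <- cbind(1, synth_design(df, schema_in))
    eta <- drop(X %*% cl$out$coef)
    y <- if (cl$out$model == "logistic")
      stats::rbinom(n, 1, stats::plogis(eta))
    else eta + stats::rnorm(n, 0, cl$out$sd)
    if (models$binary) {
      yb <- as.numeric(y >= 0.5)
      df[[models$out_name]] <- models$out_levels[yb + 1]
    } else {
      df[[models$out_name]] <- y
    }
    df
  })
  out <- do.call(rbind, pieces)
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  out[, schema_names(models$schema), drop = FALSE]
}

#' Generate a synthetic table with MMMSynth
#'
#' End-to-end pipeline: pre-cluster the table on its input columns (the
#' output column is excluded from clustering), select the number of clusters
#' by the chosen evidence estimator, fit per-cluster generative models with
#' [fit_cluster_models()], and draw a synthetic table of the same size with
#' [sample_synthetic()].
#'
#' @inheritParams mmm_cluster
#' @param select K selection: `"hmbeta"` (default), `"ti"`, `"bic"`, or
#'   `"fixed"` (use `K`).
#' @param K Number of clusters when `select = "fixed"`.
#' @param output_model Passed to [fit_cluster_models()].
#' @return List with `data` (the synthetic table), `models`, and `report`
#'   (selected K, cluster sizes, per-column fit summaries, settings).
#' @examples
#' sim <- make_mixed(n_rows = 150, delta = 4.5, ratio = c(1, 1), seed = 2)
#' df <- sim$data
#' df$out <- ifelse(sim$labels == 1, "no", "yes")
#' sch <- mmm_schema(c(stats::setNames(rep("numeric", 5), sprintf("x%02d", 1:5)),
#'                     stats::setNames(rep("categorical", 5), sprintf("c%02d", 1:5)),
#'                     out = "categorical"),
#'                   levels = c(stats::setNames(rep(list(letters[1:4]), 5),
#'                                              sprintf("c%02d", 1:5)),
#'                              list(out = c("no", "yes"))),
#'                   output = "out")
#' syn <- mmmsynth(df, sch, select = "fixed", K = 2, seed = 1)
#' nrow(syn$data)
#' @export
mmmsynth <- function(data, schema, select = c("hmbeta", "ti", "bic", "fixed"),
                     K = NULL, K_max = 8L, beta = 0.5, M = 200L,
                     burnin = NULL, thin = NULL, seed = 1L,
                     output_model = c("linear", "logistic"),
                     mode = c("batch", "sequential"), priors = NULL) {
  select <- match.arg(select)
  output_model <- match.arg(output_model)
  mode <- match.arg(mode)
  if (is.null(schema_output(schema)))
    stop("schema must flag an output column for mmmsynth")
  schema_in <- schema_inputs(schema)

  if (select == "fixed") {
    if (is.null(K)) stop("select = 'fixed' requires K")
    fit <- fit_k(data, schema_in, K, mode = mode, seed = seed,
                 priors = priors)
    labels <- fit$labels
    evidence <- NULL
  } else {
    fit <- mmm_cluster(data, schema_in, K_max = K_max, method = select,
                       beta = beta, M = M, burnin = burnin, thin = thin,
                       mode = mode, seed = seed, priors = priors)
    labels <- fit$labels
    evidence <- fit$evidence
  }

  models <- fit_cluster_models(data, schema, labels,
                               output_model = output_model, priors = priors)
  synth <- sample_synthetic(models, seed = seed)

  report <- list(
    K = length(models$clusters),
    cluster_sizes = vapply(models$clusters, `[[`, 0L, "size"),
    select = select, seed = seed, output_model = output_model,
    evidence = evidence,
    columns = lapply(models$clusters[[1]]$cols, function(col)
      if (col$kind == "numeric") c(mean = col$mean, sd = col$sd)
      else stats::setNames(col$prob, col$levels)))
  list(data = synth, models = models, report = report)
}
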