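#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement (Hubert-Arabie form): with
#' contingency counts \eqn{n_{ij}}, row sums \eqn{a_i} and column sums
#' \eqn{b_j},
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}
#'                  {\tfrac12[\sum_i\binom{a_i}{2} + \sum_j\binom{b_j}{2}] - E},
#'       \quad E = \frac{\sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}}
#'                      {\binom{N}{2}}.}
#' 1 for identical partitions, about 0 for independent ones; invariant under
#' relabeling either partition.
#'
#' @param labels_a,labels_b Label vectors of equal length (any atomic type).
#' @return A number in \eqn{[-1, 1]}.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  N <- length(labels_a)
  if (N < 2L) stop("need at least two elements")
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(N, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (max_index - expected)
}

#' @keywords internal
binary_auc <- function(truth, score, levels) {
  r <- pROC::roc(response = factor(truth, levels = levels),
                 predictor = score, levels = levels, direction = "<",
                 quiet = TRUE)
  as.numeric(pROC::auc(r))
}

# Train one classifier and score a test table. Factor levels come from the
# schema so synthetic draws missing a level still produce a full design.
#' @keywords internal
train_and_auc <- function(train, test, schema, model) {
  out_name <- schema_output(schema)
  out_levels <- schema[[out_name]]$levels
  prep <- function(df) {
    for (col in schema) {
      if (col$kind == "categorical")
        df[[col$name]] <- factor(as.character(df[[col$name]]),
                                 levels = col$levels)
      else df[[col$name]] <- as.numeric(df[[col$name]])
    }
    df[, schema_names(schema), drop = FALSE]
  }
  train <- prep(train); test <- prep(test)
  if (length(unique(train[[out_name]])) < 2L)
    stop("degenerate task: training output has a single class")
  fml <- stats::as.formula(paste0("`", out_name, "` ~ ."))
  if (model == "logistic") {
    fit <- suppressWarnings(
      stats::glm(fml, data = train, family = stats::binomial()))
    score <- suppressWarnings(
      stats::predict(fit, newdata = test, type = "response"))
  } else {
    if (!requireNamespace("ranger", quietly = TRUE))
      stop("model = 'random_forest' requires the ranger package")
    fit <- ranger::ranger(fml, data = train, probability = TRUE,
                          num.trees = 200)
    score <- stats::predict(fit, data = test)$predictions[, out_levels[2]]
  }
  binary_auc(test[[out_name]], score, out_levels)
}

#' Train-on-synthetic / test-on-real utility benchmark
#'
#' Trains a classifier on synthetic data and measures its area under the ROC
#' curve on the real data, repeated `n_runs` times (default 20) with fresh
#' synthetic draws, alongside the reference of training on the real rows
#' themselves. By default the real test set is the training table itself
#' (resubstitution); pass a held-out `real_test` for a split protocol.
#'
#' @param real_train Real data frame (used for the reference model).
#' @param real_test Real data frame to evaluate on; defaults to `real_train`.
#' @param synth Either a fixed synthetic data frame, or a function
#'   `function(seed)` returning a fresh synthetic draw per run.
#' @param schema An [mmm_schema()] with a binary categorical output column.
#' @param model `"logistic"` or `"random_forest"`.
#' @param n_runs Number of repetitions. Default 20.
#' @param seed Integer seed.
#' @return List with per-run `auc_synth` and `auc_real`, their means and
#'   standard deviations, and the run settings (classifier library versions
#'   included).
#' @export
utility_benchmark <- function(real_train, real_test = real_train, synth,
                              schema, model = c("logistic", "random_forest"),
                              n_runs = 20L, seed = 1L) {
  model <- match.arg(model)
  out_name <- schema_output(schema)
  if (is.null(out_name)) stop("schema must flag an output column")
  if (schema[[out_name]]$kind != "categorical" ||
      length(schema[[out_name]]$levels) != 2L)
    stop("utility benchmark requires a binary categorical output")
  auc_synth <- auc_real <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seed + r)
    synth_r <- if (is.function(synth)) synth(seed + r) else synth
    auc_synth[r] <- train_and_auc(synth_r, real_test, schema, model)
    auc_real[r] <- train_and_auc(real_train, real_test, schema, model)
  }
  list(auc_synth = auc_synth, auc_real = auc_real,
       mean_synth = mean(auc_synth), sd_synth = stats::sd(auc_synth),
       mean_real = mean(auc_real), sd_real = stats::sd(auc_real),
       model = model, n_runs = n_runs, seed = seed,
       versions = c(
         pROC = as.character(utils::packageVersion("pROC")),
         ranger = if (requireNamespace("ranger", quietly = TRUE))
           as.character(utils::packageVersion("ranger")) else NA_character_))
}
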