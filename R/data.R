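# Internal typed container used by the clustering engine and samplers.
#
# num: N x Ln numeric matrix (possibly 0 columns); cat: N x Lc integer matrix
# of 1-based category indices; priors: per-column hyperparameters. Input
# columns only — the schema's output column (if any) is dropped here, since
# clustering never sees it.

#' @keywords internal
new_mmm_data <- function(data, schema, priors = NULL, include_output = FALSE) {
  stopifnot(is.data.frame(data))
  if (!include_output) schema <- schema_inputs(schema)
  nms <- schema_names(schema)
  missing_cols <- setdiff(nms, names(data))
  if (length(missing_cols))
    stop("data is missing schema column(s): ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(data)
  if (n < 1L) stop("data has no rows")

  num_cols <- nms[vapply(schema, `[[`, "", "kind") == "numeric"]
  cat_cols <- nms[vapply(schema, `[[`, "", "kind") == "categorical"]

  num <- matrix(0, n, length(num_cols),
                dimnames = list(NULL, num_cols))
  for (nm in num_cols) {
    x <- data[[nm]]
    if (is.factor(x)) x <- as.character(x)
    if (is.character(x)) {
      bad <- which(is.na(x) | x == "")
      if (length(bad))
        stop("missing value in numeric column '", nm, "', row ", bad[1L],
             "; impute or interpolate missing data upstream")
      xn <- suppressWarnings(as.numeric(x))
      if (anyNA(xn))
        stop("non-numeric entry in numeric column '", nm, "', row ",
             which(is.na(xn))[1L])
      x <- xn
    }
    if (anyNA(x))
      stop("missing value in numeric column '", nm, "', row ",
           which(is.na(x))[1L],
           "; impute or interpolate missing data upstream")
    if (any(!is.finite(x)))
      stop("non-finite value in numeric column '", nm, "', row ",
           which(!is.finite(x))[1L])
    num[, nm] <- x
  }

  cat <- matrix(0L, n, length(cat_cols),
                dimnames = list(NULL, cat_cols))
  cat_levels <- list()
  for (nm in cat_cols) {
    lv <- schema[[nm]]$levels
    x <- as.character(data[[nm]])
    if (any(is.na(x) | x == ""))
      stop("missing value in categorical column '", nm, "', row ",
           which(is.na(x) | x == "")[1L],
           "; impute or interpolate missing data upstream")
    idx <- match(x, lv)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1L]
      stop("value '", x[bad], "' in column '", nm, "', row ", bad,
           " is not among the schema levels")
    }
    cat[, nm] <- idx
    cat_levels[[nm]] <- lv
  }

  d <- list(n = n, schema = schema,
            num = num, cat = cat, cat_levels = cat_levels)
  d$priors <- priors %||% default_priors(d)
  structure(d, class = "mmm_data")
}

# Empirical-Bayes default hyperparameters: uniform Dirichlet pseudo-count 1
# for categorical columns; for numeric columns mu0 = whole-column mean,
# beta0 = 1, a0 = 1, b0 = whole-column variance so the prior matches the
# column's scale (and stands in for standardization, which we do not apply).
#' @keywords internal
default_priors <- function(d) {
  cat <- lapply(colnames(d$cat) %||% character(0), function(nm)
    rep(1, length(d$cat_levels[[nm]])))
  names(cat) <- colnames(d$cat)
  num <- lapply(colnames(d$num) %||% character(0), function(nm) {
    x <- d$num[, nm]
    v <- stats::var(x)
    if (!is.finite(v) || v <= 0) v <- 1
    list(mu0 = mean(x), beta0 = 1, a0 = 1, b0 = v)
  })
  names(num) <- colnames(d$num)
  list(cat = cat, num = num)
}

#' Hyperparameter overrides for the column models
#'
#' Builds a priors object in the shape expected by the clustering and
#' evidence functions. Any column not named keeps its empirical-Bayes
#' default (pseudo-counts 1; `mu0` = column mean, `beta0` = 1, `a0` = 1,
#' `b0` = column variance).
#'
#' @param data,schema The table and its [mmm_schema()].
#' @param pseudo Named list: categorical column name -> pseudo-count vector
#'   (recycled to the number of levels).
#' @param numeric Named list: numeric column name -> list with any of
#'   `mu0`, `beta0`, `a0`, `b0`.
#' @return A priors list usable as the `priors` argument elsewhere.
#' @export
mmm_priors <- function(data, schema, pseudo = list(), numeric = list()) {
  d <- new_mmm_data(data, schema)
  pr <- d$priors
  for (nm in names(pseudo)) {
    if (!nm %in% names(pr$cat)) stop("'", nm, "' is not a categorical column")
    p <- rep_len(as.numeric(pseudo[[nm]]), length(pr$cat[[nm]]))
    if (any(p <= 0)) stop("pseudo-counts must be positive")
    pr$cat[[nm]] <- p
  }
  for (nm in names(numeric)) {
    if (!nm %in% names(pr$num)) stop("'", nm, "' is not a numeric column")
    pr$num[[nm]] <- utils::modifyList(pr$num[[nm]], numeric[[nm]])
    with(pr$num[[nm]], stopifnot(beta0 > 0, a0 > 0, b0 > 0))
  }
  pr
}

#' Read a typed data table from CSV + schema
#'
#' Reads a comma-separated file (header row required, UTF-8, `.` decimal) and
#' validates it against the schema: no missing values are accepted (impute
#' upstream), numeric columns must parse as finite numbers, and categorical
#' values must be among the schema levels. Errors name the offending row and
#' column.
#'
#' @param path CSV file path.
#' @param schema An [mmm_schema()] or path to a schema JSON.
#' @return A data frame with columns typed per the schema.
#' @export
read_mmm_table <- function(path, schema) {
  if (is.character(schema)) schema <- read_schema(schema)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  # validation happens here; include the output column if declared
  d <- new_mmm_data(raw, schema, include_output = TRUE)
  out <- raw[, schema_names(schema), drop = FALSE]
  for (col in schema) {
    if (col$kind == "numeric") out[[col$name]] <- as.numeric(out[[col$name]])
  }
  out
}

#' @param data Data frame to write.
#' @rdname read_mmm_table
#' @export
write_mmm_table <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write 1-based cluster labels as CSV
#'
#' Two columns: `row_index`, `cluster_label`.
#'
#' @param labels Integer vector of labels in `1..K`.
#' @param path File path.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(data.frame(row_index = seq_along(labels),
                              cluster_label = as.integer(labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path)
  as.integer(df$cluster_label[order(df$row_index)])
}

#' Write a machine-readable run report
#'
#' JSON report carrying results plus the configuration, seeds and package
#' version, so every run is reproducible from its report.
#'
#' @param report Named list.
#' @param path File path.
#' @export
write_report <- function(report, path) {
  report$package <- "mmmclust"
  report$version <- as.character(utils::packageVersion("mmmclust"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
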