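#' Column schema for a mixed-type table
#'
#' A schema declares, for every column of a data table, whether it is
#' categorical (with a fixed level set) or numeric, and optionally flags one
#' column as the output (response) variable used by [mmmsynth()] and the
#' utility harness. Clustering itself never uses the output column.
#'
#' Categorical levels live in the schema, not in the observed data, so a
#' cluster that happens to miss a level still assigns it positive predictive
#' probability.
#'
#' @param kinds Named character vector mapping column names to `"categorical"`
#'   or `"numeric"`.
#' @param levels Named list of character vectors giving the level set of each
#'   categorical column. Required for every categorical column.
#' @param output Optional name of the single output column.
#' @return An object of class `mmm_schema`: a list with one entry per column,
#'   each a list with `name`, `kind`, `levels` (categorical only) and `output`.
#' @examples
#' mmm_schema(c(age = "numeric", sex = "categorical"),
#'            levels = list(sex = c("F", "M")))
#' @export
mmm_schema <- function(kinds, levels = list(), output = NULL) {
  if (is.null(names(kinds)) || any(names(kinds) == ""))
    stop("`kinds` must be a named character vector")
  bad <- setdiff(unique(kinds), c("categorical", "numeric"))
  if (length(bad))
    stop("unknown column kind(s): ", paste(bad, collapse = ", "))
  if (!is.null(output) && !output %in% names(kinds))
    stop("output column '", output, "' is not declared in `kinds`")
  cols <- lapply(names(kinds), function(nm) {
    kind <- unname(kinds[[nm]])
    lv <- NULL
    if (kind == "categorical") {
      lv <- levels[[nm]]
      if (is.null(lv) || length(lv) < 2L)
        stop("categorical column '", nm, "' needs >= 2 levels in `levels`")
      lv <- as.character(lv)
      if (anyDuplicated(lv)) stop("duplicate levels for column '", nm, "'")
    }
    list(name = nm, kind = kind, levels = lv,
         output = identical(nm, output))
  })
  names(cols) <- names(kinds)
  structure(cols, class = "mmm_schema")
}

#' @export
print.mmm_schema <- function(x, ...) {
  cat("mmm_schema with", length(x), "columns:\n")
  for (col in x) {
    extra <- if (col$kind == "categorical")
      paste0(" {", paste(col$levels, collapse = ","), "}") else ""
    out <- if (isTRUE(col$output)) "  [output]" else ""
    cat(sprintf("  %-20s %s%s%s\n", col$name, col$kind, extra, out))
  }
  invisible(x)
}

#' @keywords internal
schema_names <- function(schema) vapply(schema, `[[`, "", "name")

#' @keywords internal
schema_output <- function(schema) {
  out <- Filter(function(c) isTRUE(c$output), schema)
  if (length(out) == 0L) NULL else out[[1L]]$name
}

# Schema restricted to the input (non-output) columns.
#' @keywords internal
schema_inputs <- function(schema) {
  keep <- Filter(function(c) !isTRUE(c$output), schema)
  structure(keep, class = "mmm_schema")
}

#' Draft a schema from a data frame
#'
#' Heuristic: a column that parses as numeric with more than `max_levels`
#' distinct values is numeric; otherwise categorical with the observed values
#' as levels. Integer-valued columns with few distinct values are drafted as
#' categorical with a warning, since ordinal/integer data can legitimately be
#' treated either way — review the draft before using it.
#'
#' @param data A data frame.
#' @param max_levels Maximum number of distinct values for a column to be
#'   drafted as categorical. Default 10.
#' @param output Optional output-column name to flag in the draft.
#' @return An [mmm_schema()] draft.
#' @export
infer_schema <- function(data, max_levels = 10L, output = NULL) {
  stopifnot(is.data.frame(data), nrow(data) >= 1L)
  kinds <- character(0)
  levels <- list()
  for (nm in names(data)) {
    x <- data[[nm]]
    xc <- as.character(x)
    num <- suppressWarnings(as.numeric(xc))
    n_distinct <- length(unique(xc))
    if (!anyNA(num) && n_distinct > max_levels) {
      kinds[nm] <- "numeric"
    } else {
      if (!anyNA(num) && all(num == round(num)))
        warning("column '", nm, "': integer-valued with ", n_distinct,
                " distinct values; drafted as categorical, but ordinal data ",
                "may be treated as numeric instead", call. = FALSE)
      kinds[nm] <- "categorical"
      levels[[nm]] <- sort(unique(xc))
    }
  }
  mmm_schema(kinds, levels = levels, output = output)
}

#' Read / write a schema as JSON
#'
#' @param path File path.
#' @return `read_schema()` returns an [mmm_schema()].
#' @export
read_schema <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cols <- obj$columns
  kinds <- stats::setNames(cols$kind, cols$name)
  lev <- list()
  if (!is.null(cols$levels)) {
    for (i in seq_along(cols$name))
      if (cols$kind[[i]] == "categorical")
        lev[[cols$name[[i]]]] <- unlist(cols$levels[[i]])
  }
  output <- if (!is.null(cols$output) && any(cols$output))
    cols$name[which(cols$output)[1L]] else NULL
  mmm_schema(kinds, levels = lev, output = output)
}

#' @param schema An [mmm_schema()].
#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  cols <- data.frame(name = schema_names(schema),
                     kind = vapply(schema, `[[`, "", "kind"),
                     output = vapply(schema, function(c) isTRUE(c$output), TRUE),
                     stringsAsFactors = FALSE)
  cols$levels <- lapply(schema, function(c) c$levels)
  jsonlite::write_json(list(columns = cols), path, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}
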