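#' Declare a categorical variable
#'
#' A variable schema names a categorical variable and fixes its ordered level
#' set. The cardinality of the variable is the number of declared levels,
#' which may exceed the number of levels actually observed in any one dataset
#' (registry variables routinely carry nominal level sets larger than the
#' observed support).
#'
#' @param name Variable name (single string).
#' @param levels Character vector of distinct category labels, in the order
#'   that defines the integer coding.
#' @return An object of class `cat_var` with fields `name`, `levels` and
#'   `cardinality`.
#' @examples
#' cat_var("laterality", c("left", "right", "bilateral"))
#' @export
cat_var <- function(name, levels) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (length(levels) < 1L)
    stop("variable '", name, "' must declare at least one level")
  if (anyDuplicated(levels))
    stop("variable '", name, "' has duplicated levels")
  structure(
    list(name = name, levels = levels, cardinality = length(levels)),
    class = "cat_var"
  )
}

#' @export
print.cat_var <- function(x, ...) {
  cat("<cat_var> ", x$name, " (", x$cardinality, " levels): ",
      paste(utils::head(x$levels, 8L), collapse = ", "),
      if (x$cardinality > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Build a schema from a list of variables
#'
#' @param ... `cat_var` objects, or a single list of them.
#' @return A `cat_schema`: an ordered list of `cat_var`s.
#' @export
cat_schema <- function(...) {
  vars <- list(...)
  if (length(vars) == 1L && is.list(vars[[1]]) && !inherits(vars[[1]], "cat_var"))
    vars <- vars[[1]]
  if (!length(vars)) stop("schema needs at least one variable")
  ok <- vapply(vars, inherits, logical(1), "cat_var")
  if (!all(ok)) stop("all schema entries must be cat_var objects")
  nm <- vapply(vars, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicated variable names in schema")
  names(vars) <- nm
  structure(vars, class = "cat_schema")
}

#' @export
print.cat_schema <- function(x, ...) {
  cat("<cat_schema> ", length(x), " variables\n", sep = "")
  for (v in x)
    cat("  ", format(v$name, width = 20L), " cardinality ", v$cardinality, "\n",
        sep = "")
  invisible(x)
}

schema_cardinalities <- function(schema)
  unname(vapply(schema, `[[`, integer(1), "cardinality"))

schema_names <- function(schema)
  unname(vapply(schema, `[[`, character(1), "name"))

#' Construct a categorical dataset
#'
#' Binds an n-by-p matrix of integer level codes to a schema. Codes are
#' 1-based indices into each variable's declared level list (the natural R
#' factor coding); `decode()` recovers the labels.
#'
#' @param codes Integer matrix (n rows = records, p columns = variables), or
#'   a data frame of factors/characters which is encoded against `schema`.
#' @param schema A `cat_schema` with one entry per column.
#' @return An object of class `cat_data` with fields `codes` and `schema`.
#' @seealso [decode()], [read_cat_data()], [empirical_marginal()]
#' @export
cat_data <- function(codes, schema) {
  stopifnot(inherits(schema, "cat_schema"))
  if (is.data.frame(codes)) codes <- encode_frame(codes, schema)
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  p <- length(schema)
  if (ncol(codes) != p)
    stop("codes has ", ncol(codes), " columns but schema declares ", p,
         " variables")
  card <- schema_cardinalities(schema)
  for (j in seq_len(p)) {
    cj <- codes[, j]
    if (length(cj) && (anyNA(cj) || min(cj) < 1L || max(cj) > card[j]))
      stop("column '", schema[[j]]$name, "' contains codes outside 1..",
           card[j])
  }
  colnames(codes) <- schema_names(schema)
  structure(list(codes = codes, schema = schema), class = "cat_data")
}

encode_frame <- function(df, schema) {
  p <- length(schema)
  if (ncol(df) != p)
    stop("data has ", ncol(df), " columns but schema declares ", p)
  out <- matrix(NA_integer_, nrow(df), p)
  for (j in seq_len(p)) {
    v <- schema[[j]]
    lab <- as.character(df[[j]])
    code <- match(lab, v$levels)
    if (anyNA(code) && nrow(df)) {
      bad <- unique(lab[is.na(code)])
      stop("unknown label(s) for variable '", v$name, "': ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    out[, j] <- code
  }
  out
}

#' Number of records / variables in a dataset
#' @param data A `cat_data`.
#' @return Integer count.
#' @export
n_records <- function(data) nrow(data$codes)

#' @rdname n_records
#' @export
n_variables <- function(data) length(data$schema)

#' Decode a dataset back to labels
#'
#' @param data A `cat_data`.
#' @return A data frame of factors, one column per variable, with the full
#'   declared level set attached to each factor.
#' @export
decode <- function(data) {
  stopifnot(inherits(data, "cat_data"))
  cols <- lapply(seq_along(data$schema), function(j) {
    v <- data$schema[[j]]
    factor(v$levels[data$codes[, j]], levels = v$levels)
  })
  names(cols) <- schema_names(data$schema)
  as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
}

#' @export
print.cat_data <- function(x, ...) {
  cat("<cat_data> ", n_records(x), " records x ", n_variables(x),
      " categorical variables\n", sep = "")
  card <- schema_cardinalities(x$schema)
  cat("  cardinalities: ", paste(card, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Subset records of a dataset
#'
#' @param data A `cat_data`.
#' @param i Row indices (any form `[` accepts).
#' @return A `cat_data` over the same schema.
#' @export
subset_records <- function(data, i) {
  cat_data(data$codes[i, , drop = FALSE], data$schema)
}

#' Row-bind datasets sharing a schema
#' @param ... `cat_data` objects with identical schemas.
#' @return A `cat_data`.
#' @export
bind_records <- function(...) {
  ds <- list(...)
  stopifnot(length(ds) >= 1L)
  sc <- ds[[1]]$schema
  for (d in ds[-1])
    if (!identical(schema_names(d$schema), schema_names(sc)) ||
        !identical(schema_cardinalities(d$schema), schema_cardinalities(sc)))
      stop("datasets have incompatible schemas")
  cat_data(do.call(rbind, lapply(ds, `[[`, "codes")), sc)
}
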