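#' Read a categorical dataset from delimited text
#'
#' Records are rows, variables are columns, cells are category labels. A
#' header row carries the variable names. With no schema, each column's level
#' set is collected in first-appearance order; with a schema, every cell must
#' match one of the declared levels and unobserved levels keep their place in
#' the coding.
#'
#' @param path Path to the delimited file.
#' @param schema Optional `cat_schema` fixing names and level sets.
#' @param sep Field delimiter; comma by default.
#' @param quote Quote character used for labels embedding the delimiter.
#' @return A `cat_data`.
#' @export
read_cat_data <- function(path, schema = NULL, sep = ",", quote = "\"") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = quote,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = NULL)
  if (is.null(schema)) {
    vars <- lapply(names(df), function(nm) {
      lv <- unique(df[[nm]])
      cat_var(nm, if (length(lv)) lv else "NA")
    })
    schema <- cat_schema(vars)
  } else {
    if (!identical(names(df), schema_names(schema)))
      stop("file header does not match schema variable names")
  }
  cat_data(df, schema)
}

#' Write a categorical dataset to delimited text
#'
#' Labels containing the delimiter or quote character are quoted so that
#' `read_cat_data()` round-trips the table exactly. An empty dataset writes a
#' header-only file.
#'
#' @param data A `cat_data`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_cat_data <- function(data, path, sep = ",") {
  stopifnot(inherits(data, "cat_data"))
  df <- decode(data)
  for (j in seq_along(df)) df[[j]] <- as.character(df[[j]])
  utils::write.table(df, path, sep = sep, quote = TRUE, row.names = FALSE,
                     col.names = TRUE, qmethod = "double")
  invisible(path)
}

#' Read / write a schema sidecar file
#'
#' The sidecar is a YAML mapping from variable name to its ordered level
#' list, mirroring how registry extracts ship their codebooks.
#'
#' @param path Path to the YAML file.
#' @return `read_schema()` returns a `cat_schema`.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  cat_schema(lapply(names(raw), function(nm)
    cat_var(nm, as.character(raw[[nm]]))))
}

#' @rdname read_schema
#' @param schema A `cat_schema` to serialize.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "cat_schema"))
  out <- lapply(schema, `[[`, "levels")
  yaml::write_yaml(out, path)
  invisible(path)
}
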