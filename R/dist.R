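#' Probability mass function over a variable's levels
#'
#' @param variable A `cat_var`.
#' @param probs Non-negative numeric vector over the variable's levels,
#'   summing to one (tolerance 1e-12 after normalisation checks).
#' @return An object of class `pmf`.
#' @export
pmf <- function(variable, probs) {
  stopifnot(inherits(variable, "cat_var"))
  probs <- as.numeric(probs)
  if (length(probs) != variable$cardinality)
    stop("probs length ", length(probs), " != cardinality ",
         variable$cardinality, " of '", variable$name, "'")
  if (any(probs < 0)) stop("negative probability in pmf for '",
                           variable$name, "'")
  if (abs(sum(probs) - 1) > 1e-12)
    stop("pmf for '", variable$name, "' sums to ", sum(probs), ", not 1")
  structure(list(variable = variable, probs = probs), class = "pmf")
}

#' @export
print.pmf <- function(x, digits = 4L, ...) {
  cat("<pmf> over '", x$variable$name, "'\n", sep = "")
  print(stats::setNames(round(x$probs, digits), x$variable$levels))
  invisible(x)
}

#' Empirical marginal distribution of one variable
#'
#' Relative level frequencies in the observed records; levels declared in the
#' schema but never observed get probability zero.
#'
#' @param data A `cat_data` with at least one record.
#' @param v Variable index or name.
#' @return A `pmf`.
#' @export
empirical_marginal <- function(data, v) {
  stopifnot(inherits(data, "cat_data"))
  if (n_records(data) == 0L)
    stop("marginal undefined for an empty dataset")
  j <- resolve_variable(data$schema, v)
  var <- data$schema[[j]]
  counts <- tabulate(data$codes[, j], nbins = var$cardinality)
  pmf(var, counts / n_records(data))
}

resolve_variable <- function(schema, v) {
  if (is.character(v)) {
    j <- match(v, schema_names(schema))
    if (is.na(j)) stop("unknown variable '", v, "'")
    return(j)
  }
  j <- as.integer(v)
  if (is.na(j) || j < 1L || j > length(schema))
    stop("variable index out of range: ", v)
  j
}

#' One-hot (dummy) encoding of a dataset
#'
#' Each variable expands to a block of indicator columns, one per declared
#' level; each record has exactly one 1 per block. Used by the log-cluster
#' metric's k-means step.
#'
#' @param data A `cat_data`.
#' @return A numeric matrix with `sum(cardinalities)` columns named
#'   `variable=level`.
#' @export
one_hot <- function(data) {
  stopifnot(inherits(data, "cat_data"))
  card <- schema_cardinalities(data$schema)
  offs <- c(0L, cumsum(card))
  n <- n_records(data)
  out <- matrix(0, n, sum(card))
  for (j in seq_along(card)) {
    idx <- cbind(seq_len(n), offs[j] + data$codes[, j])
    out[idx] <- 1
  }
  colnames(out) <- unlist(lapply(data$schema, function(v)
    paste(v$name, v$levels, sep = "=")))
  out
}

#' Plug-in mutual information between two variables
#'
#' Empirical mutual information in nats from the joint contingency table;
#' `mutual_information(data, u, u)` is the empirical entropy of `u`. This is
#' the edge weight used by the Chow-Liu structure step, which picks the
#' dependency tree closest in KL divergence to the empirical joint.
#'
#' @param data A `cat_data` with at least one record.
#' @param u,v Variable indices or names.
#' @return Non-negative scalar (nats).
#' @export
mutual_information <- function(data, u, v) {
  stopifnot(inherits(data, "cat_data"), n_records(data) >= 1L)
  ju <- resolve_variable(data$schema, u)
  jv <- resolve_variable(data$schema, v)
  n <- n_records(data)
  if (ju == jv) {
    p <- tabulate(data$codes[, ju], data$schema[[ju]]$cardinality) / n
    p <- p[p > 0]
    return(-sum(p * log(p)))
  }
  du <- data$schema[[ju]]$cardinality
  dv <- data$schema[[jv]]$cardinality
  joint <- tabulate((data$codes[, ju] - 1L) * dv + data$codes[, jv],
                    nbins = du * dv) / n
  joint <- matrix(joint, du, dv, byrow = TRUE)
  pu <- rowSums(joint)
  pv <- colSums(joint)
  pos <- joint > 0
  sum(joint[pos] * log(joint[pos] / outer(pu, pv)[pos]))
}

# Draw one categorical value per row of a row-stochastic matrix P (n x d),
# using one uniform per row; fully vectorised inverse-CDF.
sample_rows <- function(P, u = stats::runif(nrow(P))) {
  n <- nrow(P); d <- ncol(P)
  if (d == 1L) return(rep(1L, n))
  cs <- P %*% upper.tri(diag(d), diag = TRUE)  # row-wise cumulative sums
  as.integer(1L + rowSums(cs < u * cs[, d]))
}

# Evaluate expr with a fixed RNG seed without disturbing the caller's stream;
# seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}
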