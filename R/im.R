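#' Independent-marginals generator
#'
#' The simplest fully synthetic generator: estimate each variable's
#' empirical marginal distribution and sample every variable independently.
#' It is the baseline of the family — cheap, trivially parallel, and by
#' construction blind to any statistical dependence between variables, so
#' its synthetic output preserves marginals but destroys joint structure.
#'
#' @param data A `cat_data` with at least one record.
#' @return An object of class `c("im_model", "synth_model")` whose
#'   `marginals` field holds one [pmf] per variable.
#' @seealso [simulate.im_model()], [fit_chow_liu()], [fit_mpom()],
#'   [fit_mice()]
#' @examples
#' d <- generate_fixture(random_tree_fixture(c(3, 2, 4), seed = 7), 500, 1)
#' m <- fit_im(d)
#' s <- simulate(m, nsim = 200, seed = 2)
#' @export
fit_im <- function(data) {
  stopifnot(inherits(data, "cat_data"))
  if (n_records(data) == 0L) stop("cannot fit on an empty dataset")
  marginals <- lapply(seq_len(n_variables(data)),
                      function(j) empirical_marginal(data, j))
  structure(list(marginals = marginals, schema = data$schema,
                 n_train = n_records(data)),
            class = c("im_model", "synth_model"))
}

#' @export
print.im_model <- function(x, ...) {
  cat("Independent-marginals generator\n")
  cat("  variables:", length(x$marginals),
      " fitted on", x$n_train, "records\n")
  invisible(x)
}

#' @export
coef.im_model <- function(object, ...) {
  stats::setNames(lapply(object$marginals, `[[`, "probs"),
                  schema_names(object$schema))
}

#' Sample synthetic records from an independent-marginals model
#'
#' @param object An `im_model`.
#' @param nsim Number of synthetic records.
#' @param seed Integer seed, or NULL to use the current RNG stream.
#' @param ... Unused.
#' @return A `cat_data` over the training schema.
#' @export
simulate.im_model <- function(object, nsim = 1L, seed = NULL, ...) {
  n <- as.integer(nsim)
  with_seed(seed, {
    codes <- vapply(object$marginals, function(m)
      sample_rows(matrix(m$probs, n, length(m$probs), byrow = TRUE)),
      integer(n))
    if (n == 1L) codes <- matrix(codes, 1L)
    cat_data(codes, object$schema)
  })
}
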