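#' Sequential conditional synthesis (MICE-style)
#'
#' Factorizes the joint distribution along a topological ordering of the
#' variables, \eqn{p(x) = \prod_v p(x_v | x_{<v})}: the first variable keeps
#' its empirical marginal and every later variable gets a probabilistic
#' classifier regressing it on all its predecessors. Synthesis then samples
#' the ordering sequentially, each variable drawn from the classifier's
#' predicted probability vector (never the argmax).
#'
#' The ordering sorts variables by cardinality, ascending or descending
#' (ties broken by schema position), or may be given explicitly.
#' Conditionals are either decision trees (rpart, Gini split criterion,
#' unrestricted growth: minsplit 2, minbucket 1, no complexity pruning) or
#' multinomial-logistic regressions (nnet::multinom on one-hot predecessors
#' with a small ridge penalty so that perfectly separable — e.g.
#' deterministic — relations still fit). A target variable with a single
#' declared level, or observed at a single level, is stored as a constant.
#'
#' @param data A `cat_data` with at least two records.
#' @param order_by `"ascending"`, `"descending"`, or an explicit integer
#'   permutation of the variable indices.
#' @param classifier `"decision-tree"` or `"multinomial-logistic"`.
#' @param decay Ridge penalty for the logistic conditionals.
#' @return An object of class `c("mice_model", "synth_model")` with fields
#'   `ordering`, `first_marginal` and `conditionals`.
#' @examples
#' d <- generate_fixture(random_tree_fixture(c(2, 3, 4), seed = 2), 1000, 1)
#' m <- fit_mice(d, order_by = "ascending", classifier = "decision-tree")
#' s <- simulate(m, nsim = 500, seed = 9)
#' @export
fit_mice <- function(data, order_by = c("ascending", "descending"),
                     classifier = c("decision-tree", "multinomial-logistic"),
                     decay = 1e-3) {
  stopifnot(inherits(data, "cat_data"))
  if (n_records(data) < 2L) stop("need at least 2 records")
  p <- n_variables(data)
  card <- schema_cardinalities(data$schema)
  if (is.numeric(order_by)) {
    ordering <- as.integer(order_by)
    if (!identical(sort(ordering), seq_len(p)))
      stop("explicit ordering must be a permutation of 1..", p)
  } else {
    order_by <- match.arg(order_by)
    ordering <- if (identical(order_by, "descending"))
      order(-card, seq_len(p)) else order(card, seq_len(p))
  }
  classifier <- match.arg(classifier)
  df <- decode(data)
  first <- ordering[1L]
  conditionals <- vector("list", p)
  for (step in seq_len(p)[-1L]) {
    target <- ordering[step]
    preds <- ordering[seq_len(step - 1L)]
    conditionals[[target]] <- fit_conditional(df, target, preds,
                                              data$schema, classifier, decay)
  }
  structure(list(ordering = ordering,
                 first_marginal = empirical_marginal(data, first),
                 conditionals = conditionals, classifier = classifier,
                 schema = data$schema, n_train = n_records(data)),
            class = c("mice_model", "synth_model"))
}

fit_conditional <- function(df, target, preds, schema, classifier, decay) {
  y <- df[[target]]
  observed <- unique(as.integer(y))
  if (schema[[target]]$cardinality == 1L || length(observed) == 1L) {
    pr <- numeric(schema[[target]]$cardinality)
    pr[observed[1L]] <- 1
    return(list(kind = "constant", probs = pr, target = target,
                preds = preds))
  }
  dtrain <- df[c(target, preds)]
  names(dtrain)[1L] <- ".y"
  dtrain$.y <- droplevels(dtrain$.y)
  if (classifier == "decision-tree") {
    fit <- rpart::rpart(.y ~ ., data = dtrain, method = "class",
                        control = rpart::rpart.control(
                          minsplit = 2L, minbucket = 1L, cp = 0,
                          maxdepth = 30L, xval = 0L))
    list(kind = "tree", fit = fit, target = target, preds = preds,
         classes = levels(y))
  } else {
    fit <- nnet::multinom(.y ~ ., data = dtrain, decay = decay,
                          trace = FALSE, maxit = 200L,
                          MaxNWts = 100000L)
    list(kind = "logistic", fit = fit, target = target, preds = preds,
         classes = levels(y))
  }
}

predict_conditional <- function(cond, newdf, schema) {
  n <- nrow(newdf)
  d <- schema[[cond$target]]$cardinality
  if (cond$kind == "constant")
    return(matrix(cond$probs, n, d, byrow = TRUE))
  nd <- newdf[cond$preds]
  if (cond$kind == "tree") {
    pr <- stats::predict(cond$fit, newdata = nd, type = "prob")
  } else {
    pr <- stats::predict(cond$fit, newdata = nd, type = "probs")
    if (is.null(dim(pr))) {  # two-class multinom returns P(second level)
      lv <- cond$fit$lev
      pr <- cbind(1 - pr, pr)
      colnames(pr) <- lv
    }
  }
  out <- matrix(0, n, d)
  colnames(out) <- schema[[cond$target]]$levels
  out[, colnames(pr)] <- pr
  out
}

#' @export
print.mice_model <- function(x, ...) {
  nm <- schema_names(x$schema)
  cat("Sequential conditional synthesizer (", x$classifier, ")\n", sep = "")
  cat("  ordering:", paste(nm[x$ordering], collapse = " -> "), "\n")
  invisible(x)
}

#' Sequential sampling from a fitted conditional chain
#'
#' The first variable in the ordering is drawn from its stored empirical
#' marginal; each later variable from its classifier's predicted
#' distribution given the values already sampled.
#'
#' @param object A `mice_model`.
#' @param nsim Number of synthetic records.
#' @param seed Integer seed, or NULL.
#' @param ... Unused.
#' @return A `cat_data`.
#' @export
simulate.mice_model <- function(object, nsim = 1L, seed = NULL, ...) {
  n <- as.integer(nsim)
  p <- length(object$schema)
  schema <- object$schema
  with_seed(seed, {
    codes <- matrix(NA_integer_, n, p)
    first <- object$ordering[1L]
    codes[, first] <- sample_rows(
      matrix(object$first_marginal$probs, n,
             schema[[first]]$cardinality, byrow = TRUE))
    df <- as.data.frame(lapply(seq_len(p), function(j)
      factor(rep(NA_character_, n), levels = schema[[j]]$levels)),
      optional = TRUE)
    names(df) <- schema_names(schema)
    df[[first]] <- factor(schema[[first]]$levels[codes[, first]],
                          levels = schema[[first]]$levels)
    for (step in seq_len(p)[-1L]) {
      target <- object$ordering[step]
      pr <- predict_conditional(object$conditionals[[target]], df, schema)
      codes[, target] <- sample_rows(pr)
      df[[target]] <- factor(schema[[target]]$levels[codes[, target]],
                             levels = schema[[target]]$levels)
    }
    cat_data(codes, schema)
  })
}
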