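#' Chow-Liu tree Bayesian network
#'
#' Learns a first-order dependency tree: the spanning tree over the
#' variables with maximum total pairwise mutual information, which among all
#' tree-shaped factorizations is closest in KL divergence to the empirical
#' joint. Conditional probability tables along the edges are estimated by
#' maximum likelihood (optionally with an add-lambda pseudo-count). The
#' resulting model factorizes the joint as the root marginal times one
#' conditional per edge, and synthetic data is drawn by ancestral sampling.
#'
#' Tie-breaking is deterministic: when two candidate edges have equal mutual
#' information the edge with the lexicographically smaller (min index, max
#' index) pair wins, and the tree is rooted at the lowest-index variable.
#' A parent level never observed in training has no maximum-likelihood
#' conditional row; such rows fall back to the child's marginal.
#'
#' @param data A `cat_data` with at least two records.
#' @param smoothing Add-lambda pseudo-count for the conditional tables;
#'   0 (default) is the pure maximum-likelihood estimate.
#' @return An object of class `c("chowliu_model", "synth_model")` with
#'   fields `root`, `edges` (parent, child), `root_marginal`, `cpts`,
#'   `edge_mi` and `tree_weight` (total mutual information of the tree).
#' @examples
#' d <- generate_fixture(random_tree_fixture(c(3, 3, 2), seed = 3), 2000, 1)
#' m <- fit_chow_liu(d)
#' summary(m)
#' @export
fit_chow_liu <- function(data, smoothing = 0) {
  stopifnot(inherits(data, "cat_data"))
  if (n_records(data) < 2L) stop("need at least 2 records to fit a tree")
  p <- n_variables(data)
  schema <- data$schema
  root <- 1L
  edges <- matrix(integer(0), 0L, 2L)
  edge_mi <- numeric(0)
  if (p > 1L) {
    pairs <- utils::combn(p, 2L)
    mi <- apply(pairs, 2L, function(uv)
      mutual_information(data, uv[1L], uv[2L]))
    und <- max_spanning_tree(p, t(pairs), mi)
    edge_mi <- und$weight
    # orient away from the root by breadth-first traversal
    adj <- lapply(seq_len(p), function(i) integer(0))
    for (e in seq_len(nrow(und$edges))) {
      a <- und$edges[e, 1L]; b <- und$edges[e, 2L]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    parent <- rep(NA_integer_, p)
    queue <- root; seen <- rep(FALSE, p); seen[root] <- TRUE
    order_out <- integer(0)
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      order_out <- c(order_out, v)
      for (w in sort(adj[[v]])) if (!seen[w]) {
        seen[w] <- TRUE; parent[w] <- v; queue <- c(queue, w)
      }
    }
    edges <- cbind(parent[order_out[-1L]], order_out[-1L])
    wkey <- paste(pmin(und$edges[, 1L], und$edges[, 2L]),
                  pmax(und$edges[, 1L], und$edges[, 2L]))
    edge_mi <- und$weight[match(paste(pmin(edges[, 1L], edges[, 2L]),
                                      pmax(edges[, 1L], edges[, 2L])), wkey)]
  }
  marg <- lapply(seq_len(p), function(j) empirical_marginal(data, j)$probs)
  cpts <- lapply(seq_len(nrow(edges)), function(e) {
    pa <- edges[e, 1L]; ch <- edges[e, 2L]
    tab <- cond_table(data$codes[, pa], data$codes[, ch],
                      schema[[pa]]$cardinality, schema[[ch]]$cardinality,
                      smoothing, fallback = marg[[ch]])
    tab
  })
  structure(list(root = root, edges = edges,
                 root_marginal = marg[[root]], cpts = cpts,
                 edge_mi = edge_mi, tree_weight = sum(edge_mi),
                 schema = schema, n_train = n_records(data),
                 smoothing = smoothing),
            class = c("chowliu_model", "synth_model"))
}

# Kruskal maximum spanning tree with deterministic tie-breaks:
# sort by (-weight, min index, max index).
max_spanning_tree <- function(p, pairs, weights) {
  ord <- order(-weights, pairs[, 1L], pairs[, 2L])
  comp <- seq_len(p)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  keep <- integer(0)
  for (e in ord) {
    a <- find(pairs[e, 1L]); b <- find(pairs[e, 2L])
    if (a != b) { comp[a] <- b; keep <- c(keep, e) }
    if (length(keep) == p - 1L) break
  }
  list(edges = pairs[keep, , drop = FALSE], weight = weights[keep])
}

cond_table <- function(pa_codes, ch_codes, dpa, dch, smoothing, fallback) {
  counts <- matrix(tabulate((pa_codes - 1L) * dch + ch_codes, dpa * dch),
                   dpa, dch, byrow = TRUE)
  counts <- counts + smoothing
  rs <- rowSums(counts)
  tab <- counts / ifelse(rs > 0, rs, 1)
  empty <- rs == 0
  if (any(empty)) tab[empty, ] <- rep(fallback, each = sum(empty))
  tab
}

#' @export
print.chowliu_model <- function(x, ...) {
  cat("Chow-Liu tree Bayesian network\n")
  cat("  variables:", length(x$schema), " edges:", nrow(x$edges),
      " tree MI weight:", format(x$tree_weight, digits = 4L), "nats\n")
  invisible(x)
}

#' @export
summary.chowliu_model <- function(object, ...) {
  nm <- schema_names(object$schema)
  df <- data.frame(parent = nm[object$edges[, 1L]],
                   child = nm[object$edges[, 2L]],
                   mi = object$edge_mi)
  structure(list(root = nm[object$root], edges = df,
                 tree_weight = object$tree_weight),
            class = "summary.chowliu_model")
}

#' @export
print.summary.chowliu_model <- function(x, ...) {
  cat("Chow-Liu tree rooted at", x$root, "\n")
  print(x$edges, row.names = FALSE)
  cat("total tree weight:", format(x$tree_weight, digits = 4L), "nats\n")
  invisible(x)
}

#' Ancestral sampling from a Chow-Liu model
#'
#' Draws the root variable from its marginal and every child from its
#' conditional table row selected by the sampled parent level, in
#' topological order.
#'
#' @param object A `chowliu_model`.
#' @param nsim Number of synthetic records.
#' @param seed Integer seed, or NULL.
#' @param ... Unused.
#' @return A `cat_data`.
#' @export
simulate.chowliu_model <- function(object, nsim = 1L, seed = NULL, ...) {
  n <- as.integer(nsim)
  p <- length(object$schema)
  with_seed(seed, {
    codes <- matrix(NA_integer_, n, p)
    codes[, object$root] <- sample_rows(
      matrix(object$root_marginal, n, length(object$root_marginal),
             byrow = TRUE))
    for (e in seq_len(nrow(object$edges))) {
      pa <- object$edges[e, 1L]; ch <- object$edges[e, 2L]
      codes[, ch] <- sample_rows(object$cpts[[e]][codes[, pa], ,
                                                  drop = FALSE])
    }
    cat_data(codes, object$schema)
  })
}

#' Undirected edge set of a fitted tree
#'
#' @param model A `chowliu_model`.
#' @return Two-column matrix of (min, max) variable indices, sorted.
#' @export
tree_edges <- function(model) {
  e <- cbind(pmin(model$edges[, 1L], model$edges[, 2L]),
             pmax(model$edges[, 1L], model$edges[, 2L]))
  e[order(e[, 1L], e[, 2L]), , drop = FALSE]
}
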