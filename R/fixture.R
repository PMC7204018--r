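#' Ground-truth fixture specifications
#'
#' A fixture spec is a fully known generative description of a categorical
#' population, used to simulate registry-like data with known structure:
#' either a rooted dependency TREE (root marginal plus per-edge conditional
#' tables) or a finite MIXTURE of products of multinomials (component
#' weights plus per-component per-variable level probabilities). Because the
#' generative truth is known, structure-recovery and metric-ordering tests
#' can score estimators against it exactly.
#'
#' @param schema A `cat_schema`.
#' @param root Root variable index.
#' @param edges Two-column integer matrix of (parent, child) indices forming
#'   a spanning tree rooted at `root`.
#' @param root_marginal Probability vector over the root's levels.
#' @param cpts List, one per edge row, of conditional tables with one row per
#'   parent level and one column per child level; rows sum to one.
#' @return An object of class `fixture_spec`.
#' @name fixture_spec
NULL

#' @rdname fixture_spec
#' @export
tree_fixture <- function(schema, root, edges, root_marginal, cpts) {
  stopifnot(inherits(schema, "cat_schema"))
  p <- length(schema)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (p > 1L && nrow(edges) != p - 1L)
    stop("a spanning tree over ", p, " variables needs ", p - 1L, " edges")
  reached <- rep(FALSE, p); reached[root] <- TRUE
  remaining <- seq_len(nrow(edges))
  while (length(remaining)) {
    grow <- remaining[reached[edges[remaining, 1L]]]
    if (!length(grow)) stop("edges do not form a tree rooted at ", root)
    if (any(reached[edges[grow, 2L]])) stop("edges revisit a variable")
    reached[edges[grow, 2L]] <- TRUE
    remaining <- setdiff(remaining, grow)
  }
  if (!all(reached)) stop("edges do not span all variables")
  check_prob_vec(root_marginal, schema[[root]]$cardinality, "root marginal")
  for (e in seq_len(nrow(edges))) {
    pa <- edges[e, 1L]; ch <- edges[e, 2L]
    tab <- cpts[[e]]
    if (!is.matrix(tab) || nrow(tab) != schema[[pa]]$cardinality ||
        ncol(tab) != schema[[ch]]$cardinality)
      stop("conditional table ", e, " has the wrong shape")
    apply(tab, 1L, check_prob_vec, d = ncol(tab), what = "conditional row")
  }
  structure(list(kind = "tree", schema = schema, root = as.integer(root),
                 edges = edges, root_marginal = as.numeric(root_marginal),
                 cpts = cpts),
            class = "fixture_spec")
}

#' @rdname fixture_spec
#' @param weights Mixture component weights summing to one.
#' @param psi List over components; each element a list over variables of
#'   level-probability vectors.
#' @export
mixture_fixture <- function(schema, weights, psi) {
  stopifnot(inherits(schema, "cat_schema"))
  check_prob_vec(weights, length(weights), "mixture weights")
  card <- schema_cardinalities(schema)
  if (length(psi) != length(weights))
    stop("psi must have one entry per mixture component")
  for (h in seq_along(psi)) {
    if (length(psi[[h]]) != length(schema))
      stop("component ", h, " must cover every variable")
    for (j in seq_along(card))
      check_prob_vec(psi[[h]][[j]], card[j],
                     paste0("psi[", h, "][", j, "]"))
  }
  structure(list(kind = "mixture", schema = schema,
                 weights = as.numeric(weights), psi = psi),
            class = "fixture_spec")
}

check_prob_vec <- function(x, d, what) {
  x <- as.numeric(x)
  if (length(x) != d || any(x < 0) || abs(sum(x) - 1) > 1e-8)
    stop(what, " is not a probability vector over ", d, " levels")
  invisible(TRUE)
}

#' @export
print.fixture_spec <- function(x, ...) {
  cat("<fixture_spec> ", x$kind, " over ", length(x$schema),
      " variables (cardinalities ",
      paste(schema_cardinalities(x$schema), collapse = " "), ")\n", sep = "")
  if (x$kind == "mixture")
    cat("  ", length(x$weights), " components\n", sep = "")
  invisible(x)
}

rdirichlet1 <- function(d, conc) {
  g <- stats::rgamma(d, shape = conc)
  while (sum(g) <= 0) g <- stats::rgamma(d, shape = conc)
  g / sum(g)
}

#' Random registry-like fixture specs
#'
#' Convenience builders that draw a fixture spec at random. Probability rows
#' come from a symmetric Dirichlet with concentration `imbalance`; values
#' below one concentrate mass on a few dominant levels, reproducing the
#' strongly imbalanced level histograms typical of cancer-registry
#' variables. The default cardinality range (up to 14 levels) matches a
#' small registry variable profile.
#'
#' @param cardinalities Integer vector of level counts, one per variable.
#' @param imbalance Dirichlet concentration (< 1 = imbalanced levels).
#' @param seed Integer seed; the builders are deterministic given it.
#' @return A `fixture_spec`.
#' @export
random_tree_fixture <- function(cardinalities, imbalance = 0.4, seed = 1L) {
  card <- as.integer(cardinalities)
  p <- length(card)
  schema <- cat_schema(lapply(seq_len(p), function(j)
    cat_var(paste0("v", j), paste0("L", seq_len(card[j])))))
  with_seed(seed, {
    edges <- if (p > 1L)
      cbind(vapply(2:p, function(j) sample.int(j - 1L, 1L), integer(1)), 2:p)
    else
      matrix(integer(0), 0L, 2L)
    root_marginal <- rdirichlet1(card[1L], 1)
    cpts <- lapply(seq_len(nrow(edges)), function(e) {
      pa <- edges[e, 1L]; ch <- edges[e, 2L]
      tab <- matrix(0, card[pa], card[ch])
      for (i in seq_len(card[pa])) tab[i, ] <- rdirichlet1(card[ch], imbalance)
      tab
    })
    tree_fixture(schema, 1L, edges, root_marginal, cpts)
  })
}

#' @rdname random_tree_fixture
#' @param k Number of mixture components.
#' @export
random_mixture_fixture <- function(cardinalities, k = 3L, imbalance = 0.4,
                                   seed = 1L) {
  card <- as.integer(cardinalities)
  schema <- cat_schema(lapply(seq_along(card), function(j)
    cat_var(paste0("v", j), paste0("L", seq_len(card[j])))))
  with_seed(seed, {
    weights <- rdirichlet1(k, 5)
    psi <- lapply(seq_len(k), function(h)
      lapply(card, rdirichlet1, conc = imbalance))
    mixture_fixture(schema, weights, psi)
  })
}

#' Simulate a dataset from a fixture spec
#'
#' TREE specs draw the root from its marginal and then each child from its
#' conditional table along the edges; MIXTURE specs draw a component per
#' record and then every variable independently from that component's level
#' probabilities. A given (spec, n, seed) triple always yields the same
#' dataset.
#'
#' @param spec A `fixture_spec`.
#' @param n Number of records (>= 0).
#' @param seed Integer seed, or NULL to use the current RNG stream.
#' @return A `cat_data`.
#' @export
generate_fixture <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "fixture_spec"), n >= 0L)
  n <- as.integer(n)
  p <- length(spec$schema)
  with_seed(seed, {
    codes <- matrix(NA_integer_, n, p)
    if (n > 0L) {
      if (spec$kind == "tree") {
        codes[, spec$root] <- sample_rows(
          matrix(spec$root_marginal, n, length(spec$root_marginal),
                 byrow = TRUE))
        remaining <- seq_len(max(nrow(spec$edges), 0L))
        done <- rep(FALSE, p); done[spec$root] <- TRUE
        while (length(remaining)) {
          for (e in remaining) {
            pa <- spec$edges[e, 1L]
            if (!done[pa]) next
            ch <- spec$edges[e, 2L]
            codes[, ch] <- sample_rows(spec$cpts[[e]][codes[, pa], ,
                                                      drop = FALSE])
            done[ch] <- TRUE
            remaining <- setdiff(remaining, e)
          }
        }
      } else {
        z <- sample_rows(matrix(spec$weights, n, length(spec$weights),
                                byrow = TRUE))
        for (j in seq_len(p)) {
          probs <- do.call(rbind, lapply(spec$psi, `[[`, j))
          codes[, j] <- sample_rows(probs[z, , drop = FALSE])
        }
      }
    }
    cat_data(codes, spec$schema)
  })
}

#' Exact joint distribution of a small fixture
#'
#' Enumerates the full joint table of a fixture spec; exponential in the
#' number of variables, intended for oracle checks on toy specs.
#'
#' @param spec A `fixture_spec` with a small level-combination count.
#' @return Array of joint probabilities with one dimension per variable.
#' @export
fixture_joint <- function(spec) {
  card <- schema_cardinalities(spec$schema)
  if (prod(card) > 1e6) stop("joint table too large to enumerate")
  grid <- as.matrix(expand.grid(lapply(card, seq_len)))
  pr <- if (spec$kind == "mixture") {
    rowSums(vapply(seq_along(spec$weights), function(h) {
      ph <- rep(spec$weights[h], nrow(grid))
      for (j in seq_along(card)) ph <- ph * spec$psi[[h]][[j]][grid[, j]]
      ph
    }, numeric(nrow(grid))))
  } else {
    ph <- spec$root_marginal[grid[, spec$root]]
    for (e in seq_len(nrow(spec$edges))) {
      pa <- spec$edges[e, 1L]; ch <- spec$edges[e, 2L]
      ph <- ph * spec$cpts[[e]][cbind(grid[, pa], grid[, ch])]
    }
    ph
  }
  array(pr, dim = card)
}
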