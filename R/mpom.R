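#' Truncated Dirichlet-process mixture of product multinomials
#'
#' Fits a latent-class model in which, conditionally on a cluster
#' indicator, every variable is an independent multinomial:
#' \deqn{p(x_1 = c_1, \dots, x_p = c_p) = \sum_{h=1}^{k} \nu_h \prod_j
#' \psi^{(j)}_{h c_j}.}
#' The component weights carry a truncated stick-breaking (Dirichlet
#' process) prior with concentration `alpha`, and each level-probability
#' vector a flat symmetric Dirichlet(1) prior, making the model fully
#' conjugate. Inference is a blocked Gibbs sampler alternating
#' (a) cluster indicators z_i drawn proportional to
#' \eqn{\nu_h \prod_j \psi^{(j)}_{h, x_{ij}}},
#' (b) each \eqn{\psi^{(j)}_h} from its Dirichlet full conditional
#' (prior pseudo-counts plus within-cluster level counts), and
#' (c) stick fractions \eqn{V_h \sim Beta(1 + n_h, \alpha + \sum_{l>h}
#' n_l)} with \eqn{\nu_h = V_h \prod_{l<h} (1 - V_l)} and \eqn{V_k = 1}.
#' Every `thin`-th post-burn-in draw of (nu, psi) is retained.
#'
#' The defaults (k = 30 components, alpha = 10, 10000 sweeps with 1000
#' burn-in) are the full-scale registry settings; structure-recovery tests
#' in this package run a scaled-down budget (k = 10, 500 sweeps, 100
#' burn-in), which suffices on the fixture populations.
#'
#' @param data A `cat_data` with at least one record.
#' @param k Truncation level (maximum number of clusters).
#' @param alpha Dirichlet-process concentration parameter.
#' @param n_iter Total Gibbs sweeps.
#' @param burn_in Sweeps discarded before retaining draws.
#' @param thin Retain every `thin`-th post-burn-in draw.
#' @param seed Integer seed for the sampler.
#' @return An object of class `c("mpom_model", "synth_model")`: fields `k`,
#'   `alpha`, `nu` and `psi` (final draw), `retained` (list of retained
#'   (nu, psi) draws), and `z` (final cluster assignment).
#' @examples
#' d <- generate_fixture(random_mixture_fixture(c(2, 2, 3), k = 2, seed = 5),
#'                       400, 1)
#' m <- fit_mpom(d, k = 5, n_iter = 100, burn_in = 20, seed = 1)
#' table(m$z)
#' @export
fit_mpom <- function(data, k = 30L, alpha = 10, n_iter = 10000L,
                     burn_in = 1000L, thin = 10L, seed = NULL) {
  stopifnot(inherits(data, "cat_data"))
  n <- n_records(data)
  if (n < 1L) stop("cannot fit on an empty dataset")
  k <- as.integer(k); n_iter <- as.integer(n_iter)
  burn_in <- as.integer(burn_in); thin <- as.integer(thin)
  if (k < 1L || n_iter <= burn_in || thin < 1L)
    stop("invalid sampler settings: need k >= 1, n_iter > burn_in, thin >= 1")
  p <- n_variables(data)
  card <- schema_cardinalities(data$schema)
  x <- data$codes
  with_seed(seed, {
    # initialise from the prior predictive: random assignments, smoothed
    # within-cluster frequencies
    z <- sample.int(k, n, replace = TRUE)
    nu <- rep(1 / k, k)
    psi <- draw_psi(x, z, k, card)
    retained <- list()
    for (it in seq_len(n_iter)) {
      # (a) cluster indicators
      lw <- matrix(log(nu), n, k, byrow = TRUE)
      for (j in seq_len(p))
        lw <- lw + log(psi[[j]])[x[, j], , drop = FALSE]
      lw <- exp(lw - apply(lw, 1L, max))
      z <- sample_rows(lw)
      # (b) level probabilities
      psi <- draw_psi(x, z, k, card)
      # (c) stick-breaking weights
      nh <- tabulate(z, k)
      tail_n <- rev(cumsum(rev(nh)))[-1L]
      v <- c(stats::rbeta(k - 1L, 1 + nh[-k], alpha + tail_n), 1)
      nu <- v * cumprod(c(1, 1 - v[-k]))
      if (it > burn_in && (it - burn_in) %% thin == 0L)
        retained[[length(retained) + 1L]] <- list(nu = nu, psi = psi)
    }
    structure(list(k = k, alpha = alpha, nu = nu, psi = psi,
                   retained = retained, z = z, schema = data$schema,
                   n_train = n,
                   settings = list(n_iter = n_iter, burn_in = burn_in,
                                   thin = thin)),
              class = c("mpom_model", "synth_model"))
  })
}

# Dirichlet(1 + counts) full-conditional draw of the per-cluster
# per-variable level probabilities; psi[[j]] is card[j] x k.
draw_psi <- function(x, z, k, card) {
  n <- nrow(x)
  lapply(seq_along(card), function(j) {
    counts <- matrix(tabulate((z - 1L) * card[j] + x[, j], k * card[j]),
                     card[j], k)
    g <- matrix(stats::rgamma(card[j] * k, shape = counts + 1), card[j], k)
    sweep(g, 2L, colSums(g), "/")
  })
}

#' @export
print.mpom_model <- function(x, ...) {
  occ <- sum(tabulate(x$z, x$k) > 0)
  cat("Mixture of product multinomials (truncated DP, Gibbs)\n")
  cat("  truncation k:", x$k, " alpha:", x$alpha,
      " occupied clusters (final draw):", occ, "\n")
  cat("  retained posterior draws:", length(x$retained), "\n")
  invisible(x)
}

#' @export
summary.mpom_model <- function(object, ...) {
  nh <- tabulate(object$z, object$k)
  ord <- order(nh, decreasing = TRUE)
  data.frame(cluster = ord, size = nh[ord], weight = object$nu[ord])
}

#' Sample synthetic records from a fitted mixture
#'
#' Each record draws a component from the weights and then every variable
#' independently from that component's level probabilities. With
#' `pool_draws = TRUE` (default) each record uses a retained posterior draw
#' chosen uniformly at random — an approximation to the posterior
#' predictive; otherwise all records use the final retained draw.
#'
#' @param object An `mpom_model` with at least one retained draw.
#' @param nsim Number of synthetic records.
#' @param seed Integer seed, or NULL.
#' @param pool_draws Pool retained posterior draws per record.
#' @param ... Unused.
#' @return A `cat_data`.
#' @export
simulate.mpom_model <- function(object, nsim = 1L, seed = NULL,
                                pool_draws = TRUE, ...) {
  n <- as.integer(nsim)
  if (!length(object$retained)) stop("model has no retained draws")
  p <- length(object$schema)
  with_seed(seed, {
    draw_id <- if (pool_draws)
      sample.int(length(object$retained), n, replace = TRUE)
    else
      rep(length(object$retained), n)
    codes <- matrix(NA_integer_, n, p)
    for (d in unique(draw_id)) {
      rows <- which(draw_id == d)
      dr <- object$retained[[d]]
      z <- sample_rows(matrix(dr$nu, length(rows), object$k, byrow = TRUE))
      for (j in seq_len(p))
        codes[rows, j] <- sample_rows(t(dr$psi[[j]])[z, , drop = FALSE])
    }
    cat_data(codes, object$schema)
  })
}

#' Posterior component profiles of a fitted mixture
#'
#' Summarizes the retained posterior draws into `top` component profiles.
#' A truncated DP posterior routinely splits one true population component
#' across several clusters (fragmentation) and permutes cluster labels
#' between draws (label switching), so per-cluster averages are biased
#' summaries. With `merge = TRUE` (default) every retained (weight, psi)
#' atom across draws is pooled and grouped into `top` groups by a
#' deterministic weighted k-means on the flattened psi vectors
#' (farthest-point initialization from the heaviest atom); each group
#' reports its total weight share and its weight-averaged level
#' probabilities, which debiases fragment specialization. With
#' `merge = FALSE` the `top` clusters with largest mean weight are averaged
#' across draws by raw cluster index.
#'
#' @param model An `mpom_model` with retained draws.
#' @param top Number of component profiles to report.
#' @param merge Pool and merge cluster atoms across draws (recommended).
#' @return List with `weights` (length `top`, decreasing) and `psi` (list
#'   over components of lists over variables of level-probability vectors).
#' @export
mpom_components <- function(model, top = 2L, merge = TRUE) {
  stopifnot(length(model$retained) >= 1L)
  p <- length(model$schema)
  if (!merge) {
    nu_bar <- Reduce(`+`, lapply(model$retained, `[[`, "nu")) /
      length(model$retained)
    ord <- order(nu_bar, decreasing = TRUE)[seq_len(top)]
    psi_bar <- lapply(ord, function(h)
      lapply(seq_len(p), function(j) {
        v <- Reduce(`+`, lapply(model$retained, function(d) d$psi[[j]][, h]))
        v / length(model$retained)
      }))
    return(list(weights = nu_bar[ord], psi = psi_bar))
  }
  # pool atoms: one row per (draw, cluster), flattened psi, weight nu
  atoms <- do.call(rbind, lapply(model$retained, function(d)
    do.call(rbind, lapply(seq_len(model$k), function(h)
      c(d$nu[h], unlist(lapply(d$psi, function(m) m[, h])))))))
  w <- atoms[, 1L]
  X <- atoms[, -1L, drop = FALSE]
  keep <- w > 1e-6
  w <- w[keep]; X <- X[keep, , drop = FALSE]
  # farthest-point initialization, then weighted Lloyd iterations
  centers <- X[which.max(w), , drop = FALSE]
  while (nrow(centers) < top) {
    dmin <- apply(X, 1L, function(x)
      min(colSums((t(centers) - x)^2)))
    centers <- rbind(centers, X[which.max(dmin * w), ])
  }
  for (it in seq_len(50L)) {
    assign <- apply(X, 1L, function(x)
      which.min(colSums((t(centers) - x)^2)))
    new_centers <- centers
    for (g in seq_len(top)) {
      rows <- assign == g
      if (any(rows))
        new_centers[g, ] <- colSums(X[rows, , drop = FALSE] * w[rows]) /
          sum(w[rows])
    }
    if (max(abs(new_centers - centers)) < 1e-10) { centers <- new_centers; break }
    centers <- new_centers
  }
  wt <- vapply(seq_len(top), function(g) sum(w[assign == g]), numeric(1))
  wt <- wt / sum(w)
  ord <- order(wt, decreasing = TRUE)
  card <- schema_cardinalities(model$schema)
  offs <- c(0L, cumsum(card))
  psi_out <- lapply(ord, function(g)
    lapply(seq_len(p), function(j) {
      v <- centers[g, (offs[j] + 1L):offs[j + 1L]]
      v / sum(v)
    }))
  list(weights = wt[ord], psi = psi_out)
}
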