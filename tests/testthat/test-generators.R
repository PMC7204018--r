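test_that("independent-marginals fit matches per-column tallies and ignores dependence", {
  spec <- correlated_tree_spec()
  d <- generate_fixture(spec, 2000, seed = 1)
  m <- fit_im(d)
  for (j in seq_len(n_variables(d)))
    expect_equal(m$marginals[[j]]$probs, oracle_marginal(d, j))

  # constant columns give degenerate marginals
  schema <- binary_schema(2)
  const <- cat_data(matrix(1L, 50L, 2L), schema)
  mc <- fit_im(const)
  expect_equal(mc$marginals[[1]]$probs, c(1, 0))

  # perfectly correlated binary columns: IM samples as if independent,
  # so the joint (1,1) frequency approaches p0^2, not p0
  p0 <- 0.7
  codes <- ifelse(stats::runif(4000) < p0, 1L, 2L)
  dep <- cat_data(cbind(codes, codes), schema)
  s <- simulate(fit_im(dep), nsim = 20000, seed = 3)
  f11 <- mean(s$codes[, 1L] == 1L & s$codes[, 2L] == 1L)
  expect_lt(abs(f11 - mean(codes == 1L)^2), 0.02)
  expect_gt(abs(f11 - mean(codes == 1L)), 0.1)
})

test_that("mutual information matches direct evaluation and is symmetric", {
  # independent uniform binary columns
  set.seed(10)
  schema <- binary_schema(2)
  ind <- cat_data(cbind(sample(1:2, 10000, TRUE), sample(1:2, 10000, TRUE)),
                  schema)
  expect_lt(mutual_information(ind, 1, 2), 0.01)

  # mass 0.5 on (1,1) and 0.5 on (2,2): MI = ln 2
  two <- cat_data(cbind(rep(1:2, each = 50), rep(1:2, each = 50)), schema)
  expect_equal(mutual_information(two, 1, 2), log(2))

  spec <- correlated_tree_spec()
  d <- generate_fixture(spec, 500, seed = 2)
  for (pair in list(c(1, 2), c(3, 5), c(4, 6))) {
    u <- pair[1]; v <- pair[2]
    expect_equal(mutual_information(d, u, v),
                 oracle_mi(d$codes[, u], d$codes[, v],
                           d$schema[[u]]$cardinality,
                           d$schema[[v]]$cardinality))
    expect_equal(mutual_information(d, u, v), mutual_information(d, v, u))
  }
})

test_that("Chow-Liu recovers a strong chain and matches the brute-force tree weight", {
  d <- generate_fixture(chain_spec(), 20000, seed = 3)
  m <- fit_chow_liu(d)
  expect_equal(tree_edges(m), rbind(c(1L, 2L), c(2L, 3L)))

  # exhaustive spanning-tree enumeration oracle, p = 4 and 5
  for (pp in 4:5) {
    spec <- random_tree_fixture(rep(3L, pp), imbalance = 0.5, seed = pp)
    dd <- generate_fixture(spec, 1500, seed = pp)
    mm <- fit_chow_liu(dd)
    pairs <- t(utils::combn(pp, 2L))
    mi <- apply(pairs, 1L, function(uv)
      mutual_information(dd, uv[1L], uv[2L]))
    expect_equal(mm$tree_weight, oracle_max_tree_weight(pp, mi))
  }

  # mutually independent columns: any tree has near-zero weight
  set.seed(44)
  ind <- cat_data(matrix(sample(1:2, 4 * 20000, TRUE), ncol = 4L),
                  binary_schema(4))
  expect_lt(fit_chow_liu(ind)$tree_weight, 0.02)
})

test_that("ancestral sampling follows the fitted factorization", {
  # deterministic CPTs: child copies parent exactly
  d <- generate_fixture(copy_spec(), 2000, seed = 4)
  m <- fit_chow_liu(d)
  s <- simulate(m, nsim = 1000, seed = 5)
  expect_identical(s$codes[, 1L], s$codes[, 2L])
  expect_identical(simulate(m, 500, seed = 6)$codes,
                   simulate(m, 500, seed = 6)$codes)

  # sampled joint matches p(root) * p(child | root) within 0.02 TV
  spec <- chain_spec()
  d2 <- generate_fixture(spec, 5000, seed = 7)
  m2 <- fit_chow_liu(cat_data(d2$codes[, 1:2], binary_schema(2)))
  s2 <- simulate(m2, nsim = 20000, seed = 8)
  joint <- m2$root_marginal * m2$cpts[[1]]  # [root, child] = p(r) p(c | r)
  expect_lt(tv_dist(empirical_joint(s2), as.vector(joint)), 0.02)
})

test_that("single-variable and smoothed Chow-Liu fits behave", {
  schema <- cat_schema(cat_var("only", c("A", "B", "C")))
  d <- cat_data(matrix(c(1L, 2L, 1L, 3L), 4L, 1L), schema)
  m <- fit_chow_liu(d)
  expect_identical(nrow(m$edges), 0L)
  s <- simulate(m, 100, seed = 1)
  expect_identical(n_variables(s), 1L)

  d2 <- generate_fixture(chain_spec(), 200, seed = 9)
  msm <- fit_chow_liu(d2, smoothing = 1)
  for (tab in msm$cpts) {
    expect_true(all(tab > 0))
    expect_equal(unname(rowSums(tab)), rep(1, nrow(tab)))
  }
})

test_that("MPoM with k = 1 collapses to smoothed independent marginals", {
  spec <- correlated_tree_spec()
  d <- generate_fixture(spec, 1000, seed = 10)
  m <- fit_mpom(d, k = 1, alpha = 10, n_iter = 200, burn_in = 50,
                thin = 5, seed = 1)
  expect_equal(m$nu, 1)
  comp <- mpom_components(m, top = 1, merge = FALSE)
  n <- n_records(d)
  for (j in seq_len(n_variables(d))) {
    card <- d$schema[[j]]$cardinality
    smoothed <- (oracle_marginal(d, j) * n + 1) / (n + card)
    # posterior mean of Dirichlet(1 + counts) equals the add-one marginal
    expect_lt(tv_dist(comp$psi[[1]][[j]], smoothed), 0.02)
  }
})

test_that("MPoM Gibbs is deterministic given a seed and validates settings", {
  d <- generate_fixture(two_component_spec(), 300, seed = 2)
  a <- fit_mpom(d, k = 5, n_iter = 60, burn_in = 20, thin = 4, seed = 9)
  b <- fit_mpom(d, k = 5, n_iter = 60, burn_in = 20, thin = 4, seed = 9)
  expect_identical(a$retained, b$retained)
  expect_identical(a$z, b$z)
  expect_error(fit_mpom(d, k = 0), "invalid sampler settings")
  expect_error(fit_mpom(d, n_iter = 50, burn_in = 50),
               "invalid sampler settings")
})

test_that("MPoM sampling matches the model's exact mixture joint", {
  # single degenerate component: all records identical
  schema <- binary_schema(2)
  dg <- structure(list(k = 1L, alpha = 10, nu = 1,
                       psi = list(matrix(c(1, 0), 2L, 1L),
                                  matrix(c(0, 1), 2L, 1L)),
                       retained = list(list(nu = 1,
                                            psi = list(matrix(c(1, 0), 2L, 1L),
                                                       matrix(c(0, 1), 2L, 1L)))),
                       z = NULL, schema = schema, n_train = 0L),
                  class = c("mpom_model", "synth_model"))
  s <- simulate(dg, nsim = 50, seed = 1)
  expect_true(all(s$codes[, 1L] == 1L & s$codes[, 2L] == 2L))

  # 2-variable 2-component model: sampled joint within 0.03 TV of exact
  psi <- list(matrix(c(0.8, 0.2, 0.3, 0.7), 2L, 2L),   # var 1: comps in cols
              matrix(c(0.1, 0.9, 0.6, 0.4), 2L, 2L))
  mm <- structure(list(k = 2L, alpha = 10, nu = c(0.4, 0.6), psi = psi,
                       retained = list(list(nu = c(0.4, 0.6), psi = psi)),
                       z = NULL, schema = schema, n_train = 0L),
                  class = c("mpom_model", "synth_model"))
  s2 <- simulate(mm, nsim = 20000, seed = 2)
  exact <- numeric(4)
  for (a in 1:2) for (b in 1:2)
    exact[(b - 1) * 2 + a] <- sum(c(0.4, 0.6) * psi[[1]][a, ] * psi[[2]][b, ])
  expect_lt(tv_dist(empirical_joint(s2), exact), 0.03)
  expect_identical(simulate(mm, 100, seed = 3)$codes,
                   simulate(mm, 100, seed = 3)$codes)
  none <- mm; none$retained <- list()
  expect_error(simulate(none, 10, seed = 1), "retained")
})

test_that("MPoM with k = 1 and IM are statistically indistinguishable", {
  spec <- correlated_tree_spec()
  d <- generate_fixture(spec, 2000, seed = 13)
  s_im <- simulate(fit_im(d), nsim = 10000, seed = 21)
  m1 <- fit_mpom(d, k = 1, n_iter = 150, burn_in = 50, thin = 5, seed = 22)
  s_m1 <- simulate(m1, nsim = 10000, seed = 23)
  for (j in seq_len(n_variables(d))) {
    tab <- rbind(tabulate(s_im$codes[, j], d$schema[[j]]$cardinality),
                 tabulate(s_m1$codes[, j], d$schema[[j]]$cardinality))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    expect_gt(p, 0.001)
  }
})

test_that("MICE ordering sorts by cardinality with schema-position ties", {
  schema <- cat_schema(cat_var("a", paste0("l", 1:3)),
                       cat_var("b", paste0("l", 1:2)),
                       cat_var("c", paste0("l", 1:5)))
  set.seed(1)
  d <- cat_data(cbind(sample(1:3, 50, TRUE), sample(1:2, 50, TRUE),
                      sample(1:5, 50, TRUE)), schema)
  expect_identical(fit_mice(d, "ascending")$ordering, c(2L, 1L, 3L))
  expect_identical(fit_mice(d, "descending")$ordering, c(3L, 1L, 2L))
  # ties broken by schema position
  schema2 <- binary_schema(3)
  d2 <- cat_data(matrix(sample(1:2, 90, TRUE), 30L, 3L), schema2)
  expect_identical(fit_mice(d2, "ascending")$ordering, 1:3)
  expect_identical(fit_mice(d2, order_by = c(3, 1, 2))$ordering, c(3L, 1L, 2L))
})

test_that("MICE decision-tree conditionals capture a deterministic copy", {
  d <- generate_fixture(copy_spec(), 2000, seed = 5)
  m <- fit_mice(d, "ascending", "decision-tree")
  s <- simulate(m, nsim = 2000, seed = 6)
  expect_gte(mean(s$codes[, 1L] == s$codes[, 2L]), 0.99)
  expect_identical(simulate(m, 300, seed = 7)$codes,
                   simulate(m, 300, seed = 7)$codes)
})

test_that("MICE logistic conditionals approximate the true tree conditionals", {
  spec <- chain_spec()
  d <- generate_fixture(spec, 10000, seed = 8)
  m <- fit_mice(d, "ascending", "multinomial-logistic")
  # predictive p(v2 | v1) against the fixture's conditional table
  cond <- m$conditionals[[2L]]
  newdf <- decode(cat_data(cbind(1:2, rep(1L, 2), rep(1L, 2)),
                           d$schema))
  pr <- synthcat:::predict_conditional(cond, newdf, d$schema)
  for (a in 1:2)
    expect_lt(tv_dist(pr[a, ], spec$cpts[[1]][a, ]), 0.05)
})

test_that("single-level variables are stored and sampled as constants", {
  schema <- cat_schema(cat_var("fixed", "only"),
                       cat_var("free", c("A", "B")))
  set.seed(3)
  d <- cat_data(cbind(rep(1L, 40), sample(1:2, 40, TRUE)), schema)
  m <- fit_mice(d, "ascending", "decision-tree")
  s <- simulate(m, nsim = 100, seed = 1)
  expect_true(all(s$codes[, 1L] == 1L))
})

test_that("all samplers respect the training schema", {
  spec <- correlated_tree_spec()
  d <- generate_fixture(spec, 800, seed = 30)
  card <- vapply(d$schema, `[[`, integer(1), "cardinality")
  models <- list(fit_im(d), fit_chow_liu(d),
                 fit_mpom(d, k = 5, n_iter = 80, burn_in = 20, thin = 5,
                          seed = 2),
                 fit_mice(d, "ascending", "decision-tree"))
  for (m in models) {
    s <- simulate(m, nsim = 500, seed = 31)
    expect_identical(dim(s$codes), c(500L, length(card)))
    for (j in seq_along(card))
      expect_true(all(s$codes[, j] >= 1L & s$codes[, j] <= card[j]))
  }
})

test_that("fit_generator dispatches by family name", {
  d <- generate_fixture(copy_spec(), 300, seed = 1)
  expect_s3_class(fit_generator(d, "im"), "im_model")
  expect_s3_class(fit_generator(d, "chowliu"), "chowliu_model")
  expect_s3_class(fit_generator(d, "mice", order_by = "descending"),
                  "mice_model")
  expect_error(fit_generator(d, "nonesuch"))
})

test_that("table-based models serialize to YAML and back", {
  d <- generate_fixture(chain_spec(), 500, seed = 2)
  path <- withr::local_tempfile(fileext = ".yaml")
  for (m in list(fit_im(d), fit_chow_liu(d),
                 fit_mpom(d, k = 3, n_iter = 40, burn_in = 10, thin = 5,
                          seed = 3))) {
    write_model(m, path)
    back <- read_model(path)
    expect_identical(simulate(back, 200, seed = 4)$codes,
                     simulate(m, 200, seed = 4)$codes)
  }
  expect_error(write_model(fit_mice(d), path), "YAML")
})
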