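# Shared fixture builders and independent oracles used across test files.

binary_schema <- function(p, labels = c("a", "b")) {
  cat_schema(lapply(seq_len(p), function(j)
    cat_var(paste0("v", j), labels)))
}

# Two well-separated product-multinomial components over 5 binary
# variables, level probabilities 0.9/0.1 mirrored.
two_component_spec <- function() {
  mixture_fixture(binary_schema(5),
                  weights = c(0.5, 0.5),
                  psi = list(lapply(1:5, function(j) c(0.9, 0.1)),
                             lapply(1:5, function(j) c(0.1, 0.9))))
}

# Chain A -> B -> C over 3 binary variables with strong (0.9) copying edges.
chain_spec <- function(stay = 0.9) {
  cpt <- matrix(c(stay, 1 - stay, 1 - stay, stay), 2L, 2L, byrow = TRUE)
  tree_fixture(binary_schema(3), root = 1L,
               edges = cbind(c(1L, 2L), c(2L, 3L)),
               root_marginal = c(0.5, 0.5),
               cpts = list(cpt, cpt))
}

# Two variables where the child copies the parent deterministically.
copy_spec <- function(card = 2L) {
  schema <- cat_schema(cat_var("parent", paste0("L", seq_len(card))),
                       cat_var("child", paste0("L", seq_len(card))))
  tree_fixture(schema, root = 1L, edges = cbind(1L, 2L),
               root_marginal = rep(1 / card, card),
               cpts = list(diag(card)))
}

# Star over six 5-level variables, every leaf a strong copy of the uniform
# hub. Known-attribute neighborhoods are sharp while the marginals carry no
# dominant level, so a k-NN vote that reaches past the matching records
# (diffuse neighborhoods) loses its signal — the regime in which larger k
# dilutes the attribute attack.
star_spec <- function(stay = 0.85, card = 5L) {
  schema <- cat_schema(lapply(1:6, function(j)
    cat_var(paste0("v", j), paste0("L", seq_len(card)))))
  cpt <- matrix((1 - stay) / (card - 1), card, card)
  diag(cpt) <- stay
  tree_fixture(schema, 1L, cbind(rep(1L, 5L), 2:6), rep(1 / card, card),
               rep(list(cpt), 5L))
}

# Moderately sized correlated tree fixture used by the ordering tests.
correlated_tree_spec <- function(seed = 11L) {
  random_tree_fixture(c(4L, 3L, 5L, 2L, 4L, 3L), imbalance = 0.25,
                      seed = seed)
}

small_toy_data <- function() {
  schema <- cat_schema(cat_var("x", c("A", "B", "C")),
                       cat_var("y", c("u", "v")))
  cat_data(cbind(c(1L, 2L, 3L, 1L, 2L), c(1L, 2L, 1L, 2L, 1L)), schema)
}

# --- independent oracles -------------------------------------------------

tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# Brute-force per-column level tally.
oracle_marginal <- function(data, j) {
  card <- data$schema[[j]]$cardinality
  counts <- vapply(seq_len(card), function(l) sum(data$codes[, j] == l),
                   numeric(1))
  counts / nrow(data$codes)
}

# Direct-summation mutual information from an explicit joint table.
oracle_mi <- function(codes_u, codes_v, du, dv) {
  n <- length(codes_u)
  mi <- 0
  for (a in seq_len(du)) for (b in seq_len(dv)) {
    pab <- sum(codes_u == a & codes_v == b) / n
    if (pab > 0) {
      pa <- sum(codes_u == a) / n
      pb <- sum(codes_v == b) / n
      mi <- mi + pab * log(pab / (pa * pb))
    }
  }
  mi
}

# Exhaustive maximum spanning tree weight: enumerate all (p-1)-edge
# subsets of the complete graph and keep the spanning ones.
oracle_max_tree_weight <- function(p, mi_lookup) {
  pairs <- t(utils::combn(p, 2L))
  best <- -Inf
  for (subset in utils::combn(nrow(pairs), p - 1L, simplify = FALSE)) {
    comp <- seq_len(p)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    spanning <- TRUE
    for (e in subset) {
      a <- find(pairs[e, 1L]); b <- find(pairs[e, 2L])
      if (a == b) { spanning <- FALSE; break }
      comp[a] <- b
    }
    if (spanning)
      best <- max(best, sum(mi_lookup[subset]))
  }
  best
}

# Empirical joint distribution of a dataset as a named vector over level
# combinations (for TV comparisons against exact joints).
empirical_joint <- function(data) {
  card <- vapply(data$schema, `[[`, integer(1), "cardinality")
  key <- as.vector((data$codes - 1L) %*% cumprod(c(1, card[-length(card)])))
  tabulate(key + 1L, prod(card)) / nrow(data$codes)
}

exact_joint_vector <- function(spec) {
  as.vector(fixture_joint(spec))
}
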