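---
title: "Generating and evaluating fully synthetic categorical data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and evaluating fully synthetic categorical data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Registries holding sensitive patient-level categorical data (cancer
registries are the motivating case) often cannot release record-level
extracts. One release strategy is *fully synthetic data*: fit a generative
model to the private table, sample an entirely artificial table from it,
and publish only the artificial one. The release is useful exactly to the
extent that the synthetic table preserves the statistical structure of the
original, and it is safe exactly to the extent that it does not leak
individual records. `synthcat` implements both sides of that trade-off:
four generative model families for multivariate categorical data, five
utility metrics, and two disclosure attacks, plus the machinery (fixtures,
benchmark harness, edit-rule checks) to run controlled experiments.

All data is categorical: a record is a vector of `p` level codes, one per
variable, and a variable's *cardinality* is the number of levels its schema
declares. Schemas may declare levels that are never observed — registry
codebooks routinely do — and every dataset is bound to an explicit schema
(`cat_schema`, `cat_data`) so that codes are stable across files and model
objects.

## The generator families

**Independent marginals** (`fit_im`). Each variable's empirical marginal is
estimated and sampled independently. It is the baseline: it preserves
marginals perfectly (up to sampling noise) and destroys all dependence.

**Chow-Liu tree Bayesian network** (`fit_chow_liu`). The joint is
factorized over a dependency tree,
\[
p(x) = \prod_{v} p(x_v \mid x_{\mathrm{pa}(v)}),
\]
with the tree chosen as the maximum-weight spanning tree under empirical
pairwise mutual information — among all tree factorizations this is the one
closest in KL divergence to the empirical joint. Conditional probability
tables are maximum-likelihood conditional frequencies, optionally with an
add-λ pseudo-count (`smoothing`, default 0, i.e. pure MLE). Sampling is
ancestral. Design choices the method itself does not fix: ties in edge
weight are broken toward the lexicographically smaller (min, max) index
pair, the tree is rooted at the lowest-index variable (the factorization is
invariant to rooting), and a parent level never observed in training falls
back to the child's marginal. All three choices exist to make fitting and
sampling deterministic and total.

**Mixture of product multinomials** (`fit_mpom`). The joint is a finite
mixture in which variables are independent within a component,
\[
p(x_1 = c_1, \dots, x_p = c_p) = \sum_{h=1}^{k} \nu_h \prod_{j=1}^{p}
\psi^{(j)}_{h c_j},
\]
with a truncated stick-breaking (Dirichlet process) prior on the weights
and symmetric Dirichlet(1) priors on each \(\psi\) (the model is fully
conjugate; the flat prior is the default because no informative choice is
canonical). Inference is a blocked Gibbs sampler: indicators, then ψ from
Dirichlet full conditionals, then stick fractions \(V_h \sim
\mathrm{Beta}(1 + n_h,\ \alpha + \sum_{l>h} n_l)\) with \(V_k = 1\). The
full-scale defaults are k = 30, α = 10 and 10 000 sweeps with 1 000
burn-in, thinned every 10; the package's own validation experiments run a
scaled-down budget (k = 10, 500 sweeps, 100 burn-in) on fixture
populations of a few thousand records, where chains mix in seconds.
Synthetic sampling pools the retained posterior draws per record by
default (`pool_draws = TRUE`), approximating the posterior predictive; a
single-draw mode is available since neither convention is canonical.

A truncated DP posterior fragments true components across clusters and
permutes labels between draws, so per-cluster averages are biased
summaries. `mpom_components()` therefore pools every retained (weight, ψ)
atom and merges them into the requested number of groups with a
deterministic weighted k-means (farthest-point initialization from the
heaviest atom); each group's weight-averaged profile is the reported
component. On a two-component fixture this recovers both profiles within
the 0.05 total-variation tolerance the validation suite asserts, where
raw per-cluster averages fall short of it.

**Sequential conditional synthesis** (`fit_mice`). The joint is factorized
along a variable ordering, \(p(x) = \prod_v p(x_v \mid x_{<v})\); the first
variable keeps its empirical marginal and each later one is a
probabilistic classifier on all predecessors, sampled (never arg-maxed) in
order. The ordering sorts by cardinality, ascending or descending, with
ties broken by schema position (the tie rule is ours; only the sort
direction is standard). Decision-tree conditionals use `rpart` with the
Gini criterion, `minsplit = 2`, `minbucket = 1` and no complexity pruning
— i.e. effectively unrestricted growth, though `rpart` caps depth at 30.
Multinomial-logistic conditionals use `nnet::multinom` on the predecessor
factors with a small weight decay (`decay = 1e-3`): without the ridge
term, perfectly separable (e.g. deterministic) relations have divergent
maximum-likelihood coefficients and the fit is unstable. Single-level
variables (registry extracts contain them) are stored as constants, no
classifier fit.

All samplers are pure functions of (model, n, seed): seeding is handled
with `withr::with_seed`, so the caller's RNG stream is never disturbed,
and every sampler draws categorical values by a vectorized inverse-CDF
against row-stochastic matrices.

## Utility metrics

- **KL divergence** (`kl_divergence`, `kl_per_variable`): per-variable
  divergence of real from synthetic marginals, natural log, 0·log 0 = 0.
  A synthetic marginal missing a real level makes the raw value infinite;
  the default smooths Q to (Q + ε)/(1 + ε|v|) with ε = 1e-6 — small enough
  to leave reported values visually unchanged, large enough to keep
  generator comparisons finite and ordered. ε = 0 reproduces the raw
  definition (with a warning on infinite values).
- **Pairwise correlation difference** (`pairwise_correlation_difference`):
  Frobenius norm of the difference of Pearson correlation matrices. The
  metric's p×p shape implies a per-variable numeric encoding; integer
  level codes are the default and one-hot is offered, since no encoding is
  canonical for nominal data. Constant columns (zero variance) get zero
  off-diagonal correlation by convention rather than NA.
- **Log-cluster** (`log_cluster`): k-means with G clusters (default 20) on
  the one-hot encoding of the merged data, then
  \(U_c = \log\big(\tfrac1G\sum_j [n^R_j/n_j - c]^2\big)\),
  \(c = n^R/(n^R+n^S)\). Lower is better. k-means uses 10 random restarts
  under a fixed seed, keeping the best inertia; restarts under a fixed
  seed serve the same variance-reduction purpose as more elaborate seeding
  heuristics while keeping runs exactly reproducible. Clusters that come
  back empty are dropped from the average; if the merged data has fewer
  distinct rows than G, G is capped (with a message). The clustering-free
  core is exposed as `log_cluster_eval` so that closed-form cases — e.g.
  complete real/synthetic separation at c = 0.5 giving log(1/4) — can be
  verified without k-means.
- **Support coverage** (`support_coverage`): mean over variables of the
  fraction of *observed real* levels also present in the synthetic data.
  Coverage is measured against observed support, not the declared schema:
  declared-but-unobserved levels say nothing about generator quality.
- **Cross-classification** (`cross_classification`): for direction RS the
  real data is split 70/30 (seeded), a decision tree per target variable is
  trained on the 70% with all other variables as predictors, and the
  reported ratio is accuracy(synthetic)/accuracy(real hold-out), averaged
  over targets; SR mirrors it (train on 70% of synthetic, ratio =
  accuracy(real)/accuracy(synthetic hold-out)), so "close to 1" means
  transferability in both directions. The classifier mirrors the MICE-DT
  tree settings; accuracy is the default performance measure with macro-F1
  behind a flag; the evaluation side uses the full other dataset. The
  split fraction, measure and hold-out conventions are package choices —
  the procedure itself only fixes train/test/score roles.

## Disclosure attacks

**Membership** (`membership_disclosure`): a record is claimed present in
training if any synthetic record lies within a normalized Hamming distance
threshold. Normalization (mismatches / p) makes thresholds comparable
across attribute-set sizes. With r records per side, precision and recall
are computed from the 2r claims; zero positive claims leave precision
*undefined* (NA), never 0, so degenerate generators are not rewarded. At
threshold 1 every claim is positive, forcing recall 1 and precision
exactly r/2r = 0.5 — a useful analytic anchor. `membership_split` draws
the r train / r held-out target records uniformly without replacement
under a seed.

**Attribute** (`attribute_disclosure`): the attacker knows a proper subset
of attributes, takes the k nearest synthetic records under Hamming
distance on the known attributes (distance ties broken by synthetic record
index: first k in file order), and infers each unknown attribute by
majority vote (vote ties to the smallest level code; both tie rules are
ours, chosen for determinism). A target is disclosed only if *all* unknown
attributes are recovered. Note the k = 1 tie rule makes the attack use the
first exact match per known pattern, which adds variance across synthetic
replicates; ordering claims about k are therefore asserted over seeds, not
per run.

Whether larger k helps or hurts the attacker is a property of the data
regime, not of the code: with binary unknowns a large-k vote aggregates
weak signal and can *improve* the attack, while dilution appears when
neighborhoods are diffuse — many known-attribute patterns, few exact
matches per pattern, and no dominant marginal mode to fall back on. The
test suite's `star_spec` fixture (six 5-level variables, uniform hub,
strong copies) instantiates that regime, with k = 100 forced to reach far
beyond the ~20 matching records of a 120-record synthetic sample.

## Fixtures: what they emulate and what they do not

Real registry extracts are access-restricted, so all validation runs on
simulated populations with known generative truth. `random_tree_fixture`
and `random_mixture_fixture` draw probability rows from symmetric
Dirichlet distributions with concentration below 1 (`imbalance`, default
0.4), which concentrates mass on a few dominant levels per variable — the
strongly imbalanced level histograms typical of registry variables —
and cardinalities are chosen in the small-registry range (up to ~14
levels). Hand-built specs (`tree_fixture`, `mixture_fixture`) cover
deterministic relations and separated mixtures. `fixture_joint` enumerates
a spec's exact joint for oracle comparisons.

Fixtures are *not* registry data: they have no missing-data conventions,
no variables with hundreds of levels, no deterministic administrative
couplings beyond those built in, and tree/mixture truth by construction.
Passing the validation suite shows the estimators recover the structures
they target and the metrics order generators correctly where the ordering
is knowable; it does not show that any particular real extract is safe to
release.

Study sizes used throughout the suite — fixture populations of 300–20 000
records, synthetic samples of 120–20 000, 10 seeded replicates for
ordering claims, the scaled-down Gibbs budget — were chosen once as the
smallest sizes at which the corresponding statistical signals are stable,
and the full suite runs in well under a minute on one core.

## Harness

`run_benchmark` fits each configured generator once and replicates the
*sampling* m times (per-replicate seeds derived from the master seed),
reporting mean and sd per metric; refit-per-replicate is available by flag
since reported spread can be read either way. Failures yield NA cells and
the run continues. `grid_search` scores candidate hyper-parameter settings
by the log-cluster criterion — the only metric in the battery that
responds to the full joint rather than marginals or pairwise association —
and returns the argmin with a full trace. `edit_check` evaluates
antecedent → allowed-set consistency rules (the printed-rule form used by
registry edit systems; richer rule languages are out of scope) and reports
the fraction of records violating at least one rule.

## Known limitations

- Categorical variables only; no ordinal structure, counts or dates.
- The Chow-Liu model cannot represent dependence beyond first order, by
  construction; MPoM can, at the cost of Gibbs runtime on wide data.
- `mpom_components` assumes the merged groups are well separated; heavily
  overlapping mixtures will not be resolved.
- MICE models embed fitted `rpart`/`nnet` objects and do not serialize to
  the YAML model format (`write_model` covers the table-based families).
- The attribute attack's deterministic tie-breaks make k = 1 results
  sensitive to synthetic record order; interpret single-run values with
  care.
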