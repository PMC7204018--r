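#' Kullback-Leibler divergence between two marginal PMFs
#'
#' \deqn{D_{KL}(P \| Q) = \sum_i P(i) \log P(i) / Q(i)} in natural log,
#' with the convention 0 log 0 = 0. The divergence is computed per
#' variable, so it compares marginals only and is blind to dependence. When
#' the synthetic distribution `Q` misses a level that `P` supports the raw
#' divergence is infinite; with `eps > 0`, `Q` is smoothed to
#' `(Q + eps) / (1 + eps * |v|)` which keeps the value finite while
#' preserving the ordering between generators.
#'
#' @param P,Q `pmf` objects over the same level set (real and synthetic,
#'   conventionally), or bare probability vectors of equal length.
#' @param eps Smoothing constant applied to `Q`; 0 disables smoothing.
#' @return Non-negative scalar; `Inf` (with a warning) if `eps = 0` and `Q`
#'   lacks support where `P` has mass.
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.25, 0.75), eps = 0)
#' @export
kl_divergence <- function(P, Q, eps = 1e-6) {
  p <- if (inherits(P, "pmf")) P$probs else as.numeric(P)
  q <- if (inherits(Q, "pmf")) Q$probs else as.numeric(Q)
  if (inherits(P, "pmf") && inherits(Q, "pmf") &&
      !identical(P$variable$levels, Q$variable$levels))
    stop("P and Q are over different level sets")
  if (length(p) != length(q)) stop("P and Q have different lengths")
  if (eps > 0) q <- (q + eps) / (1 + eps * length(q))
  pos <- p > 0
  if (any(q[pos] == 0)) {
    warning("Q has zero mass where P is positive; divergence is infinite")
    return(Inf)
  }
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Per-variable KL divergences between two datasets
#'
#' @param real,synthetic `cat_data` objects over the same schema.
#' @param eps Smoothing for the synthetic marginals.
#' @return Named numeric vector, one divergence per variable.
#' @export
kl_per_variable <- function(real, synthetic, eps = 1e-6) {
  check_same_schema(real, synthetic)
  vapply(seq_len(n_variables(real)), function(j)
    kl_divergence(empirical_marginal(real, j),
                  empirical_marginal(synthetic, j), eps = eps),
    numeric(1)) |> stats::setNames(schema_names(real$schema))
}

check_same_schema <- function(a, b) {
  if (!identical(schema_names(a$schema), schema_names(b$schema)) ||
      !identical(schema_cardinalities(a$schema),
                 schema_cardinalities(b$schema)))
    stop("datasets must share a schema")
  invisible(TRUE)
}

#' Pairwise correlation difference (PCD)
#'
#' Frobenius norm of the difference between the Pearson correlation
#' matrices of the real and synthetic data matrices. Smaller is better;
#' identical datasets give 0. Correlation of categorical columns requires a
#' numeric encoding: the default uses the integer level codes (yielding the
#' p-by-p matrix the metric's definition implies); a one-hot encoding is
#' available as an option. A constant column has undefined Pearson
#' correlation; its off-diagonal entries are set to 0 (and diagonal to 1)
#' so degenerate variables do not poison the norm.
#'
#' @param real,synthetic `cat_data` objects over the same schema, each with
#'   at least two records.
#' @param encoding `"integer-codes"` (default) or `"one-hot"`.
#' @return Non-negative scalar.
#' @export
pairwise_correlation_difference <- function(real, synthetic,
                                            encoding = c("integer-codes",
                                                         "one-hot")) {
  check_same_schema(real, synthetic)
  if (n_records(real) < 2L || n_records(synthetic) < 2L)
    stop("PCD needs at least 2 records per dataset")
  encoding <- match.arg(encoding)
  enc <- function(d) if (encoding == "one-hot") one_hot(d) else d$codes
  cr <- safe_cor(enc(real))
  cs <- safe_cor(enc(synthetic))
  sqrt(sum((cr - cs)^2))
}

safe_cor <- function(m) {
  sds <- apply(m, 2L, stats::sd)
  cc <- suppressWarnings(stats::cor(m))
  cc[is.na(cc)] <- 0
  diag(cc) <- 1
  # columns with zero variance: no linear association by convention
  cc[sds == 0, ] <- 0; cc[, sds == 0] <- 0
  diag(cc) <- 1
  cc
}

#' Log-cluster similarity of real and synthetic data
#'
#' Merges the two datasets, clusters the merged one-hot matrix with k-means
#' into `G` clusters, and scores how evenly real records spread over the
#' clusters:
#' \deqn{U_c = \log\left( \frac{1}{G} \sum_j \left[ n_j^R / n_j - c
#' \right]^2 \right)}
#' with \eqn{c = n^R / (n^R + n^S)}. If real and synthetic data share the
#' same latent cluster structure every cluster's real fraction is near `c`
#' and the metric is very negative; disparities push it towards
#' \eqn{\log((1-c)c^2 + c(1-c)^2)} and beyond. Lower is better.
#'
#' k-means runs on the one-hot encoding with `restarts` random starts under
#' a fixed seed, keeping the best within-cluster sum of squares. Clusters
#' that come back empty are dropped from the average (k-means may also
#' return fewer than `G` clusters when the merged data has fewer distinct
#' rows; `G` is capped at that count, with a message).
#'
#' @param real,synthetic `cat_data` objects over the same schema.
#' @param G Number of clusters (default 20).
#' @param seed Integer seed for the clustering.
#' @param restarts Random restarts for k-means.
#' @return Scalar, typically negative.
#' @export
log_cluster <- function(real, synthetic, G = 20L, seed = 1L,
                        restarts = 10L) {
  check_same_schema(real, synthetic)
  nR <- n_records(real); nS <- n_records(synthetic)
  if (nR + nS < G) stop("need at least G records in the merged data")
  merged <- one_hot(bind_records(real, synthetic))
  distinct <- nrow(unique(merged))
  if (distinct < G) {
    message("merged data has only ", distinct,
            " distinct records; using G = ", distinct)
    G <- distinct
  }
  km <- with_seed(seed,
                  stats::kmeans(merged, centers = G, nstart = restarts,
                                iter.max = 50L))
  is_real <- rep(c(TRUE, FALSE), c(nR, nS))
  log_cluster_eval(km$cluster, is_real)
}

#' Evaluate the log-cluster statistic from a given cluster assignment
#'
#' The clustering-free core of [log_cluster()]: given cluster labels for
#' the merged data and a real/synthetic indicator, computes
#' \eqn{\log( (1/G) \sum_j [n_j^R / n_j - c]^2 )}. Exposed so that the
#' closed-form behaviour (e.g. complete separation of real and synthetic
#' clusters with c = 0.5 giving log 0.25) can be evaluated without k-means.
#'
#' @param cluster Integer cluster labels for the merged records.
#' @param is_real Logical vector: TRUE for records from the real dataset.
#' @param c_frac Real-data fraction; defaults to `mean(is_real)`.
#' @return Scalar.
#' @export
log_cluster_eval <- function(cluster, is_real, c_frac = mean(is_real)) {
  stopifnot(length(cluster) == length(is_real))
  nj <- tapply(rep(1L, length(cluster)), cluster, sum)
  njR <- tapply(as.integer(is_real), cluster, sum)
  keep <- nj > 0
  log(mean((njR[keep] / nj[keep] - c_frac)^2))
}

#' Support coverage of a synthetic dataset
#'
#' Average over variables of the fraction of the real data's observed
#' levels that also occur in the synthetic data:
#' \deqn{S_c = \frac{1}{V} \sum_v |S^v \cap R^v| / |R^v|} where \eqn{R^v}
#' and \eqn{S^v} are the observed supports of variable v in the real and
#' synthetic data. Equals 1 when every observed real level is represented;
#' rare levels that the generator never emits pull it down. Support is
#' measured against the real data's observed levels, not the schema's
#' declared levels, so declared-but-unobserved levels do not dilute the
#' metric.
#'
#' @param real A non-empty `cat_data`.
#' @param synthetic A `cat_data` over the same schema.
#' @return Scalar in [0, 1].
#' @export
support_coverage <- function(real, synthetic) {
  check_same_schema(real, synthetic)
  if (n_records(real) == 0L) stop("real dataset is empty")
  ratios <- vapply(seq_len(n_variables(real)), function(j) {
    rs <- unique(real$codes[, j])
    ss <- unique(synthetic$codes[, j])
    length(intersect(ss, rs)) / length(rs)
  }, numeric(1))
  mean(ratios)
}

#' Cross-classification utility (CrCl-RS / CrCl-SR)
#'
#' Measures whether predictive structure carries over between real and
#' synthetic data. For direction `"RS"`: the real data is split into
#' training and test sets; for each variable in turn a decision-tree
#' classifier is trained on the training split with all other variables as
#' predictors; its accuracy is measured on the real test split and on the
#' synthetic data, and the per-variable ratio accuracy(synthetic) /
#' accuracy(real test) is reported together with the mean over variables.
#' Direction `"SR"` mirrors the procedure with the roles swapped: train on
#' a split of the synthetic data, ratio = accuracy(real) /
#' accuracy(synthetic hold-out). Values close to 1 are ideal in both
#' directions.
#'
#' @param real,synthetic Non-empty `cat_data` objects over the same schema
#'   with at least two variables.
#' @param direction `"RS"` (train on real) or `"SR"` (train on synthetic).
#' @param test_fraction Held-out fraction of the training-side dataset.
#' @param seed Integer seed for the split.
#' @param measure `"accuracy"` (default) or `"macro-F1"`.
#' @return List with `ratios` (named per-variable vector, NA where the
#'   denominator accuracy is zero) and `mean` (over defined ratios).
#' @export
cross_classification <- function(real, synthetic, direction = c("RS", "SR"),
                                 test_fraction = 0.3, seed = 1L,
                                 measure = c("accuracy", "macro-F1")) {
  check_same_schema(real, synthetic)
  direction <- match.arg(direction)
  measure <- match.arg(measure)
  if (n_records(real) == 0L || n_records(synthetic) == 0L)
    stop("both datasets must be non-empty")
  p <- n_variables(real)
  if (p < 2L) stop("cross-classification needs at least 2 variables")
  train_side <- if (direction == "RS") real else synthetic
  other_side <- if (direction == "RS") synthetic else real
  n <- n_records(train_side)
  idx_test <- with_seed(seed,
                        sample.int(n, size = max(1L, round(test_fraction * n))))
  train <- decode(subset_records(train_side, -idx_test))
  test <- decode(subset_records(train_side, idx_test))
  other <- decode(other_side)
  nm <- schema_names(real$schema)
  ratios <- stats::setNames(rep(NA_real_, p), nm)
  for (j in seq_len(p)) {
    dtr <- train; names(dtr)[j] <- ".y"
    dtr$.y <- droplevels(dtr$.y)
    if (nlevels(dtr$.y) < 2L) {
      # constant target: every prediction is that constant
      pred_test <- rep(levels(dtr$.y), nrow(test))
      pred_other <- rep(levels(dtr$.y), nrow(other))
    } else {
      fit <- rpart::rpart(.y ~ ., data = dtr, method = "class",
                          control = rpart::rpart.control(
                            minsplit = 2L, minbucket = 1L, cp = 0,
                            maxdepth = 30L, xval = 0L))
      pred_test <- as.character(stats::predict(fit, test[-j],
                                               type = "class"))
      pred_other <- as.character(stats::predict(fit, other[-j],
                                                type = "class"))
    }
    perf_hold <- class_perf(as.character(test[[j]]), pred_test, measure)
    perf_other <- class_perf(as.character(other[[j]]), pred_other, measure)
    # RS: synthetic over real hold-out; SR: real over synthetic hold-out
    num <- perf_other
    den <- perf_hold
    if (den == 0) {
      warning("zero hold-out performance for '", nm[j],
              "'; ratio undefined")
    } else {
      ratios[j] <- num / den
    }
  }
  list(ratios = ratios, mean = mean(ratios, na.rm = TRUE),
       direction = direction, measure = measure)
}

class_perf <- function(truth, pred, measure) {
  if (measure == "accuracy") return(mean(truth == pred))
  classes <- unique(truth)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f1)
}

#' Full utility battery
#'
#' Computes all five utility metrics for one real/synthetic pair and
#' returns them in a flat report.
#'
#' @param real,synthetic `cat_data` objects over the same schema.
#' @param G Cluster count for [log_cluster()].
#' @param seed Seed shared by the seeded sub-metrics.
#' @param eps KL smoothing.
#' @return A list of class `utility_report`: `kl_per_variable`, `kl_mean`,
#'   `pcd`, `log_cluster`, `support_coverage`, `crcl_rs`, `crcl_sr`.
#' @export
utility_report <- function(real, synthetic, G = 20L, seed = 1L,
                           eps = 1e-6) {
  kl <- kl_per_variable(real, synthetic, eps = eps)
  rs <- cross_classification(real, synthetic, "RS", seed = seed)
  sr <- cross_classification(real, synthetic, "SR", seed = seed)
  structure(list(kl_per_variable = kl, kl_mean = mean(kl),
                 pcd = pairwise_correlation_difference(real, synthetic),
                 log_cluster = log_cluster(real, synthetic, G = G,
                                           seed = seed),
                 support_coverage = support_coverage(real, synthetic),
                 crcl_rs = rs, crcl_sr = sr),
            class = "utility_report")
}

#' @export
print.utility_report <- function(x, digits = 4L, ...) {
  cat("Synthetic data utility report\n")
  cat("  mean KL divergence : ", round(x$kl_mean, digits), "\n", sep = "")
  cat("  PCD                : ", round(x$pcd, digits), "\n", sep = "")
  cat("  log-cluster        : ", round(x$log_cluster, digits), "\n", sep = "")
  cat("  support coverage   : ", round(x$support_coverage, digits), "\n",
      sep = "")
  cat("  CrCl-RS (mean)     : ", round(x$crcl_rs$mean, digits), "\n",
      sep = "")
  cat("  CrCl-SR (mean)     : ", round(x$crcl_sr$mean, digits), "\n",
      sep = "")
  invisible(x)
}
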