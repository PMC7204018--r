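#' Hamming distance between two records
#'
#' Number of positions at which two equal-length records disagree,
#' optionally divided by the record length. The disclosure attacks use the
#' normalized form so that thresholds are comparable across attribute-set
#' sizes.
#'
#' @param a,b Equal-length vectors of level codes (or labels).
#' @param normalized Divide by the record length.
#' @return Scalar in `[0, length(a)]` (or `[0, 1]` normalized).
#' @export
hamming <- function(a, b, normalized = TRUE) {
  if (length(a) != length(b)) stop("records have different lengths")
  d <- sum(a != b)
  if (normalized) d / length(a) else d
}

# All-pairs Hamming distance counts between two code matrices (rows =
# records), computed one variable at a time; returns an n_a x n_b matrix of
# mismatch counts.
hamming_cross <- function(A, B) {
  D <- matrix(0L, nrow(A), nrow(B))
  for (j in seq_len(ncol(A)))
    D <- D + outer(A[, j], B[, j], "!=")
  D
}

#' Membership disclosure attack
#'
#' An attacker holding 2r candidate records — r used to train the generator
#' and r held out — claims a record was in the training set if at least one
#' synthetic record lies within a normalized Hamming distance `threshold`
#' of it. Claims are scored against the truth: precision = TP / (TP + FP)
#' and recall = TP / r. When no record is claimed, precision is undefined
#' (`NA`, never 0) so degenerate generators are not rewarded. At threshold
#' 1 every claim is positive for any non-empty synthetic set, forcing
#' recall 1 and precision exactly 0.5.
#'
#' @param train_sample `cat_data` of r records that were used in fitting.
#' @param test_sample `cat_data` of r records that were not.
#' @param synthetic Non-empty `cat_data` over the same schema.
#' @param threshold Normalized Hamming radius of the neighborhood.
#' @return An object of class `membership_result`: `precision` (NA when
#'   undefined), `recall`, `counts` (tp/fp/tn/fn), `threshold`, `r`.
#' @export
membership_disclosure <- function(train_sample, test_sample, synthetic,
                                  threshold) {
  check_same_schema(train_sample, test_sample)
  check_same_schema(train_sample, synthetic)
  r <- n_records(train_sample)
  if (r < 1L || n_records(test_sample) != r)
    stop("need r >= 1 records on each side, equally many")
  if (n_records(synthetic) == 0L) stop("synthetic dataset is empty")
  p <- n_variables(synthetic)
  claim <- function(targets) {
    D <- hamming_cross(targets$codes, synthetic$codes)
    apply(D / p <= threshold, 1L, any)
  }
  pos_train <- claim(train_sample)   # claimed present, truly present
  pos_test <- claim(test_sample)    # claimed present, truly absent
  tp <- sum(pos_train); fn <- r - tp
  fp <- sum(pos_test); tn <- r - fp
  precision <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  if (tp + fp == 0L)
    message("no positive membership claims; precision undefined")
  structure(list(precision = precision, recall = tp / r,
                 counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 threshold = threshold, r = r),
            class = "membership_result")
}

#' @export
print.membership_result <- function(x, ...) {
  cat("Membership disclosure (normalized Hamming threshold ", x$threshold,
      ", r = ", x$r, ")\n", sep = "")
  cat("  precision:", ifelse(is.na(x$precision), "undefined",
                             format(x$precision, digits = 4L)),
      " recall:", format(x$recall, digits = 4L), "\n")
  cat("  counts: ", paste(names(x$counts), x$counts, sep = "=",
                          collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Attribute disclosure attack
#'
#' For each target record, the attacker knows the attributes in
#' `known_idx`, finds the `k` synthetic records nearest in Hamming distance
#' restricted to those attributes (distance ties broken by synthetic record
#' index: the first k in file order), and infers every unknown attribute by
#' majority vote over the k neighbors (vote ties go to the smallest level
#' code). A target counts as disclosed only if every unknown attribute is
#' inferred exactly; the success rate is the fraction of disclosed targets.
#' The attack is deterministic: identical inputs give identical results.
#'
#' @param targets `cat_data` of real records under attack.
#' @param synthetic `cat_data` over the same schema with at least `k`
#'   records.
#' @param known_idx Indices (or names) of the attributes the attacker
#'   knows; a proper, non-empty subset.
#' @param k Number of nearest neighbors in the vote.
#' @return An object of class `attribute_result`: `success_rate`, `k`,
#'   `known_idx`, `per_record` logical flags.
#' @export
attribute_disclosure <- function(targets, synthetic, known_idx, k = 1L) {
  check_same_schema(targets, synthetic)
  p <- n_variables(targets)
  known <- sort(unique(vapply(known_idx, resolve_variable,
                              integer(1), schema = targets$schema)))
  if (length(known) == 0L || length(known) >= p)
    stop("known attributes must be a proper, non-empty subset")
  k <- as.integer(k)
  if (k < 1L || n_records(synthetic) < k)
    stop("need 1 <= k <= number of synthetic records")
  unknown <- setdiff(seq_len(p), known)
  D <- hamming_cross(targets$codes[, known, drop = FALSE],
                     synthetic$codes[, known, drop = FALSE])
  nt <- n_records(targets)
  success <- logical(nt)
  for (i in seq_len(nt)) {
    nb <- order(D[i, ], seq_len(ncol(D)))[seq_len(k)]
    ok <- TRUE
    for (j in unknown) {
      votes <- tabulate(synthetic$codes[nb, j],
                        nbins = targets$schema[[j]]$cardinality)
      guess <- which.max(votes)  # ties: smallest level code
      if (guess != targets$codes[i, j]) { ok <- FALSE; break }
    }
    success[i] <- ok
  }
  structure(list(success_rate = mean(success), k = k, known_idx = known,
                 per_record = success),
            class = "attribute_result")
}

#' @export
print.attribute_result <- function(x, ...) {
  cat("Attribute disclosure (k = ", x$k, ", ", length(x$known_idx),
      " known attributes)\n", sep = "")
  cat("  success rate:", format(x$success_rate, digits = 4L), "over",
      length(x$per_record), "targets\n")
  invisible(x)
}

#' Seeded train/test target split for the membership attack
#'
#' Draws r record indices for fitting and r disjoint held-out indices,
#' uniformly without replacement, so a full membership experiment (fit on
#' the sampled training records, attack with both sets) is reproducible
#' from the seed.
#'
#' @param data A `cat_data` with at least 2r records.
#' @param r Records per side.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
membership_split <- function(data, r = 1000L, seed = 1L) {
  n <- n_records(data)
  r <- as.integer(r)
  if (n < 2L * r) stop("need at least 2r records")
  with_seed(seed, {
    idx <- sample.int(n, 2L * r)
    list(train = idx[seq_len(r)], test = idx[r + seq_len(r)])
  })
}
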