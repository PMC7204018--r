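#' Benchmark generator families on one dataset
#'
#' For every configured generator: fit on the real data, then for each of
#' `m` replicates draw a synthetic dataset of `n_synth` records (replicate
#' seeds derived from `seed`) and compute the utility battery. By default
#' the model is fitted once and only the sampling is replicated, so the
#' reported spread reflects sampling variability; `refit = TRUE` refits per
#' replicate instead. A generator that fails to fit or sample yields NA
#' cells (with a warning) and the run continues.
#'
#' @param real A `cat_data`.
#' @param generators Named list; each element a list with `family` (see
#'   [fit_generator()]) and optional fitting arguments.
#' @param m Number of synthetic replicates per generator.
#' @param n_synth Synthetic records per replicate.
#' @param G Cluster count for the log-cluster metric.
#' @param seed Master seed; replicate seeds are `seed * 1000 + replicate`.
#' @param refit Refit the generator for every replicate.
#' @return A data frame of class `benchmark_result` with one row per
#'   generator: mean and sd columns for PCD, log-cluster, support coverage,
#'   CrCl-RS, CrCl-SR and mean KL.
#' @export
run_benchmark <- function(real, generators, m = 10L, n_synth = n_records(real),
                          G = 20L, seed = 1L, refit = FALSE) {
  stopifnot(m >= 1L, length(generators) >= 1L)
  if (is.null(names(generators)) || any(!nzchar(names(generators))))
    stop("generators must be a named list")
  metric_names <- c("kl_mean", "pcd", "log_cluster", "support_coverage",
                    "crcl_rs", "crcl_sr")
  rows <- lapply(names(generators), function(gname) {
    g <- generators[[gname]]
    fit_args <- g[setdiff(names(g), "family")]
    vals <- matrix(NA_real_, m, length(metric_names),
                   dimnames = list(NULL, metric_names))
    model <- NULL
    for (rep_i in seq_len(m)) {
      rep_seed <- as.integer(seed) * 1000L + rep_i
      res <- tryCatch({
        if (is.null(model) || refit) {
          fa <- fit_args
          if ("seed" %in% names(formals(
            switch(g$family, im = fit_im, chowliu = fit_chow_liu,
                   mpom = fit_mpom, mice = fit_mice))) &&
            is.null(fa$seed)) fa$seed <- rep_seed
          model <- do.call(fit_generator,
                           c(list(data = real, family = g$family), fa))
        }
        synth <- simulate(model, nsim = n_synth, seed = rep_seed)
        urep <- utility_report(real, synth, G = G, seed = rep_seed)
        c(kl_mean = urep$kl_mean, pcd = urep$pcd,
          log_cluster = urep$log_cluster,
          support_coverage = urep$support_coverage,
          crcl_rs = urep$crcl_rs$mean, crcl_sr = urep$crcl_sr$mean)
      }, error = function(e) {
        warning("generator '", gname, "' replicate ", rep_i, " failed: ",
                conditionMessage(e))
        stats::setNames(rep(NA_real_, length(metric_names)), metric_names)
      })
      vals[rep_i, ] <- res[metric_names]
    }
    stats <- c(colMeans(vals, na.rm = TRUE),
               apply(vals, 2L, stats::sd, na.rm = TRUE))
    names(stats) <- c(paste0(metric_names, "_mean"),
                      paste0(metric_names, "_sd"))
    c(list(generator = gname), as.list(stats))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  class(out) <- c("benchmark_result", class(out))
  attr(out, "m") <- m
  attr(out, "n_synth") <- n_synth
  out
}

#' Hyper-parameter selection by the log-cluster criterion
#'
#' Evaluates each point of a hyper-parameter grid by fitting the generator,
#' sampling a synthetic dataset and scoring the log-cluster metric against
#' the real data; the grid point with the lowest (best) value wins. The
#' log-cluster criterion is used because it is the only metric in the
#' battery sensitive to the full joint distribution rather than marginals
#' or pairwise association alone. Grid points that fail are recorded as NA
#' in the trace and skipped.
#'
#' @param family Generator family name (see [fit_generator()]).
#' @param grid List of named lists, one per candidate setting.
#' @param data Real `cat_data`.
#' @param n_synth Synthetic records drawn per evaluation.
#' @param G Cluster count for the criterion.
#' @param seed Integer seed shared by every evaluation.
#' @return List with `best` (the winning settings), `best_value`, and
#'   `trace` (data frame of settings and criterion values, one row per grid
#'   point).
#' @export
grid_search <- function(family, grid, data, n_synth = n_records(data),
                        G = 20L, seed = 1L) {
  stopifnot(length(grid) >= 1L)
  values <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    values[i] <- tryCatch({
      args <- grid[[i]]
      if (family == "mpom" && is.null(args$seed)) args$seed <- seed
      model <- do.call(fit_generator,
                       c(list(data = data, family = family), args))
      synth <- simulate(model, nsim = n_synth, seed = seed)
      log_cluster(data, synth, G = G, seed = seed)
    }, error = function(e) {
      warning("grid point ", i, " failed: ", conditionMessage(e))
      NA_real_
    })
  }
  if (all(is.na(values))) stop("every grid point failed")
  best_i <- which.min(values)
  trace <- data.frame(point = seq_along(grid),
                      settings = vapply(grid, function(g)
                        paste(names(g), unlist(g), sep = "=",
                              collapse = ", "), character(1)),
                      log_cluster = values)
  list(best = grid[[best_i]], best_value = values[best_i], trace = trace)
}

#' If-then edit rules
#'
#' An edit rule states that whenever the antecedent variable takes a level
#' in `when_levels`, the consequent variable must take a level in
#' `allowed_levels` — the form of registry consistency edits such as
#' requiring a microscopic diagnostic confirmation code for in-situ
#' behavior codes. A record fails the rule iff the antecedent holds and the
#' consequent value is outside the allowed set.
#'
#' @param antecedent_var,consequent_var Variable names.
#' @param when_levels Levels (labels) triggering the rule.
#' @param allowed_levels Labels the consequent may take when triggered.
#' @param id Optional rule identifier.
#' @return An object of class `edit_rule`.
#' @export
edit_rule <- function(antecedent_var, when_levels, consequent_var,
                      allowed_levels, id = NULL) {
  structure(list(antecedent_var = antecedent_var,
                 when_levels = as.character(when_levels),
                 consequent_var = consequent_var,
                 allowed_levels = as.character(allowed_levels),
                 id = id %||% paste0(antecedent_var, "->", consequent_var)),
            class = "edit_rule")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run edit checks over a dataset
#'
#' @param data A `cat_data`.
#' @param rules List of [edit_rule()]s; variables must exist in the schema.
#' @return List with `fraction_failing` (share of records violating at
#'   least one rule) and `per_rule` (named vector of violation counts).
#' @export
edit_check <- function(data, rules) {
  stopifnot(inherits(data, "cat_data"))
  n <- n_records(data)
  df <- decode(data)
  any_fail <- rep(FALSE, n)
  per_rule <- integer(length(rules))
  names(per_rule) <- vapply(rules, `[[`, character(1), "id")
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    for (v in c(r$antecedent_var, r$consequent_var))
      if (!v %in% names(df)) stop("rule '", r$id,
                                  "' references unknown variable '", v, "'")
    trig <- as.character(df[[r$antecedent_var]]) %in% r$when_levels
    bad <- trig & !(as.character(df[[r$consequent_var]]) %in%
                      r$allowed_levels)
    per_rule[i] <- sum(bad)
    any_fail <- any_fail | bad
  }
  list(fraction_failing = if (n == 0L) 0 else mean(any_fail),
       per_rule = per_rule)
}
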