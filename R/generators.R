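#' Fit a synthetic-data generator by family name
#'
#' Common front end over the four generator families. Every fitted model is
#' a `synth_model` and supports `simulate(model, nsim, seed)` returning a
#' `cat_data` over the training schema; by construction no sampler can emit
#' a level outside the schema.
#'
#' @param data A `cat_data`.
#' @param family One of `"im"`, `"chowliu"`, `"mpom"`, `"mice"`.
#' @param ... Passed to the family's fitting function ([fit_im()],
#'   [fit_chow_liu()], [fit_mpom()], [fit_mice()]).
#' @return A `synth_model`.
#' @export
fit_generator <- function(data, family = c("im", "chowliu", "mpom", "mice"),
                          ...) {
  family <- match.arg(family)
  switch(family,
         im = fit_im(data),
         chowliu = fit_chow_liu(data, ...),
         mpom = fit_mpom(data, ...),
         mice = fit_mice(data, ...))
}

#' @export
summary.synth_model <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Serialize a table-based model to YAML
#'
#' Independent-marginals, Chow-Liu and mixture models are plain collections
#' of probability tables and serialize to a YAML document (weights and
#' tables inline) that `read_model()` restores exactly. MICE models embed
#' fitted classifier objects and are not YAML-serializable.
#'
#' @param model An `im_model`, `chowliu_model` or `mpom_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "mice_model"))
    stop("MICE models embed classifier fits and cannot be written as YAML")
  doc <- list(schema = lapply(model$schema, `[[`, "levels"))
  if (inherits(model, "im_model")) {
    doc$family <- "im"
    doc$marginals <- lapply(model$marginals, `[[`, "probs")
  } else if (inherits(model, "chowliu_model")) {
    doc$family <- "chowliu"
    doc$root <- model$root
    doc$edges <- apply(model$edges, 1L, as.list)
    doc$root_marginal <- model$root_marginal
    doc$cpts <- lapply(model$cpts, function(m) apply(m, 1L, as.list))
  } else if (inherits(model, "mpom_model")) {
    doc$family <- "mpom"
    doc$k <- model$k
    doc$alpha <- model$alpha
    doc$draws <- lapply(model$retained, function(d)
      list(nu = d$nu, psi = lapply(d$psi, function(m) apply(m, 2L, as.list))))
  } else stop("unsupported model class")
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- yaml::read_yaml(path)
  schema <- cat_schema(lapply(names(doc$schema), function(nm)
    cat_var(nm, as.character(doc$schema[[nm]]))))
  card <- schema_cardinalities(schema)
  if (doc$family == "im") {
    marg <- lapply(seq_along(card), function(j)
      pmf(schema[[j]], as.numeric(doc$marginals[[j]])))
    structure(list(marginals = marg, schema = schema, n_train = NA_integer_),
              class = c("im_model", "synth_model"))
  } else if (doc$family == "chowliu") {
    edges <- do.call(rbind, lapply(doc$edges, function(e)
      c(e[[1]], e[[2]])))
    if (is.null(edges)) edges <- matrix(integer(0), 0L, 2L)
    cpts <- lapply(doc$cpts, function(rows)
      do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r)))))
    structure(list(root = doc$root, edges = edges,
                   root_marginal = as.numeric(doc$root_marginal),
                   cpts = cpts, edge_mi = rep(NA_real_, nrow(edges)),
                   tree_weight = NA_real_, schema = schema,
                   n_train = NA_integer_, smoothing = NA_real_),
              class = c("chowliu_model", "synth_model"))
  } else if (doc$family == "mpom") {
    retained <- lapply(doc$draws, function(d)
      list(nu = as.numeric(d$nu),
           psi = lapply(seq_along(card), function(j)
             do.call(cbind, lapply(d$psi[[j]], function(col)
               as.numeric(unlist(col)))))))
    last <- retained[[length(retained)]]
    structure(list(k = doc$k, alpha = doc$alpha, nu = last$nu,
                   psi = last$psi, retained = retained, z = NULL,
                   schema = schema, n_train = NA_integer_,
                   settings = NULL),
              class = c("mpom_model", "synth_model"))
  } else stop("unknown model family '", doc$family, "'")
}
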