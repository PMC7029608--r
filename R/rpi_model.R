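#' Train the full interaction model on a labeled pair set
#'
#' Dataset-level counterpart of [stack_model()]: fits the protein
#' truncated-SVD reducer together with the stacked ensemble, nesting the
#' reducer inside the out-of-fold construction. For each internal fold the
#' reducer is refitted on that fold's training proteins only, so the
#' level-0 probabilities used to train the logistic merge reflect the same
#' projection shift that genuinely unseen proteins will undergo; a reducer
#' fitted once on all training proteins would make base learners that are
#' sensitive to that shift (the RBF SVM in particular) look better to the
#' merge than they are on new data.
#'
#' The reduction target is capped at one less than the number of distinct
#' training proteins (the rank bound of the uncentered SVD).
#'
#' @param pairs data.frame with `protein_id`, `rna_id`, `label`.
#' @param rna_features per-RNA feature matrix ([encode_rna()]).
#' @param protein_moments per-protein moment matrix ([encode_proteins()]).
#' @param n_components protein reduction target (default 500).
#' @param configs base-learner configurations ([default_configs()]).
#' @param strategy `"stacked"` or `"averaged"`, see [stack_model()].
#' @param n_inner_folds internal folds for the out-of-fold construction.
#' @param seed integer seed controlling all randomness.
#' @return object of class `rpi_model` with elements `reducer`, `bases`,
#'   `meta`, `strategy`, `seed`.
#' @export
rpi_model <- function(pairs, rna_features, protein_moments,
                      n_components = 500L, configs = default_configs(),
                      strategy = c("stacked", "averaged"),
                      n_inner_folds = 5L, seed = 1L) {
  strategy <- match.arg(strategy)
  y <- as.integer(pairs$label)
  build <- function(rows_fit, rows_out) {
    prot_fit <- unique(pairs$protein_id[rows_fit])
    d_eff <- min(n_components, length(prot_fit) - 1L, ncol(protein_moments))
    reducer <- fit_reducer(protein_moments[prot_fit, , drop = FALSE], d_eff)
    red <- predict(reducer, protein_moments)
    list(reducer = reducer,
         x_fit = make_pair_features(pairs[rows_fit, , drop = FALSE],
                                    red, rna_features),
         x_out = if (length(rows_out))
           make_pair_features(pairs[rows_out, , drop = FALSE],
                              red, rna_features))
  }
  meta <- NULL
  if (strategy == "stacked") {
    folds <- stratified_folds(y, n_inner_folds, seed)
    oof <- matrix(NA_real_, nrow = length(y), ncol = length(configs),
                  dimnames = list(NULL, names(configs)))
    for (f in seq_len(n_inner_folds)) {
      tr <- which(folds != f)
      held <- which(folds == f)
      parts <- build(tr, held)
      for (j in seq_along(configs)) {
        b <- fit_base(parts$x_fit, y[tr], configs[[j]], seed = seed + f)
        oof[held, j] <- predict_base(b, parts$x_out)
      }
    }
    meta <- fit_stack(oof, y)
  }
  parts <- build(seq_along(y), integer())
  bases <- lapply(configs, function(cfg)
    fit_base(parts$x_fit, y, cfg, seed = seed))
  structure(list(reducer = parts$reducer, bases = bases, meta = meta,
                 strategy = strategy, configs = configs, seed = seed,
                 n_components = n_components),
            class = "rpi_model")
}

#' Predict interaction probabilities for new pairs
#'
#' @param object an `rpi_model`.
#' @param pairs data.frame with `protein_id`, `rna_id` (a `label` column,
#'   if present, is ignored).
#' @param rna_features,protein_moments feature matrices covering the ids
#'   referenced by `pairs`.
#' @param type `"prob"` (default), `"class"` or `"all"`, as in
#'   [predict.stack_model()].
#' @param ... unused.
#' @return per `type`: probability vector, 0/1 vector, or list with the
#'   merged probability and base probability matrix.
#' @export
predict.rpi_model <- function(object, pairs, rna_features, protein_moments,
                              type = c("prob", "class", "all"), ...) {
  type <- match.arg(type)
  red <- predict(object$reducer, protein_moments)
  x <- make_pair_features(pairs, red, rna_features)
  P <- vapply(object$bases, predict_base, numeric(nrow(x)), x = x)
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L,
                                   dimnames = list(NULL, names(object$bases)))
  prob <- if (object$strategy == "stacked") {
    as.numeric(plogis(object$meta$intercept + P %*% object$meta$weights))
  } else {
    rowMeans(P)
  }
  switch(type,
    prob = prob,
    class = as.integer(prob >= 0.5),
    all = list(prob = prob, base = P))
}

#' @export
print.rpi_model <- function(x, ...) {
  cat(sprintf("rpi_model (%s): reducer %d -> %d, bases %s\n",
              x$strategy, nrow(x$reducer$rotation), x$reducer$n_components,
              paste(names(x$bases), collapse = " + ")))
  if (!is.null(x$meta)) {
    cat("level-1 weights:",
        paste(sprintf("%s=%.3f", names(x$meta$weights), x$meta$weights),
              collapse = ", "),
        sprintf("(intercept %.3f)\n", x$meta$intercept))
  }
  invisible(x)
}
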