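#' Base-learner configuration
#'
#' Builds the hyperparameter record for one of the three level-0
#' classifiers. Defaults: gradient-boosted trees (up to 500 rounds with
#' validation-based early stopping, depth 6, learning rate 0.1, L2 leaf
#' penalty 1, column subsampling 0.5); RBF-kernel
#' SVM (cost 1, gamma 1/d, internal standardization, Platt-calibrated
#' probabilities); extremely randomized trees (500 trees, one random
#' cut-point per candidate feature, no bootstrap).
#'
#' @param kind `"gbdt"`, `"svm_rbf"` or `"extratrees"`.
#' @param ... overrides of the kind's default hyperparameters.
#' @return list of class `base_config`.
#' @export
base_config <- function(kind = c("gbdt", "svm_rbf", "extratrees"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    gbdt = list(nrounds = 500L, max_depth = 6L, eta = 0.1, lambda = 1,
                colsample_bytree = 0.5, early_stopping = TRUE),
    svm_rbf = list(cost = 1, gamma = NULL),  # NULL gamma -> 1/ncol(x)
    extratrees = list(num_trees = 500L, mtry = NULL,
                      num_random_splits = 1L))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("base_config: unknown parameter(s) for ", kind, ": ",
                        paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  structure(c(list(kind = kind), defaults), class = "base_config")
}

#' Default level-0 classifier set
#'
#' @return named list of three [base_config()] objects in the canonical
#'   column order `gbdt`, `svm_rbf`, `extratrees`.
#' @export
default_configs <- function() {
  list(gbdt = base_config("gbdt"),
       svm_rbf = base_config("svm_rbf"),
       extratrees = base_config("extratrees"))
}

.check_xy <- function(x, y) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("x rows and y length differ")
  if (!all(is.finite(x))) stop("non-finite feature value(s)")
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L) stop("single-class labels: need both classes")
  x
}

#' Fit a single base classifier
#'
#' @param x numeric feature matrix.
#' @param y 0/1 integer labels.
#' @param config a [base_config()].
#' @param seed integer seed for the learner's randomness.
#' @return object of class `rp_base`; get probabilities with
#'   [predict_base()].
#' @export
fit_base <- function(x, y, config, seed = 1L) {
  x <- .check_xy(x, y)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  kind <- config$kind
  set.seed(seed)
  if (kind == "gbdt") {
    params <- list(objective = "binary:logistic",
                   max_depth = config$max_depth, eta = config$eta,
                   lambda = config$lambda,
                   colsample_bytree = config$colsample_bytree,
                   nthread = 1L, seed = seed)
    nrounds <- config$nrounds
    if (isTRUE(config$early_stopping)) {
      # choose the boosting length on a stratified 20% validation split
      # (patience 30), then refit on all rows at that length -- guards
      # against overfitting without a hand-picked round count
      vi <- unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        sample(idx, max(1L, round(0.2 * length(idx))))
      }), use.names = FALSE)
      probe <- xgboost::xgb.train(
        params = c(params, list(eval_metric = "logloss")),
        data = xgboost::xgb.DMatrix(x[-vi, , drop = FALSE], label = y[-vi]),
        evals = list(val = xgboost::xgb.DMatrix(x[vi, , drop = FALSE],
                                                label = y[vi])),
        nrounds = config$nrounds, early_stopping_rounds = 30L, verbose = 0)
      best <- suppressWarnings(
        as.integer(xgboost::xgb.attr(probe, "best_iteration")))
      if (!is.na(best) && best >= 1L) nrounds <- best
    }
    fit <- xgboost::xgb.train(params = params,
                              data = xgboost::xgb.DMatrix(x, label = y),
                              nrounds = nrounds, verbose = 0)
    scaling <- NULL
  } else if (kind == "svm_rbf") {
    # standardize here (constant columns get unit scale) so the SVM never
    # sees degenerate variance; tree learners are scale-invariant
    ctr <- colMeans(x)
    scl <- apply(x, 2L, sd)
    scl[scl == 0] <- 1
    xs <- scale(x, center = ctr, scale = scl)
    gamma <- if (is.null(config$gamma)) 1 / ncol(x) else config$gamma
    fit <- e1071::svm(xs, factor(y, levels = c(0L, 1L)), kernel = "radial",
                      cost = config$cost, gamma = gamma,
                      probability = TRUE, scale = FALSE)
    scaling <- list(center = ctr, scale = scl)
  } else {
    fit <- ranger::ranger(x = x, y = factor(y, levels = c(0L, 1L)),
                          num.trees = config$num_trees,
                          mtry = config$mtry,
                          splitrule = "extratrees",
                          num.random.splits = config$num_random_splits,
                          replace = FALSE, sample.fraction = 1,
                          probability = TRUE,
                          seed = seed, num.threads = 1L)
    scaling <- NULL
  }
  structure(list(kind = kind, fit = fit, config = config, scaling = scaling),
            class = "rp_base")
}

#' Probability of interaction from a fitted base classifier
#'
#' @param model an `rp_base` from [fit_base()].
#' @param x numeric feature matrix.
#' @return numeric vector of P(label = 1) per row.
#' @export
predict_base <- function(model, x) {
  if (!inherits(model, "rp_base")) stop("predict_base: not a fitted base learner")
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  switch(model$kind,
    gbdt = as.numeric(predict(model$fit, xgboost::xgb.DMatrix(x))),
    svm_rbf = {
      xs <- scale(x, center = model$scaling$center, scale = model$scaling$scale)
      pr <- predict(model$fit, xs, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "1"])
    },
    extratrees = as.numeric(predict(model$fit, data = x,
                                    num.threads = 1L)$predictions[, "1"]))
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds so that fold sizes differ by at
#' most one overall and within each class.
#'
#' @param y 0/1 labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  n <- length(y)
  if (length(unique(y)) < 2L || min(table(y)) < k) {
    stop("stratified_folds: fewer than ", k, " samples in a class")
  }
  set.seed(seed)
  ord <- unlist(lapply(unique(y), function(cl) sample(which(y == cl))),
                use.names = FALSE)
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(k), n)
  folds
}

#' Out-of-fold level-0 probability matrix
#'
#' For each training row, each base classifier's probability is produced by
#' a model fitted with that row's fold held out, so the level-1 merge never
#' sees probabilities from a model trained on its own input row.
#'
#' @param x numeric feature matrix.
#' @param y 0/1 labels.
#' @param configs named list of [base_config()]s (default
#'   [default_configs()]).
#' @param n_folds number of internal stratified folds (default 5).
#' @param seed RNG seed.
#' @return n x length(configs) matrix of probabilities, columns in config
#'   order, with the fold assignment attached as attribute `folds`.
#' @export
oof_probabilities <- function(x, y, configs = default_configs(),
                              n_folds = 5L, seed = 1L) {
  x <- .check_xy(x, y)
  folds <- stratified_folds(y, n_folds, seed)
  P <- matrix(NA_real_, nrow = nrow(x), ncol = length(configs),
              dimnames = list(NULL, names(configs)))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    for (j in seq_along(configs)) {
      m <- fit_base(x[tr, , drop = FALSE], y[tr], configs[[j]],
                    seed = seed + f)
      P[!tr, j] <- predict_base(m, x[!tr, , drop = FALSE])
    }
  }
  attr(P, "folds") <- folds
  P
}

#' Fit the level-1 logistic-regression merge
#'
#' Learns a weight per base classifier (plus intercept) from the level-0
#' probability matrix: the stacked probability is
#' `sigma(w' p + b)` with `sigma` the logistic function. With equal weights
#' the stacked score is a monotone function of the mean base probability,
#' i.e. the merge degenerates to the averaging strategy.
#'
#' @param oof n x B matrix of (out-of-fold) base probabilities in `[0, 1]`.
#' @param labels 0/1 labels.
#' @return object of class `stack_merge`: list with `weights` (length B),
#'   `intercept` and the underlying `glm` fit.
#' @export
fit_stack <- function(oof, labels) {
  oof <- as.matrix(oof)
  if (any(oof < 0 | oof > 1)) stop("fit_stack: base outputs must be probabilities")
  if (nrow(oof) != length(labels)) stop("fit_stack: row/label mismatch")
  const <- apply(oof, 2L, function(v) diff(range(v)) == 0)
  if (any(const)) {
    warning("fit_stack: constant base-probability column(s): ",
            paste(colnames(oof)[const], collapse = ", "))
  }
  df <- data.frame(y = labels, oof)
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  cf <- coef(fit)
  cf[is.na(cf)] <- 0
  structure(list(weights = cf[-1L], intercept = cf[[1L]], fit = fit),
            class = "stack_merge")
}

#' Train the full stacked (or averaged) ensemble
#'
#' Fits the three base classifiers and, for the stacked strategy, the
#' level-1 logistic merge on out-of-fold base probabilities; the base
#' learners are then refitted on all supplied rows for prediction.
#'
#' @param x numeric feature matrix (conjoint pair features).
#' @param y 0/1 labels.
#' @param configs named list of [base_config()]s.
#' @param strategy `"stacked"` (logistic-regression merge, default) or
#'   `"averaged"` (arithmetic mean of base probabilities).
#' @param n_inner_folds internal folds for the out-of-fold construction.
#' @param seed integer seed controlling all randomness.
#' @return object of class `stack_model`.
#' @export
stack_model <- function(x, y, configs = default_configs(),
                        strategy = c("stacked", "averaged"),
                        n_inner_folds = 5L, seed = 1L) {
  strategy <- match.arg(strategy)
  x <- .check_xy(x, y)
  meta <- NULL
  if (strategy == "stacked") {
    oof <- oof_probabilities(x, y, configs, n_inner_folds, seed)
    meta <- fit_stack(oof, y)
  }
  bases <- lapply(configs, function(cfg) fit_base(x, y, cfg, seed = seed))
  structure(list(bases = bases, meta = meta, strategy = strategy,
                 configs = configs, seed = seed),
            class = "stack_model")
}

#' Predict interaction probabilities from a stacked ensemble
#'
#' @param object a `stack_model`.
#' @param newdata numeric feature matrix.
#' @param type `"prob"` (default), `"class"` (label 1 iff probability
#'   >= 0.5) or `"all"` (list with the merged probability and the base
#'   probability matrix).
#' @param ... unused.
#' @return numeric vector, integer vector, or list, per `type`.
#' @export
predict.stack_model <- function(object, newdata,
                                type = c("prob", "class", "all"), ...) {
  type <- match.arg(type)
  P <- vapply(object$bases, predict_base, numeric(nrow(as.matrix(newdata))),
              x = newdata)
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
print.stack_model <- function(x, ...) {
  cat(sprintf("stack_model (%s): %s\n", x$strategy,
              paste(vapply(x$bases, `[[`, "", "kind"), collapse = " + ")))
  if (!is.null(x$meta)) {
    cat("level-1 weights:",
        paste(sprintf("%s=%.3f", names(x$meta$weights), x$meta$weights),
              collapse = ", "),
        sprintf("(intercept %.3f)\n", x$meta$intercept))
  }
  invisible(x)
}
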