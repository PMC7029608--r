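#' Confusion counts for binary predictions
#'
#' @param labels true 0/1 labels.
#' @param predictions predicted 0/1 labels.
#' @return named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("confusion_counts: length mismatch")
  }
  if (!all(labels %in% 0:1) || !all(predictions %in% 0:1)) {
    stop("confusion_counts: labels and predictions must be 0/1")
  }
  c(TP = sum(labels == 1L & predictions == 1L),
    TN = sum(labels == 0L & predictions == 0L),
    FP = sum(labels == 0L & predictions == 1L),
    FN = sum(labels == 1L & predictions == 0L))
}

#' Classification metrics from confusion counts
#'
#' Accuracy `(TN+TP)/(TN+TP+FN+FP)`, true positive rate `TP/(TP+FN)`,
#' true negative rate `TN/(TN+FP)`, positive predictive value `TP/(TP+FP)`
#' and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Ratios with a zero denominator are `NA`; MCC with a zero denominator is
#' 0 by convention (the classifier carries no information in that case).
#'
#' @param counts named vector from [confusion_counts()].
#' @return named numeric vector `c(Acc, TPR, TNR, PPV, MCC)`, all as
#'   fractions (multiply by 100 for the conventional percent reporting).
#' @export
classification_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  total <- tp + tn + fp + fn
  if (total == 0) stop("classification_metrics: empty confusion counts")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  c(Acc = (tn + tp) / total,
    TPR = ratio(tp, tp + fn),
    TNR = ratio(tn, tn + fp),
    PPV = ratio(tp, tp + fp),
    MCC = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den)
}

#' Area under the ROC curve
#'
#' Midrank (Mann-Whitney) AUC: the probability that a random positive
#' outscores a random negative, with ties contributing one half.
#'
#' @param labels true 0/1 labels (both classes required).
#' @param scores real-valued scores (higher = more positive).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("roc_auc: length mismatch")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("roc_auc: need both classes")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param labels true 0/1 labels.
#' @param scores real-valued scores.
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, one row per
#'   distinct score (plus the endpoints), suitable for plotting or TSV
#'   export.
#' @export
roc_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  keep <- !duplicated(sc, fromLast = TRUE)
  tpr <- cumsum(lab == 1L)[keep] / sum(lab == 1L)
  fpr <- cumsum(lab == 0L)[keep] / sum(lab == 0L)
  data.frame(threshold = c(Inf, sc[keep]),
             fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Splits the labeled pairs into stratified folds; within each fold the
#' protein truncated-SVD reducer and all classifiers are fitted on the
#' training pairs only and applied unchanged to the held-out pairs, so no
#' information flows from test to train. Per-fold metrics and their
#' mean and standard deviation are returned.
#'
#' The reduction target is capped (silently, per fold) at one less than the
#' number of distinct training proteins, the rank bound of the uncentered
#' SVD fit.
#'
#' @param pairs data.frame with `protein_id`, `rna_id`, `label`.
#' @param rna_features per-RNA feature matrix ([encode_rna()]).
#' @param protein_moments per-protein Legendre-moment matrix
#'   ([encode_proteins()]).
#' @param n_folds number of folds (default 5).
#' @param seed RNG seed controlling folds and classifier randomness.
#' @param configs base-classifier configurations.
#' @param n_components protein reduction target (default 500).
#' @param svd_scope `"fold"` (default; reducer fitted per training fold) or
#'   `"global"` (one reducer on all proteins, for replication of published
#'   protocols that reduce before splitting).
#' @param strategy ensemble strategy, see [stack_model()].
#' @param n_inner_folds internal folds for out-of-fold stacking.
#' @return object of class `rp_cv`: list with `metrics` (per-fold
#'   data.frame of Acc, TPR, TNR, PPV, MCC, AUC), `mean`, `sd`, `folds`,
#'   `scores` (held-out probabilities in pair order), `seed`.
#' @export
cross_validate <- function(pairs, rna_features, protein_moments,
                           n_folds = 5L, seed = 1L,
                           configs = default_configs(),
                           n_components = 500L,
                           svd_scope = c("fold", "global"),
                           strategy = c("stacked", "averaged"),
                           n_inner_folds = 5L) {
  svd_scope <- match.arg(svd_scope)
  strategy <- match.arg(strategy)
  y <- as.integer(pairs$label)
  folds <- stratified_folds(y, n_folds, seed)
  if (svd_scope == "global") {
    d_eff <- min(n_components, nrow(protein_moments) - 1L,
                 ncol(protein_moments))
    red_all <- predict(fit_reducer(protein_moments, d_eff), protein_moments)
  }
  per_fold <- vector("list", n_folds)
  scores <- numeric(length(y))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (svd_scope == "fold") {
      # full pipeline (reducer + learners) fitted on the training fold only
      model <- rpi_model(pairs[tr, , drop = FALSE], rna_features,
                         protein_moments, n_components = n_components,
                         configs = configs, strategy = strategy,
                         n_inner_folds = n_inner_folds, seed = seed + f)
      p <- predict(model, pairs[!tr, , drop = FALSE], rna_features,
                   protein_moments, type = "prob")
    } else {
      xtr <- make_pair_features(pairs[tr, , drop = FALSE], red_all,
                                rna_features)
      xte <- make_pair_features(pairs[!tr, , drop = FALSE], red_all,
                                rna_features)
      model <- stack_model(xtr, y[tr], configs, strategy,
                           n_inner_folds = n_inner_folds, seed = seed + f)
      p <- predict(model, xte, type = "prob")
    }
    scores[!tr] <- p
    cm <- classification_metrics(confusion_counts(y[!tr], as.integer(p >= 0.5)))
    per_fold[[f]] <- c(fold = f, cm, AUC = roc_auc(y[!tr], p))
  }
  metrics <- as.data.frame(do.call(rbind, per_fold))
  structure(list(metrics = metrics,
                 mean = colMeans(metrics[, -1L]),
                 sd = apply(metrics[, -1L], 2L, sd),
                 folds = folds, scores = scores, seed = seed,
                 n_components = n_components, svd_scope = svd_scope,
                 strategy = strategy),
            class = "rp_cv")
}

#' @export
print.rp_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s ensemble, %s-scope SVD, seed %d)\n",
              nrow(x$metrics), x$strategy, x$svd_scope, x$seed))
  m <- x$metrics
  m[, c("Acc", "TPR", "TNR", "PPV", "MCC")] <-
    round(100 * m[, c("Acc", "TPR", "TNR", "PPV", "MCC")], 2)
  m$AUC <- round(m$AUC, 3)
  print(m, row.names = FALSE)
  cat(sprintf("mean: Acc %.2f%% | TPR %.2f%% | TNR %.2f%% | PPV %.2f%% | MCC %.2f%% | AUC %.3f\n",
              100 * x$mean[["Acc"]], 100 * x$mean[["TPR"]],
              100 * x$mean[["TNR"]], 100 * x$mean[["PPV"]],
              100 * x$mean[["MCC"]], x$mean[["AUC"]]))
  invisible(x)
}

#' Write cross-validation results as TSV
#'
#' One row per fold plus a summary row (mean +/- sd), percentages for the
#' confusion-based metrics, mirroring the conventional benchmark-table
#' layout.
#'
#' @param cv an `rp_cv` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cv_results <- function(cv, path) {
  m <- cv$metrics
  fmt <- function(v, pct) if (pct) sprintf("%.2f", 100 * v) else sprintf("%.3f", v)
  body <- data.frame(fold = as.character(m$fold),
                     Acc = fmt(m$Acc, TRUE), TPR = fmt(m$TPR, TRUE),
                     TNR = fmt(m$TNR, TRUE), PPV = fmt(m$PPV, TRUE),
                     MCC = fmt(m$MCC, TRUE), AUC = fmt(m$AUC, FALSE))
  summ <- data.frame(
    fold = "mean±sd",
    Acc = sprintf("%.2f±%.2f", 100 * cv$mean[["Acc"]], 100 * cv$sd[["Acc"]]),
    TPR = sprintf("%.2f±%.2f", 100 * cv$mean[["TPR"]], 100 * cv$sd[["TPR"]]),
    TNR = sprintf("%.2f±%.2f", 100 * cv$mean[["TNR"]], 100 * cv$sd[["TNR"]]),
    PPV = sprintf("%.2f±%.2f", 100 * cv$mean[["PPV"]], 100 * cv$sd[["PPV"]]),
    MCC = sprintf("%.2f±%.2f", 100 * cv$mean[["MCC"]], 100 * cv$sd[["MCC"]]),
    AUC = sprintf("%.3f±%.3f", cv$mean[["AUC"]], cv$sd[["AUC"]]))
  write.table(rbind(body, summ), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
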