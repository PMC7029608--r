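test_that("confusion counts match hand tallies", {
  labels <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  preds <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)
  cc <- confusion_counts(labels, preds)
  expect_equal(cc, c(TP = 3L, TN = 4L, FP = 1L, FN = 2L))

  perfect <- confusion_counts(labels, labels)
  expect_equal(perfect[["FP"]], 0L)
  expect_equal(perfect[["FN"]], 0L)

  inverted <- confusion_counts(labels, 1 - labels)
  expect_equal(inverted[["TP"]], perfect[["FN"]])
  expect_equal(inverted[["FN"]], perfect[["TP"]])
  expect_equal(inverted[["FP"]], perfect[["TN"]])

  expect_error(confusion_counts(labels, preds[-1]), "length")
  expect_error(confusion_counts(labels, preds + 1), "0/1")
})

test_that("metrics reproduce hand-computed values", {
  m <- classification_metrics(c(TP = 3, TN = 4, FP = 1, FN = 2))
  expect_equal(m[["Acc"]], 0.7)
  expect_equal(m[["TPR"]], 0.6)
  expect_equal(m[["TNR"]], 0.8)
  expect_equal(m[["PPV"]], 0.75)
  expect_equal(m[["MCC"]], 10 / sqrt(600))  # ~0.4082

  p <- classification_metrics(c(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_true(all(p == 1))

  # all-positive predictions on balanced data: TNR = 0, MCC = 0 by convention
  ap <- classification_metrics(c(TP = 5, TN = 0, FP = 5, FN = 0))
  expect_equal(ap[["TNR"]], 0)
  expect_equal(ap[["MCC"]], 0)
  expect_error(classification_metrics(c(TP = 0, TN = 0, FP = 0, FN = 0)),
               "empty")
})

test_that("metrics are invariant under joint permutation of the inputs", {
  set.seed(31)
  labels <- rbinom(50, 1, 0.5)
  preds <- rbinom(50, 1, 0.5)
  perm <- sample(50)
  expect_equal(
    classification_metrics(confusion_counts(labels, preds)),
    classification_metrics(confusion_counts(labels[perm], preds[perm])))
})

test_that("AUC equals the pairwise Mann-Whitney oracle, ties half-weighted", {
  labels <- rep(c(1L, 0L), c(5, 5))
  expect_equal(roc_auc(labels, c(10:6, 5:1)), 1.0)
  expect_equal(roc_auc(labels, rep(2, 10)), 0.5)
  set.seed(32)
  for (i in 1:5) {
    lab <- c(1L, 0L, rbinom(48, 1, 0.5))
    sc <- round(rnorm(50), 1)  # coarse rounding to force some ties
    expect_equal(roc_auc(lab, sc), auc_brute(lab, sc))
  }
  expect_error(roc_auc(rep(1L, 5), rnorm(5)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(33)
  lab <- rbinom(80, 1, 0.5)
  sc <- rnorm(80) + lab
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(lab, sc), ref, tolerance = 1e-12)
})

test_that("roc_points starts at (0,0), ends at (1,1), is monotone", {
  set.seed(34)
  lab <- rbinom(40, 1, 0.5)
  sc <- rnorm(40)
  rp <- roc_points(lab, sc)
  expect_equal(c(rp$fpr[1], rp$tpr[1]), c(0, 0))
  expect_equal(c(rp$fpr[nrow(rp)], rp$tpr[nrow(rp)]), c(1, 1))
  expect_true(all(diff(rp$fpr) >= 0) && all(diff(rp$tpr) >= 0))
})

test_that("cross-validation partitions pairs and is reproducible", {
  sd <- small_dataset()
  red <- predict(fit_reducer(sd$feats$protein_moments, 20),
                 sd$feats$protein_moments)
  cv <- cross_validate(sd$ds$pairs, sd$feats$rna_features,
                       sd$feats$protein_moments,
                       n_folds = 5, seed = 9, configs = small_configs(),
                       n_components = 20)
  expect_s3_class(cv, "rp_cv")
  expect_equal(nrow(cv$metrics), 5)
  # folds partition all pairs with sizes differing by at most one
  expect_length(cv$folds, nrow(sd$ds$pairs))
  tab <- table(cv$folds)
  expect_true(max(tab) - min(tab) <= 1)
  # no train/test overlap: every pair is tested exactly once
  expect_equal(sum(tab), nrow(sd$ds$pairs))
  expect_true(all(cv$metrics$Acc >= 0 & cv$metrics$Acc <= 1))
  expect_true(all(cv$metrics$MCC >= -1 & cv$metrics$MCC <= 1))
  expect_true(all(cv$scores >= 0 & cv$scores <= 1))

  cv2 <- cross_validate(sd$ds$pairs, sd$feats$rna_features,
                        sd$feats$protein_moments,
                        n_folds = 5, seed = 9, configs = small_configs(),
                        n_components = 20)
  expect_identical(cv$metrics, cv2$metrics)
  expect_error(cross_validate(sd$ds$pairs[c(1:3, 41:43), ], sd$feats$rna_features,
                              sd$feats$protein_moments, n_folds = 5,
                              configs = small_configs()),
               "fewer than")
})

test_that("cv results serialize to a per-fold table with a summary row", {
  sd <- small_dataset()
  cv <- cached("small_cv", {
    cross_validate(sd$ds$pairs, sd$feats$rna_features,
                   sd$feats$protein_moments, n_folds = 3, seed = 10,
                   configs = small_configs(), n_components = 15)
  })
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cv_results(cv, f)
  tab <- read.delim(f, colClasses = "character")
  expect_equal(nrow(tab), 4)  # 3 folds + summary
  expect_equal(tab$fold[4], "mean±sd")
  expect_named(tab, c("fold", "Acc", "TPR", "TNR", "PPV", "MCC", "AUC"))
})
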