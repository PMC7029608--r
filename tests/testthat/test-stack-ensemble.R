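test_that("each base learner separates linearly separable data", {
  d <- separable_xy(n = 60, seed = 21)
  for (cfg in small_configs()) {
    m <- fit_base(d$x, d$y, cfg, seed = 1)
    acc <- mean(as.integer(predict_base(m, d$x) >= 0.5) == d$y)
    expect_equal(acc, 1.0)
  }
})

test_that("base learners are near chance when labels are independent of features", {
  set.seed(22)
  x <- matrix(rnorm(400 * 5), 400, 5)
  y <- rep(0:1, 200)
  tr <- 1:300
  for (cfg in small_configs()) {
    m <- fit_base(x[tr, ], y[tr], cfg, seed = 2)
    auc <- roc_auc(y[-tr], predict_base(m, x[-tr, ]))
    expect_gt(auc, 0.4)
    expect_lt(auc, 0.6)
  }
})

test_that("fit_base validates inputs", {
  d <- separable_xy(20)
  cfg <- base_config("gbdt")
  expect_error(fit_base(d$x, rep(1L, 20), cfg), "single-class")
  xna <- d$x; xna[1, 1] <- NaN
  expect_error(fit_base(xna, d$y, cfg), "non-finite")
  expect_error(base_config("gbdt", bogus = 1), "unknown parameter")
})

test_that("tree learners tolerate duplicated feature columns", {
  d <- separable_xy(n = 120, seed = 23)
  te <- separable_xy(n = 60, seed = 24)
  for (kind in c("gbdt", "extratrees")) {
    cfg <- small_configs()[[if (kind == "gbdt") "gbdt" else "extratrees"]]
    m1 <- fit_base(d$x, d$y, cfg, seed = 3)
    m2 <- fit_base(cbind(d$x, d$x), d$y, cfg, seed = 3)
    a1 <- mean(as.integer(predict_base(m1, te$x) >= 0.5) == te$y)
    a2 <- mean(as.integer(predict_base(m2, cbind(te$x, te$x)) >= 0.5) == te$y)
    expect_lt(abs(a1 - a2), 0.1)
  }
})

test_that("stratified folds partition samples with balanced sizes", {
  y <- rep(c(0L, 1L), c(44, 56))
  f <- stratified_folds(y, 5, seed = 4)
  expect_setequal(unique(f), 1:5)
  expect_true(max(table(f)) - min(table(f)) <= 1)
  for (k in 1:5) expect_true(all(table(y[f == k]) >= 1))
  expect_identical(f, stratified_folds(y, 5, seed = 4))
  expect_error(stratified_folds(rep(c(0L, 1L), c(3, 97)), 5), "fewer than")
})

test_that("out-of-fold probabilities are reproducible and leakage-free by construction", {
  d <- separable_xy(n = 100, seed = 25)
  cfgs <- small_configs()
  P1 <- oof_probabilities(d$x, d$y, cfgs, n_folds = 5, seed = 5)
  P2 <- oof_probabilities(d$x, d$y, cfgs, n_folds = 5, seed = 5)
  expect_identical(P1, P2)
  expect_equal(colnames(P1), c("gbdt", "svm_rbf", "extratrees"))
  expect_true(all(P1 >= 0 & P1 <= 1))
  folds <- attr(P1, "folds")
  expect_length(folds, 100)
  # strongly separable data: every base is informative out of fold
  for (j in 1:3) expect_gt(roc_auc(d$y, P1[, j]), 0.9)
})

test_that("the level-1 merge weights the informative base most", {
  set.seed(26)
  n <- 400
  y <- rep(0:1, n / 2)
  oof <- cbind(gbdt = plogis(ifelse(y == 1, 3, -3) + rnorm(n)),  # near perfect
               svm_rbf = runif(n),                               # chance
               extratrees = runif(n))                            # chance
  mrg <- fit_stack(oof, y)
  expect_equal(names(which.max(abs(mrg$weights))), "gbdt")
})

test_that("equal weights reduce the merge to the averaging strategy", {
  set.seed(27)
  P <- matrix(runif(300), 100, 3)
  equal <- list(weights = rep(1, 3), intercept = 0)
  stacked <- as.numeric(plogis(equal$intercept + P %*% equal$weights))
  avg <- rowMeans(P)
  expect_equal(cor(stacked, avg, method = "spearman"), 1.0)
})

test_that("identical base columns leave the ranking (and AUC) unchanged", {
  set.seed(28)
  y <- rep(0:1, 50)
  p <- plogis(ifelse(y == 1, 1, -1) + rnorm(100))
  oof <- cbind(gbdt = p, svm_rbf = p, extratrees = p)
  mrg <- fit_stack(oof, y)
  stacked <- plogis(mrg$intercept + oof %*% mrg$weights)
  expect_equal(roc_auc(y, stacked), roc_auc(y, p))
})

test_that("degenerate constant base columns fit with a warning", {
  y <- rep(0:1, 30)
  oof <- cbind(gbdt = plogis(ifelse(y == 1, 1, -1)),
               svm_rbf = rep(0.5, 60), extratrees = runif(60))
  expect_warning(mrg <- fit_stack(oof, y), "constant")
  expect_true(is.finite(mrg$intercept))
  expect_error(fit_stack(oof * 2, y), "probabilities")
})

test_that("stack_model predictions respect the 0.5 threshold and the mean rule", {
  d <- separable_xy(n = 80, seed = 29)
  cfgs <- small_configs()
  m <- stack_model(d$x, d$y, cfgs, strategy = "averaged", seed = 6)
  out <- predict(m, d$x, type = "all")
  expect_equal(out$prob, rowMeans(out$base))
  expect_equal(predict(m, d$x, type = "class"), as.integer(out$prob >= 0.5))
  # averaged strategy on fixed base outputs (0.2, 0.4, 0.9) scores 0.5
  expect_equal(mean(c(0.2, 0.4, 0.9)), 0.5)

  ms <- stack_model(d$x, d$y, cfgs, strategy = "stacked", seed = 6)
  p1 <- predict(ms, d$x)
  p2 <- predict(stack_model(d$x, d$y, cfgs, strategy = "stacked", seed = 6),
                d$x)
  expect_identical(p1, p2)  # same seed, bitwise-identical run
  expect_true(all(p1 >= 0 & p1 <= 1))
})
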