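# Shared fixtures. Heavy objects are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# fast base-learner configurations for unit tests (the statistical
# behaviour under test does not need full-size ensembles)
small_configs <- function() {
  list(gbdt = base_config("gbdt", nrounds = 60L, max_depth = 3L),
       svm_rbf = base_config("svm_rbf"),
       extratrees = base_config("extratrees", num_trees = 120L))
}

# a small but learnable synthetic dataset, featurized
small_dataset <- function() {
  cached("small_ds", {
    ds <- synth_generate(synth_config(n_pairs = 80L, seed = 42L))
    feats <- suppressMessages(featurize(ds$rnas, ds$proteins))
    list(ds = ds, feats = feats)
  })
}

# the full default-condition benchmark (600 pairs, beta = 0.9), featurized;
# used by the end-to-end acceptance checks
default_dataset <- function(seed = 1L) {
  cached(paste0("default_ds_", seed), {
    ds <- synth_generate(synth_config(seed = seed))
    feats <- suppressMessages(featurize(ds$rnas, ds$proteins))
    list(ds = ds, feats = feats)
  })
}

# simple 2-D separable classification problem
separable_xy <- function(n = 60L, seed = 1L) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- cbind(rnorm(n, mean = ifelse(y == 1, 3, -3)), rnorm(n))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = y)
}

write_temp_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
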