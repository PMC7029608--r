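test_that("kmer_index ranks k-mers lexicographically with A < C < G < U", {
  expect_equal(kmer_index("AAAA"), 1L)   # first of the 256 4-mers
  expect_equal(kmer_index("AAAC"), 2L)
  expect_equal(kmer_index("UUUU"), 256L) # last of 4^4
  expect_equal(kmer_labels(4)[c(1, 2, 256)], c("AAAA", "AAAC", "UUUU"))
  expect_equal(kmer_index(kmer_labels(3)[37]), 37L)
  expect_error(kmer_index("AANG"), "invalid letter")
})

test_that("build_kmer_matrix places ones at the scanned windows", {
  M <- build_kmer_matrix("AAAA", k = 4)
  expect_equal(dim(M), c(256L, 1L))
  expect_equal(sum(M), 1)
  expect_equal(unname(M[1, 1]), 1)

  # two windows of AAAAA, both equal to AAAA
  M2 <- build_kmer_matrix("AAAAA", k = 4)
  expect_equal(dim(M2), c(256L, 2L))
  expect_equal(as.numeric(M2[1, ]), c(1, 1))
  expect_equal(sum(M2), 5 - 4 + 1)

  # windows containing a non-ACGU letter are skipped as all-zero columns
  M3 <- build_kmer_matrix("ACGUN", k = 4)
  expect_equal(dim(M3), c(256L, 2L))
  expect_equal(unname(M3[kmer_index("ACGU"), 1]), 1)
  expect_equal(sum(M3[, 2]), 0)

  expect_error(build_kmer_matrix("ACG", k = 4), "shorter than k")
})

test_that("column sums are 0/1 and total count hits L-k+1 iff pure ACGU", {
  set.seed(11)
  for (i in 1:20) {
    L <- sample(10:120, 1)
    chars <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
    if (i %% 2 == 0) chars[sample(L, 2)] <- "N"  # half the cases impure
    seq <- paste(chars, collapse = "")
    M <- build_kmer_matrix(seq, k = 4)
    cs <- Matrix::colSums(M)
    expect_true(all(cs %in% c(0, 1)))
    if (!grepl("N", seq)) {
      expect_equal(sum(M), L - 4 + 1)
    } else {
      expect_lt(sum(M), L - 4 + 1)
    }
  }
})

test_that("aligned reduction equals the closed-form SVD of a one-hot-column matrix", {
  set.seed(2)
  for (i in 1:5) {
    seq <- paste(sample(c("A", "C", "G", "U"), 60, replace = TRUE),
                 collapse = "")
    M <- build_kmer_matrix(seq, 4)
    got <- reduce_rna(M)  # default mode: aligned
    # oracle: full dense SVD; singular values of M are sqrt of k-mer counts
    s <- svd(as.matrix(M))
    expect_equal(sort(got[got > 0], decreasing = TRUE),
                 s$d[s$d > 1e-12], tolerance = 1e-8)
    # and alignment: entry i is sqrt of the number of windows of k-mer i
    expect_equal(got, sqrt(as.numeric(Matrix::rowSums(M))), tolerance = 1e-12)
  }
})

test_that("leading mode returns sigma_1 * u_1 with a fixed sign convention", {
  # single 1 at row i: the only left-singular direction is e_i, sigma = 1
  M <- Matrix::sparseMatrix(i = 37, j = 1, x = 1, dims = c(256, 1))
  v <- reduce_rna(M, mode = "leading")
  expect_equal(v, as.numeric(1:256 == 37))

  # rank-1 matrix u v' with unit v: leading pair is (|u|, u/|u|)
  set.seed(2)
  u <- abs(rnorm(256))
  vv <- rnorm(10); vv <- vv / sqrt(sum(vv^2))
  v1 <- reduce_rna(u %*% t(vv), mode = "leading")
  expect_equal(v1, u, tolerance = 1e-10)
})

test_that("leading mode matches a full-SVD oracle on random binary matrices", {
  set.seed(3)
  for (i in 1:5) {
    M <- matrix(rbinom(256 * 10, 1, 0.1), 256, 10)
    if (all(M == 0)) M[1, 1] <- 1
    got <- reduce_rna(M, mode = "leading")
    s <- svd(M)  # full decomposition as the oracle
    want <- s$d[1] * s$u[, 1]
    if (want[which.max(abs(want))] < 0) want <- -want
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("duplicating a column of a rank-1 matrix rescales sigma_1, not the direction", {
  set.seed(4)
  u <- abs(rnorm(256))
  vv <- runif(6) + 0.5
  M <- u %*% t(vv)                    # rank 1: u spans the column space
  v1 <- reduce_rna(M, mode = "leading")
  v2 <- reduce_rna(cbind(M, M[, 3]), mode = "leading")  # rank stays 1
  d1 <- v1 / sqrt(sum(v1^2))
  d2 <- v2 / sqrt(sum(v2^2))
  expect_equal(d1, d2, tolerance = 1e-8)
  expect_gt(sqrt(sum(v2^2)), sqrt(sum(v1^2)))  # sigma_1 grew
})

test_that("reduce_rna modes: fixed output length and spectrum padding", {
  for (seq in c("ACGU", strrep("ACGU", 30), strrep("A", 7))) {
    for (mode in c("aligned", "leading", "spectrum")) {
      expect_length(reduce_rna(build_kmer_matrix(seq, 4), mode), 256L)
    }
  }
  M <- build_kmer_matrix(strrep("ACGU", 10), 4)
  sp <- reduce_rna(M, mode = "spectrum")
  expect_length(sp, 256L)
  expect_equal(sp[1:ncol(M)], svd(as.matrix(M))$d)
  expect_true(all(sp[(ncol(M) + 1):256] == 0))
  expect_error(reduce_rna(build_kmer_matrix("NNNNN", 4)), "all-zero")
})

test_that("encode_rna is deterministic and keeps ids", {
  seqs <- c(a = strrep("ACGU", 25), b = strrep("GGCAU", 20))
  e1 <- encode_rna(seqs)
  e2 <- encode_rna(seqs)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(2L, 256L))
  expect_equal(rownames(e1), c("a", "b"))
})
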