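#' Lexicographic rank of a k-mer
#'
#' Row index of a k-mer in the k-mer sparse matrix, under the lexicographic
#' ordering A < C < G < U ("AAAA" is row 1, "UUUU" is row 4^k).
#'
#' @param kmer character string over \{A, C, G, U\}.
#' @return integer row index in `[1, 4^nchar(kmer)]`.
#' @export
kmer_index <- function(kmer) {
  code <- .rna_codes(kmer)
  if (anyNA(code)) stop("kmer_index: invalid letter in k-mer '", kmer, "'")
  k <- length(code)
  as.integer(sum(code * 4^((k - 1L):0L)) + 1L)
}

# map a sequence string to 0..3 codes (A,C,G,U); NA for anything else
.rna_codes <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  m <- match(chars, RNA_ALPHABET)
  m - 1L
}

#' All k-mers over ACGU in lexicographic order
#' @param k word length.
#' @return character vector of length 4^k.
#' @export
kmer_labels <- function(k = 4L) {
  grids <- rev(rep(list(RNA_ALPHABET), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

#' Build the binary k-mer sparse matrix of an RNA sequence
#'
#' Scans the sequence from beginning to end with a window of k nucleotides,
#' moving one nucleotide at a time. Entry (i, j) is 1 iff window j equals
#' the i-th k-mer (lexicographic order). Windows containing a letter outside
#' \{A, C, G, U\} contribute an all-zero column, so the column count is
#' always L - k + 1.
#'
#' @param seq RNA sequence (string over ACGU; other letters allowed but
#'   their windows are skipped).
#' @param k window size (default 4, giving 256 rows).
#' @return a [Matrix::sparseMatrix()] of dimension 4^k x (L - k + 1) with
#'   k-mer rownames.
#' @export
build_kmer_matrix <- function(seq, k = 4L) {
  L <- nchar(seq)
  if (L < k) stop("build_kmer_matrix: sequence shorter than k (", L, " < ", k, ")")
  code <- .rna_codes(seq)
  ncols <- L - k + 1L
  # rolling base-4 rank of each window; windows touching an NA are skipped
  win <- stats::embed(code, k)             # row j = code[j+k-1], ..., code[j]
  pow <- 4^(0:(k - 1L))
  idx <- as.vector(win %*% pow) + 1L       # NA where any letter invalid
  j <- which(!is.na(idx))
  M <- Matrix::sparseMatrix(i = idx[j], j = j, x = 1,
                            dims = c(4L^k, ncols),
                            dimnames = list(kmer_labels(k), NULL))
  M
}

#' Reduce a k-mer sparse matrix to a fixed-length RNA feature vector
#'
#' Singular value decomposition of the 4^k x (L - k + 1) matrix yields a
#' fixed-length summary independent of sequence length. Because every
#' column of the k-mer matrix is one-hot (or all-zero), the Gram matrix
#' `M M'` is exactly diagonal, so the SVD is available in closed form: the
#' left singular vectors are the k-mer coordinate directions and the
#' singular value attached to direction i is `sqrt(count_i)`, the square
#' root of the number of windows spelling k-mer i.
#'
#' Modes:
#' * `"aligned"` (default): the full singular spectrum aligned with its
#'   left-singular (k-mer) directions, i.e. entry i = `sqrt(count_i)`.
#'   This keeps every singular pair and the k-mer identity of each.
#' * `"leading"`: sigma_1 * u_1 only (sign fixed so the largest-magnitude
#'   entry is positive). For this matrix family u_1 collapses to the
#'   indicator of the most frequent k-mer, so almost all information is
#'   discarded; the mode exists for comparison.
#' * `"spectrum"`: singular values sorted decreasingly, zero-padded to
#'   4^k; discards the k-mer identities.
#'
#' @param m matrix from [build_kmer_matrix()].
#' @param mode `"aligned"` (default), `"leading"` or `"spectrum"`.
#' @return numeric vector of length `nrow(m)` (256 at k = 4).
#' @export
reduce_rna <- function(m, mode = c("aligned", "leading", "spectrum")) {
  mode <- match.arg(mode)
  if (all(m == 0)) {
    stop("reduce_rna: all-zero k-mer matrix (no valid ACGU window)")
  }
  if (mode == "aligned") {
    # closed-form SVD of a one-hot-column matrix: M M' = diag(row counts)
    return(sqrt(as.numeric(Matrix::rowSums(m))))
  }
  dm <- as.matrix(m)
  if (mode == "spectrum") {
    d <- svd(dm, nu = 0L, nv = 0L)$d
    out <- numeric(nrow(dm))
    out[seq_along(d)] <- d
    return(out)
  }
  s <- svd(dm, nu = 1L, nv = 0L)
  v <- s$d[1L] * s$u[, 1L]
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

#' Encode a set of RNA sequences
#'
#' Convenience wrapper: k-mer sparse matrix then SVD reduction per sequence.
#'
#' @param seqs named character vector of RNA sequences.
#' @param k window size (default 4).
#' @param mode SVD reduction mode, see [reduce_rna()].
#' @return numeric matrix, one row per sequence (rownames = ids), 4^k columns.
#' @export
encode_rna <- function(seqs, k = 4L, mode = c("aligned", "leading", "spectrum")) {
  mode <- match.arg(mode)
  out <- t(vapply(seqs, function(s) reduce_rna(build_kmer_matrix(s, k), mode),
                  numeric(4L^k)))
  rownames(out) <- names(seqs)
  out
}
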