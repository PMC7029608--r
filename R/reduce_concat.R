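#' Fit an uncentered truncated-SVD reducer
#'
#' Truncated singular value decomposition of a feature matrix without
#' centering (unlike PCA, which decomposes the covariance of centered
#' data). Used to reduce protein Legendre-moment vectors from 676 to 500
#' dimensions. When `n_components` is not smaller than the number of rows
#' (or exceeds the number of columns) it is capped at
#' `min(nrow - 1, ncol)` with a warning.
#'
#' @param x numeric matrix, n rows (samples) x p columns (features).
#' @param n_components target dimension (default 500).
#' @return object of class `svd_reducer` with elements `rotation`
#'   (p x n_components right-singular basis), `d` (singular values) and
#'   `n_components`. Project new rows with [predict.svd_reducer()].
#' @export
fit_reducer <- function(x, n_components = 500L) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) stop("fit_reducer: need at least 2 rows")
  if (n_components >= n || n_components > p) {
    n_components <- min(n - 1L, p)
    warning("fit_reducer: n_components capped at ", n_components)
  }
  s <- svd(x, nu = 0L, nv = n_components)
  structure(list(rotation = s$v,
                 d = s$d[seq_len(n_components)],
                 n_components = as.integer(n_components)),
            class = "svd_reducer")
}

#' Project rows onto a fitted truncated-SVD basis
#'
#' @param object an `svd_reducer` from [fit_reducer()].
#' @param newdata numeric matrix (or single vector) with the same number of
#'   columns the reducer was fitted on.
#' @param ... unused.
#' @return matrix with `n_components` columns.
#' @export
predict.svd_reducer <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != nrow(object$rotation)) {
    stop("predict.svd_reducer: newdata has ", ncol(newdata),
         " columns, reducer expects ", nrow(object$rotation))
  }
  out <- as.matrix(newdata) %*% object$rotation
  rownames(out) <- rownames(newdata)
  out
}

#' @export
print.svd_reducer <- function(x, ...) {
  cat(sprintf("svd_reducer: %d -> %d (uncentered truncated SVD)\n",
              nrow(x$rotation), x$n_components))
  invisible(x)
}

#' Assemble conjoint pair feature vectors
#'
#' Concatenates, for each labeled pair, the (reduced) protein feature block
#' followed by the RNA feature block. At the package defaults (500 reduced
#' protein dimensions, 256 RNA dimensions) each pair vector has length 756.
#'
#' @param pairs data.frame with columns `protein_id`, `rna_id` and
#'   optionally `label`.
#' @param protein_features numeric matrix of per-protein features, rownames
#'   = protein ids.
#' @param rna_features numeric matrix of per-RNA features, rownames = RNA
#'   ids.
#' @return numeric matrix, one row per pair (in pair-list order), with the
#'   pair labels (if present) attached as attribute `labels`.
#' @export
make_pair_features <- function(pairs, protein_features, rna_features) {
  miss_p <- setdiff(pairs$protein_id, rownames(protein_features))
  if (length(miss_p)) {
    stop("make_pair_features: no protein feature row for id(s): ",
         paste(head(miss_p, 5L), collapse = ", "))
  }
  miss_r <- setdiff(pairs$rna_id, rownames(rna_features))
  if (length(miss_r)) {
    stop("make_pair_features: no RNA feature row for id(s): ",
         paste(head(miss_r, 5L), collapse = ", "))
  }
  x <- cbind(protein_features[pairs$protein_id, , drop = FALSE],
             rna_features[pairs$rna_id, , drop = FALSE])
  rownames(x) <- paste(pairs$protein_id, pairs$rna_id, sep = "|")
  colnames(x) <- c(paste0("prot", seq_len(ncol(protein_features))),
                   paste0("rna", seq_len(ncol(rna_features))))
  if (!is.null(pairs$label)) attr(x, "labels") <- as.integer(pairs$label)
  x
}
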