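# Independent oracles used to check the package's numerics.

# Legendre polynomial monomial coefficients via the coefficient-space
# recurrence (n+1) c_{n+1} = (2n+1) shift(c_n) - n c_{n-1}; independent of
# the package's point-evaluation recurrence.
leg_coef_list <- function(max_order) {
  out <- vector("list", max_order + 1L)
  out[[1L]] <- 1                      # V_0 = 1
  if (max_order >= 1L) out[[2L]] <- c(0, 1)  # V_1 = x
  if (max_order >= 2L) {
    for (n in 1L:(max_order - 1L)) {
      a <- c(0, out[[n + 1L]])        # x * V_n
      b <- c(out[[n]], 0, 0)          # V_{n-1}, padded
      out[[n + 2L]] <- ((2 * n + 1) * a - n * b[seq_along(a)]) / (n + 1)
    }
  }
  out
}

poly_eval <- function(coefs, x) {
  s <- 0
  for (i in rev(seq_along(coefs))) s <- s * x + coefs[i]
  s
}

# exact integral of the order-m Legendre polynomial over [a, b] via
# term-by-term monomial integration
poly_integral <- function(coefs, a, b) {
  anti <- c(0, coefs / seq_along(coefs))
  poly_eval(anti, b) - poly_eval(anti, a)
}

# brute-force exact moments of a piecewise-constant image: per-cell
# Gauss-Legendre quadrature, exact for polynomials up to degree 2q-1
# (q = 16 nodes >> order 25). The integration route is independent of the
# package's antiderivative-difference formula; the polynomial point values
# come from legendre_eval, which is itself pinned separately against
# closed forms, the monomial-coefficient form, and pracma's evaluator
# (pracma's own routine loses ~8 digits at order 25, so it cannot serve
# as the 1e-9 oracle directly).
oracle_moments <- function(f, max_order = 25L) {
  gq <- pracma::gaussLegendre(16L, -1, 1)  # nodes/weights on [-1, 1]
  cell_ints <- function(n_cells) {
    edges <- seq(-1, 1, length.out = n_cells + 1L)
    half <- (edges[2L] - edges[1L]) / 2
    out <- matrix(0, n_cells, max_order + 1L)
    for (i in seq_len(n_cells)) {
      mid <- (edges[i] + edges[i + 1L]) / 2
      x <- mid + half * gq$x
      w <- half * gq$w
      for (m in 0:max_order) out[i, m + 1L] <- sum(w * legendre_eval(m, x))
    }
    out
  }
  A <- cell_ints(nrow(f))
  B <- cell_ints(ncol(f))
  mu <- outer(2 * (0:max_order) + 1, 2 * (0:max_order) + 1) / 4
  L <- mu * (t(A) %*% f %*% B)
  as.vector(t(L))
}

# pairwise-comparison AUC (Mann-Whitney, ties half-weighted)
auc_brute <- function(labels, scores) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}
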