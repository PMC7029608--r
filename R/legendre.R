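#' Evaluate a Legendre polynomial
#'
#' Legendre polynomial of order `m` on `[-1, 1]`, evaluated by the stable
#' three-term recurrence `(n+1) P_{n+1}(x) = (2n+1) x P_n(x) - n P_{n-1}(x)`
#' (consistent with the Rodrigues form). Order `-1` is defined as
#' identically zero: this is the convention forced by the antiderivative
#' identity `int V_m dx = (V_{m+1} - V_{m-1}) / (2m+1)` at `m = 0`.
#'
#' @param m integer order, `m >= -1`.
#' @param x numeric vector of evaluation points in `[-1, 1]`.
#' @return numeric vector, `V_m(x)`.
#' @export
legendre_eval <- function(m, x) {
  if (m < -1L) stop("legendre_eval: order must be >= -1")
  if (m == -1L) return(numeric(length(x)) + 0 * x)
  .legendre_table(m, x)[m + 1L, ]
}

# rows = orders 0..max_order, columns = points
.legendre_table <- function(max_order, x) {
  P <- matrix(0, nrow = max_order + 1L, ncol = length(x))
  P[1L, ] <- 1
  if (max_order >= 1L) P[2L, ] <- x
  if (max_order >= 2L) {
    for (n in 1L:(max_order - 1L)) {
      P[n + 2L, ] <- ((2 * n + 1) * x * P[n + 1L, ] - n * P[n, ]) / (n + 1)
    }
  }
  P
}

#' Antiderivative difference of a Legendre polynomial across a cell
#'
#' `Delta(p, t, dt) = V_{p+1}(t + dt/2) - V_{p-1}(t + dt/2)
#'                  - V_{p+1}(t - dt/2) + V_{p-1}(t - dt/2)`,
#' so that `Delta(p, t, dt) / (2p + 1)` is exactly the integral of `V_p`
#' over the cell `[t - dt/2, t + dt/2]`.
#'
#' @param p integer order, `p >= 0`.
#' @param t cell center (vectorized).
#' @param dt cell width.
#' @return numeric vector.
#' @export
legendre_delta <- function(p, t, dt) {
  if (p < 0L) stop("legendre_delta: order must be >= 0")
  hi <- t + dt / 2
  lo <- t - dt / 2
  legendre_eval(p + 1L, hi) - legendre_eval(p - 1L, hi) -
    legendre_eval(p + 1L, lo) + legendre_eval(p - 1L, lo)
}

# per-axis matrix W with W[m+1, i] = integral of V_m over cell i
# = Delta(m, x_i, dt) / (2m + 1); cells tile [-1, 1] exactly with
# centers x_i = -1 + (2i - 1)/n and width 2/n (pixel-center convention)
.cell_integrals <- function(n_cells, max_order) {
  centers <- -1 + (2 * seq_len(n_cells) - 1) / n_cells
  dt <- 2 / n_cells
  Thi <- .legendre_table(max_order + 1L, centers + dt / 2)
  Tlo <- .legendre_table(max_order + 1L, centers - dt / 2)
  W <- matrix(0, nrow = max_order + 1L, ncol = n_cells)
  for (m in 0:max_order) {
    vm1_hi <- if (m == 0L) 0 else Thi[m, ]
    vm1_lo <- if (m == 0L) 0 else Tlo[m, ]
    W[m + 1L, ] <- (Thi[m + 2L, ] - vm1_hi - Tlo[m + 2L, ] + vm1_lo) / (2 * m + 1)
  }
  W
}

#' Exact discrete 2-D Legendre moments of a matrix
#'
#' Treats an R x S matrix `f` as a piecewise-constant image on
#' `[-1, 1] x [-1, 1]` (rows mapped to x, columns to y, cell centers at
#' `x_i = -1 + (2i - 1)/R`) and computes
#' `L_mn = mu_mn * sum_ij [Delta(m, x_i)/(2m+1)] [Delta(n, y_j)/(2n+1)] f_ij`
#' with `mu_mn = (2m+1)(2n+1)/4`. Because the per-cell integrals of the
#' Legendre polynomials are evaluated in closed form via antiderivative
#' differences, the result carries no quadrature error: it equals the true
#' moment integral of the piecewise-constant image.
#'
#' @param f numeric matrix (for protein profiles: the l x 20 PWM), or a
#'   `pwm_profile` object.
#' @param max_order maximum order per axis (default 25, giving a
#'   `(25+1)^2 = 676`-dimensional moment vector).
#' @return named numeric vector of length `(max_order + 1)^2`, row-major
#'   over orders `(m, n)` (names `L<m>_<n>`).
#' @export
legendre_moments <- function(f, max_order = 25L) {
  if (inherits(f, "pwm_profile")) f <- f$matrix
  f <- as.matrix(f)
  if (nrow(f) == 0L || ncol(f) == 0L) stop("legendre_moments: empty matrix")
  if (!all(is.finite(f))) stop("legendre_moments: non-finite value(s)")
  A <- .cell_integrals(nrow(f), max_order)
  B <- .cell_integrals(ncol(f), max_order)
  mu <- outer(2 * (0:max_order) + 1, 2 * (0:max_order) + 1) / 4
  L <- mu * (A %*% f %*% t(B))
  v <- as.vector(t(L))  # row-major over (m, n)
  names(v) <- as.vector(t(outer(0:max_order, 0:max_order,
                                function(m, n) sprintf("L%d_%d", m, n))))
  v
}

#' Legendre-moment vectors for a set of protein profiles
#'
#' @param profiles named list of `pwm_profile` objects
#'   (from [protein_profiles()]).
#' @param max_order maximum order per axis (default 25).
#' @return numeric matrix, one row per protein, `(max_order + 1)^2` columns.
#' @export
encode_proteins <- function(profiles, max_order = 25L) {
  out <- t(vapply(profiles, legendre_moments, numeric((max_order + 1L)^2),
                  max_order = max_order))
  rownames(out) <- names(profiles)
  out
}
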