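# ---------------------------------------------------------------------------
# Truncated tensor algebra over R^d.
#
# A truncated tensor holds, for each level k = 0..p, the coefficient vector of
# the level-k component in row-major multi-index order: the word (i1,...,ik)
# sits at position sum_j (i_j - 1) * d^(k - j) + 1.  Level 0 is a scalar.
# ---------------------------------------------------------------------------

new_tensor <- function(d, p, levels) {
  structure(list(d = as.integer(d), p = as.integer(p), levels = levels),
            class = "truncated_tensor")
}

#' Identity element of the truncated tensor algebra
#'
#' @param d alphabet size (number of channels).
#' @param p truncation level.
#' @return A `truncated_tensor` with level-0 coefficient 1 and all higher
#'   levels zero; the neutral element of [tensor_mul()].
#' @export
tensor_identity <- function(d, p) {
  stopifnot(d >= 1, p >= 1)
  levels <- vector("list", p + 1L)
  levels[[1L]] <- 1
  for (k in seq_len(p)) levels[[k + 1L]] <- numeric(d^k)
  new_tensor(d, p, levels)
}

# Kronecker product of two flat level vectors, first factor's index major.
.tkron <- function(a, b) {
  rep(a, each = length(b)) * rep.int(b, length(a))
}

#' Signature of a single linear segment
#'
#' The signature of a straight-line segment with increment `increment` is the
#' tensor exponential of its level-1 element: level k equals the k-fold tensor
#' power of the increment divided by k!.
#'
#' @param increment numeric vector of per-channel increments (length d).
#' @param p truncation level (>= 1).
#' @return A `truncated_tensor`.
#' @export
segment_signature <- function(increment, p) {
  if (length(increment) < 1L || anyNA(increment))
    stop("'increment' must be a non-empty numeric vector")
  if (p < 1L) stop("truncation level 'p' must be >= 1")
  d <- length(increment)
  levels <- vector("list", p + 1L)
  levels[[1L]] <- 1
  lv <- as.numeric(increment)
  levels[[2L]] <- lv
  if (p >= 2L) for (k in 2:p) {
    lv <- .tkron(lv, increment) / k
    levels[[k + 1L]] <- lv
  }
  new_tensor(d, p, levels)
}

#' Chen (concatenation) product of two truncated tensors
#'
#' Level k of the product is the convolution `sum_j A_j (x) B_(k-j)`.  This is
#' the product under which the signature of a concatenated path is the product
#' of the segment signatures (Chen's identity).
#'
#' @param A,B `truncated_tensor` objects sharing `d` and `p`.
#' @return A `truncated_tensor`.
#' @export
tensor_mul <- function(A, B) {
  if (A$d != B$d || A$p != B$p)
    stop("tensors must share alphabet size 'd' and truncation level 'p'")
  p <- A$p
  levels <- vector("list", p + 1L)
  for (k in 0:p) {
    acc <- 0
    for (j in 0:k) {
      acc <- acc + .tkron(A$levels[[j + 1L]], B$levels[[k - j + 1L]])
    }
    levels[[k + 1L]] <- acc
  }
  new_tensor(A$d, p, levels)
}

# a <- a + s * b on the level lists of two tensors
.tensor_axpy <- function(a, s, b) {
  for (k in seq_along(a)) a[[k]] <- a[[k]] + s * b[[k]]
  a
}

#' Tensor logarithm
#'
#' The truncated power series `log(A) = sum_{n>=1} (-1)^(n+1) (A - 1)^n / n`.
#' Requires the level-0 coefficient of `A` to equal 1 (as it does for any
#' signature).
#'
#' @param A a `truncated_tensor` with unit level-0 coefficient.
#' @param tol tolerance on the level-0 check.
#' @return A `truncated_tensor` with zero level-0 coefficient (a Lie series
#'   when `A` is a signature).
#' @export
tensor_log <- function(A, tol = 1e-9) {
  if (abs(A$levels[[1L]] - 1) > tol)
    stop("tensor_log requires a level-0 coefficient equal to 1")
  p <- A$p
  B <- A
  B$levels[[1L]] <- 0
  out <- B$levels
  P <- B
  if (p >= 2L) for (n in 2:p) {
    P <- tensor_mul(P, B)
    out <- .tensor_axpy(out, (-1)^(n + 1) / n, P$levels)
  }
  new_tensor(A$d, p, out)
}

#' Tensor exponential
#'
#' Inverse of [tensor_log()] for tensors with zero level-0 coefficient.
#'
#' @param T_ a `truncated_tensor` with zero level-0 coefficient.
#' @return A `truncated_tensor` with unit level-0 coefficient.
#' @export
tensor_exp <- function(T_) {
  if (abs(T_$levels[[1L]]) > 1e-9)
    stop("tensor_exp requires a zero level-0 coefficient")
  p <- T_$p
  out <- tensor_identity(T_$d, p)$levels
  term <- T_
  out <- .tensor_axpy(out, 1, term$levels)
  if (p >= 2L) for (n in 2:p) {
    term <- tensor_mul(term, T_)
    term$levels <- lapply(term$levels, function(v) v / n)
    out <- .tensor_axpy(out, 1, term$levels)
  }
  new_tensor(T_$d, p, out)
}

#' Truncate a tensor to a lower level
#'
#' @param A a `truncated_tensor`.
#' @param q target level `<= A$p`.
#' @return A `truncated_tensor` of level `q`.
#' @export
truncate_tensor <- function(A, q) {
  stopifnot(q >= 1, q <= A$p)
  new_tensor(A$d, q, A$levels[seq_len(q + 1L)])
}

#' Signature of a piecewise-linear path
#'
#' Computes the truncated signature of the piecewise-linear path through the
#' given points as the Chen product of per-segment signatures.  Level 1 of the
#' result equals the total increment (last point minus first); the signature is
#' invariant under subdivision of segments (reparameterisation invariance).
#'
#' @param points numeric matrix, one row per point, `d` columns; at least two
#'   rows.  Consecutive duplicate rows are permitted (zero segments).
#' @param p truncation level.
#' @return A `truncated_tensor`.
#' @export
path_signature <- function(points, p) {
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    stop("a path needs at least 2 points")
  if (anyNA(points)) stop("path points must not contain NA")
  incs <- diff(points)
  sig <- segment_signature(incs[1L, ], p)
  if (nrow(incs) >= 2L) for (s in 2:nrow(incs)) {
    sig <- tensor_mul(sig, segment_signature(incs[s, ], p))
  }
  sig
}

#' Extract one signature coefficient by multi-index
#'
#' @param A a `truncated_tensor`.
#' @param multi_index integer vector of letters in `1..d`.
#' @return The coefficient of the word `multi_index`.
#' @export
tensor_coefficient <- function(A, multi_index) {
  k <- length(multi_index)
  stopifnot(k >= 0, k <= A$p, all(multi_index >= 1), all(multi_index <= A$d))
  if (k == 0L) return(A$levels[[1L]])
  pos <- sum((multi_index - 1) * A$d^((k - 1):0)) + 1
  A$levels[[k + 1L]][pos]
}

#' Brute-force iterated integral (verification oracle)
#'
#' Evaluates a single coordinate iterated integral of a piecewise-linear path
#' by nested left-Riemann sums on a uniform grid refined so that segment
#' endpoints are grid points.  Slow; used only to cross-check
#' [path_signature()].
#'
#' @param points path points (matrix, one row per point).
#' @param multi_index integer vector of channel indices (the word).
#' @param n_steps subdivision count per linear segment (>= 100 recommended;
#'   the left-Riemann bias decays like 1/n_steps).
#' @return The (approximate) iterated-integral coefficient.
#' @export
brute_force_coefficient <- function(points, multi_index, n_steps = 10000L) {
  points <- as.matrix(points)
  nseg <- nrow(points) - 1L
  stopifnot(nseg >= 1L, length(multi_index) >= 1L)
  m <- max(1L, as.integer(n_steps))
  # grid of path values; each segment subdivided into m equal pieces
  frac <- seq_len(m) / m
  rows <- vector("list", nseg + 1L)
  rows[[1L]] <- points[1L, , drop = FALSE]
  for (s in seq_len(nseg)) {
    a <- points[s, ]
    b <- points[s + 1L, ]
    seg <- outer(1 - frac, a) + outer(frac, b)
    rows[[s + 1L]] <- seg
  }
  X <- do.call(rbind, rows)
  G <- nrow(X)
  f <- rep.int(1, G)
  for (idx in multi_index) {
    dX <- diff(X[, idx])
    f <- c(0, cumsum(f[-G] * dX))
  }
  f[G]
}

#' @export
print.truncated_tensor <- function(x, ...) {
  cat(sprintf("Truncated tensor: d = %d, level p = %d\n", x$d, x$p))
  cat(sprintf("  level 0: %g\n", x$levels[[1L]]))
  cat(sprintf("  level 1: %s\n",
              paste(signif(x$levels[[2L]], 4), collapse = " ")))
  if (x$p >= 2L)
    cat(sprintf("  (levels 2..%d: %s coefficients)\n", x$p,
                paste(x$d^(2:x$p), collapse = ", ")))
  invisible(x)
}
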