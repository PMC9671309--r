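# ---------------------------------------------------------------------------
# Lyndon-word basis of the truncated free Lie algebra, and log-signature
# coordinates on it.
#
# The log-signature of a path lives in the free Lie algebra over the d
# channels; Lyndon words of length <= p index a basis of its truncation.  We
# expand the standard bracketing of each Lyndon word into tensor coordinates
# once per (d, p), factor the resulting per-level matrices, and recover the
# coordinates of any tensor logarithm by linear solves.
# ---------------------------------------------------------------------------

.moodsig_cache <- new.env(parent = emptyenv())

# Duval's algorithm: all Lyndon words over {1..d} of length <= p, lexicographic.
.duval <- function(d, p) {
  out <- list()
  w <- 1L
  repeat {
    out[[length(out) + 1L]] <- w
    # extend periodically to length p
    w <- w[((seq_len(p) - 1L) %% length(w)) + 1L]
    while (length(w) && w[length(w)] == d) w <- w[-length(w)]
    if (!length(w)) break
    w[length(w)] <- w[length(w)] + 1L
  }
  out
}

#' Number of Lyndon words via the Witt formula
#'
#' Returns `sum_{k<=p} (1/k) sum_{m|k} mu(m) d^(k/m)`, the dimension of the
#' free Lie algebra over `d` letters truncated at level `p` — hence the length
#' of a level-`p` log-signature feature vector.
#'
#' @param d alphabet size.
#' @param p truncation level.
#' @return Integer word count.
#' @export
witt_dimension <- function(d, p) {
  mobius <- function(n) {
    if (n == 1L) return(1L)
    f <- n
    primes <- integer(0)
    q <- 2L
    while (q * q <= f) {
      if (f %% q == 0L) {
        f <- f %/% q
        if (f %% q == 0L) return(0L)
        primes <- c(primes, q)
      } else q <- q + 1L
    }
    if (f > 1L) primes <- c(primes, f)
    as.integer((-1L)^length(primes))
  }
  total <- 0
  for (k in seq_len(p)) {
    divs <- which(k %% seq_len(k) == 0L)
    total <- total + sum(vapply(divs, mobius, integer(1)) * d^(k / divs)) / k
  }
  as.integer(round(total))
}

#' Lyndon words over an alphabet, ordered by length then lexicographically
#'
#' A Lyndon word is strictly smaller than all of its proper rotations.  The
#' words of length `<= p` over `{1..d}` index a basis of the truncated free
#' Lie algebra; they are returned sorted primarily by length and secondarily
#' lexicographically, so level-1 (single-letter) coordinates come first.
#'
#' @param d alphabet size (>= 1).
#' @param p maximum word length (>= 1).
#' @return An object of class `lyndon_basis`: list with `d`, `p`, `words`
#'   (list of integer vectors) and `strings` (words pasted without separator).
#' @export
lyndon_words <- function(d, p) {
  stopifnot(d >= 1, p >= 1)
  words <- .duval(as.integer(d), as.integer(p))
  lens <- lengths(words)
  strs <- vapply(words, paste, character(1), collapse = "")
  ord <- order(lens, strs)
  words <- words[ord]
  structure(list(d = as.integer(d), p = as.integer(p),
                 words = words, strings = strs[ord],
                 lengths = lens[ord]),
            class = "lyndon_basis")
}

#' @export
print.lyndon_basis <- function(x, ...) {
  cat(sprintf("Lyndon basis: d = %d, p = %d, %d words\n",
              x$d, x$p, length(x$words)))
  cat(" ", paste(utils::head(x$strings, 20L), collapse = " "))
  if (length(x$strings) > 20L) cat(" ...")
  cat("\n")
  invisible(x)
}

# Expand the standard (right) bracketing of a Lyndon word into the flat
# level-|w| tensor coordinate vector.  [a, b] = a (x) b - b (x) a.
.lyndon_expand <- function(w, d) {
  k <- length(w)
  if (k == 1L) {
    v <- numeric(d)
    v[w] <- 1
    return(v)
  }
  is_lyndon <- function(u) {
    n <- length(u)
    if (n == 1L) return(TRUE)
    s <- paste(u, collapse = ",")
    for (i in 2:n)
      if (paste(c(u[i:n], u[1:(i - 1L)]), collapse = ",") <= s) return(FALSE)
    TRUE
  }
  # standard factorization: v is the longest proper Lyndon suffix
  split_at <- 0L
  for (i in 2:k) {
    if (is_lyndon(w[i:k])) { split_at <- i; break }
  }
  a <- .lyndon_expand(w[1:(split_at - 1L)], d)
  b <- .lyndon_expand(w[split_at:k], d)
  .tkron(a, b) - .tkron(b, a)
}

# Basis + per-level QR factorizations of the bracket-expansion matrices,
# cached per (d, p).
.logsig_basis <- function(d, p) {
  key <- paste0(d, "_", p)
  hit <- .moodsig_cache[[key]]
  if (!is.null(hit)) return(hit)
  basis <- lyndon_words(d, p)
  proj <- vector("list", p)
  for (k in seq_len(p)) {
    idx <- which(basis$lengths == k)
    if (!length(idx)) { proj[[k]] <- NULL; next }
    E <- vapply(basis$words[idx], .lyndon_expand, numeric(d^k), d = d)
    proj[[k]] <- qr(as.matrix(E))
  }
  out <- list(basis = basis, proj = proj)
  assign(key, out, envir = .moodsig_cache)
  out
}

#' Log-signature of a piecewise-linear path on the Lyndon basis
#'
#' Computes the tensor logarithm of the truncated path signature and expresses
#' it in the basis of standard bracketings of Lyndon words, solving one
#' triangular-by-construction linear system per level.  Level-1 coordinates
#' equal the per-channel total increments.
#'
#' @param points path points (matrix, one row per point, `d` columns).
#' @param p truncation level (the study default is 3).
#' @return An object of class `logsig_feature`: list with `coords` (named
#'   numeric vector, one entry per Lyndon word, ordered by length then
#'   lexicographically), `basis`, `d` and `p`.
#' @examples
#' ls1 <- logsig(rbind(c(0, 0), c(1, 0), c(1, 1)), p = 2)
#' ls1$coords  # increments 1, 1 and Levy area 0.5 on word "12"
#' @export
logsig <- function(points, p) {
  points <- as.matrix(points)
  d <- ncol(points)
  bp <- .logsig_basis(d, p)
  L <- tensor_log(path_signature(points, p))
  coords <- numeric(length(bp$basis$words))
  names(coords) <- bp$basis$strings
  for (k in seq_len(p)) {
    idx <- which(bp$basis$lengths == k)
    if (!length(idx)) next
    coords[idx] <- qr.coef(bp$proj[[k]], L$levels[[k + 1L]])
  }
  structure(list(coords = coords, basis = bp$basis, d = d, p = as.integer(p)),
            class = "logsig_feature")
}

#' @export
print.logsig_feature <- function(x, ...) {
  cat(sprintf("Log-signature feature: d = %d, p = %d, %d coordinates\n",
              x$d, x$p, length(x$coords)))
  print(signif(utils::head(x$coords, 15L), 4))
  if (length(x$coords) > 15L) cat("  ...\n")
  invisible(x)
}
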