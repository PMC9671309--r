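# ---------------------------------------------------------------------------
# Comparison models: naive per-window mean scores, and KNN / probabilistic-PCA
# imputation feeding flattened window vectors.  All run under the identical
# cross-validation, voting and evaluation harness as the log-signature model.
# ---------------------------------------------------------------------------

# Cohort weekly observation matrix: one row per participant-week, NA marks a
# missing response.  Also returns the row range of each stream.
.weekly_matrix <- function(cohort) {
  mats <- lapply(cohort, function(s) {
    m <- s$scores
    m[m == s$sentinel] <- NA
    m
  })
  X <- do.call(rbind, mats)
  rownames(X) <- NULL
  ns <- vapply(mats, nrow, integer(1))
  offsets <- cumsum(c(0L, ns[-length(ns)]))
  names(offsets) <- names(cohort)
  list(X = X, offsets = offsets, n_weeks = ns,
       row_participant = rep(names(cohort), ns))
}

# Window index table aligned with cut_windows(): one row per window with the
# global starting row into the weekly matrix.
.window_index <- function(cohort, spec) {
  wm <- .weekly_matrix(cohort)
  rows <- lapply(seq_along(cohort), function(i) {
    W <- wm$n_weeks[i]
    if (W < spec$width) return(NULL)
    starts <- seq.int(1L, W - spec$width + 1L, by = spec$stride)
    data.frame(participant_id = names(cohort)[i],
               diagnosis = cohort[[i]]$diagnosis,
               global_start = wm$offsets[i] + starts,
               stringsAsFactors = FALSE)
  })
  list(index = do.call(rbind, rows), weekly = wm)
}

#' Naive per-window mean-score features
#'
#' The clinic-style summary: the arithmetic mean of each instrument's valid
#' (non-missing) scores over the window's ten weeks.  A channel with no valid
#' value inside the window falls back to the participant's full-stream mean of
#' that channel; if the channel is never observed anywhere the error names the
#' participant and channel.
#'
#' @param window_scores width x 4 matrix of raw scores with `NA` (or the
#'   sentinel) for missing entries.
#' @param stream_scores the participant's full W x 4 raw matrix, used for the
#'   fallback.
#' @param participant_id used in error messages.
#' @param sentinel missing-value code, converted to `NA` internally.
#' @return Numeric 4-vector of per-channel means on the raw score scale.
#' @export
naive_features <- function(window_scores, stream_scores = window_scores,
                           participant_id = "?",
                           sentinel = MOODSIG_SENTINEL) {
  window_scores[window_scores == sentinel] <- NA
  stream_scores[stream_scores == sentinel] <- NA
  vapply(seq_len(ncol(window_scores)), function(ch) {
    v <- window_scores[, ch]
    if (any(!is.na(v))) return(mean(v, na.rm = TRUE))
    fv <- stream_scores[, ch]
    if (all(is.na(fv)))
      stop(sprintf("participant %s: channel %d never observed",
                   participant_id, ch))
    mean(fv, na.rm = TRUE)
  }, numeric(1))
}

#' K-nearest-neighbour imputation of weekly observations
#'
#' Distances between weekly observation rows are missing-aware Euclidean
#' distances: squared differences over mutually observed channels, rescaled
#' by the fraction of channels used, then square-rooted.  Each missing entry
#' is replaced by the mean of that variable over the `K` nearest rows in
#' `pool` where it is observed.  Rows sharing no observed channel with a
#' candidate are infinitely far; a target row with no observed channel at all
#' (a fully missing week) falls back to the pool column mean.
#'
#' @param X numeric matrix with `NA` for missing entries.
#' @param K neighbour count (default 5).
#' @param pool matrix of candidate neighbour rows (defaults to `X` itself).
#' @return `X` with every `NA` replaced; observed entries untouched.
#' @export
knn_impute <- function(X, K = 5L, pool = X) {
  stopifnot(K >= 1L, ncol(X) == ncol(pool))
  if (!anyNA(X)) return(X)
  D <- ncol(X)
  obs_ok <- colSums(!is.na(pool))
  if (any(obs_ok == 0L))
    stop("variable(s) never observed in the neighbour pool: ",
         paste(which(obs_ok == 0L), collapse = ", "))
  pool_obs <- !is.na(pool)
  col_means <- colMeans(pool, na.rm = TRUE)
  out <- X
  short <- FALSE
  for (i in which(rowSums(is.na(X)) > 0L)) {
    x <- X[i, ]
    xobs <- !is.na(x)
    if (!any(xobs)) {
      out[i, !xobs] <- col_means[!xobs]
      next
    }
    diffs <- sweep(pool[, xobs, drop = FALSE], 2L, x[xobs])
    shared <- pool_obs[, xobs, drop = FALSE]
    d2 <- rowSums(diffs^2 * shared, na.rm = TRUE)
    nsh <- rowSums(shared)
    dist <- sqrt(D * d2 / nsh)
    dist[nsh == 0L] <- Inf
    for (v in which(!xobs)) {
      cand <- which(pool_obs[, v] & is.finite(dist))
      if (!length(cand)) {
        out[i, v] <- col_means[v]
        next
      }
      if (length(cand) < K) short <- TRUE
      take <- cand[order(dist[cand], cand)][seq_len(min(K, length(cand)))]
      out[i, v] <- mean(pool[take, v])
    }
  }
  if (short)
    warning("fewer than K candidate neighbours for some entries; used all available")
  out
}

#' Probabilistic-PCA imputation by expectation-maximisation
#'
#' Fits the probabilistic PCA model `x = mu + W z + eps`,
#' `z ~ N(0, I_q)`, `eps ~ N(0, sigma^2 I)`, to a matrix with missing
#' entries by exact EM: the E-step computes posterior moments of the latent
#' factors and the missing entries per row; the M-step jointly updates
#' `(mu, W)` via an augmented-factor regression and `sigma^2` in closed form,
#' so the observed-data log-likelihood is non-decreasing.  Missing entries
#' are filled with their posterior means; observed entries are untouched.
#'
#' @param X numeric matrix with `NA` for missing entries.
#' @param n_components latent dimension `q` (< ncol(X), default 2).
#' @param tol convergence tolerance on the relative change of the completed
#'   matrix.
#' @param max_iter maximum EM iterations.
#' @return An object of class `ppca_imputation`: list with `completed`,
#'   `mu`, `W`, `sigma2`, `loglik` (per-iteration observed-data
#'   log-likelihood trace), `converged`.
#' @export
ppca_impute <- function(X, n_components = 2L, tol = 1e-6, max_iter = 500L) {
  q <- as.integer(n_components)
  d <- ncol(X)
  n <- nrow(X)
  stopifnot(q >= 1L, q < d)
  if (any(colSums(!is.na(X)) == 0L))
    stop("variable(s) never observed: ",
         paste(which(colSums(!is.na(X)) == 0L), collapse = ", "))
  if (!anyNA(X)) {
    fit <- .ppca_em(X, q, tol, max_iter)
    fit$completed <- X
    return(fit)
  }
  .ppca_em(X, q, tol, max_iter)
}

# EM core; also used to fit on a training pool and fill new rows.
.ppca_em <- function(X, q, tol, max_iter) {
  d <- ncol(X)
  n <- nrow(X)
  mu <- colMeans(X, na.rm = TRUE)
  Xf <- X
  for (j in seq_len(d)) Xf[is.na(Xf[, j]), j] <- mu[j]
  sv <- svd(sweep(Xf, 2L, mu), nu = 0L, nv = q)
  ev <- sv$d^2 / max(n - 1L, 1L)
  sigma2 <- if (d > q) max(mean(ev[(q + 1L):min(d, length(ev))]), 1e-8)
            else 1e-8
  W <- sv$v %*% diag(sqrt(pmax(ev[seq_len(q)] - sigma2, 1e-8)), q, q)
  miss <- is.na(X)
  pat <- apply(miss, 1L, function(m) paste(as.integer(m), collapse = ""))
  loglik <- numeric(0)
  completed <- Xf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    est <- .ppca_estep(X, miss, mu, W, sigma2, pat)
    loglik <- c(loglik, est$loglik)
    Wt_new <- est$S_xz %*% solve(est$S_zz)
    sigma2_new <- max((sum(est$S_xx) - sum(Wt_new * est$S_xz)) / (n * d),
                      1e-12)
    W <- Wt_new[, seq_len(q), drop = FALSE]
    mu <- Wt_new[, q + 1L]
    sigma2 <- sigma2_new
    delta <- max(abs(est$completed - completed))
    scale <- max(abs(est$completed), 1)
    completed <- est$completed
    if (delta / scale < tol) {
      converged <- TRUE
      break
    }
  }
  completed[!miss] <- X[!miss]
  structure(list(completed = completed, mu = mu, W = W, sigma2 = sigma2,
                 loglik = loglik, converged = converged),
            class = "ppca_imputation")
}

# One E-step: posterior moments, sufficient statistics, observed loglik.
# Rows are grouped by missingness pattern to reuse the per-pattern algebra.
.ppca_estep <- function(X, miss, mu, W, sigma2, pat) {
  n <- nrow(X)
  d <- ncol(X)
  q <- ncol(W)
  S_zz <- matrix(0, q + 1L, q + 1L)
  S_xz <- matrix(0, d, q + 1L)
  S_xx <- numeric(d)
  completed <- X
  ll <- 0
  for (pp in unique(pat)) {
    rows <- which(pat == pp)
    m <- miss[rows[1L], ]
    o <- !m
    W_o <- W[o, , drop = FALSE]
    M <- crossprod(W_o) + sigma2 * diag(q)
    Minv <- solve(M)
    Sz <- sigma2 * Minv
    Xo <- X[rows, o, drop = FALSE]
    dev <- sweep(Xo, 2L, mu[o])
    Zbar <- dev %*% W_o %*% Minv                       # rows x q
    if (any(m)) {
      W_m <- W[m, , drop = FALSE]
      Xm <- sweep(Zbar %*% t(W_m), 2L, mu[m], "+")
      completed[rows, m] <- Xm
      Cxz_m <- W_m %*% Sz                              # |m| x q
      var_m <- rowSums((W_m %*% Sz) * W_m) + sigma2    # diag of posterior var
    }
    nr <- length(rows)
    Ezz <- crossprod(Zbar) + nr * Sz
    zsum <- colSums(Zbar)
    S_zz <- S_zz + rbind(cbind(Ezz, zsum), c(zsum, nr))
    Exz <- matrix(0, d, q)
    Exz[o, ] <- crossprod(Xo, Zbar)
    xsum <- numeric(d)
    xsum[o] <- colSums(Xo)
    if (any(m)) {
      Exz[m, ] <- crossprod(Xm, Zbar) + nr * Cxz_m
      xsum[m] <- colSums(rbind(Xm))
      S_xx[m] <- S_xx[m] + colSums(rbind(Xm^2)) + nr * var_m
    }
    S_xx[o] <- S_xx[o] + colSums(Xo^2)
    S_xz <- S_xz + cbind(Exz, xsum)
    # observed-data log-likelihood for this pattern
    if (any(o)) {
      C_oo <- tcrossprod(W_o) + sigma2 * diag(sum(o))
      ch <- chol(C_oo)
      logdet <- 2 * sum(log(diag(ch)))
      qf <- rowSums((dev %*% chol2inv(ch)) * dev)
      ll <- ll - 0.5 * (nr * (sum(o) * log(2 * pi) + logdet) + sum(qf))
    }
  }
  list(S_zz = S_zz, S_xz = S_xz, S_xx = S_xx, completed = completed,
       loglik = ll)
}

# Fill new rows using an already-fitted PPCA model (posterior means).
.ppca_fill <- function(fit, X) {
  miss <- is.na(X)
  if (!any(miss)) return(X)
  q <- ncol(fit$W)
  out <- X
  for (i in which(rowSums(miss) > 0L)) {
    o <- !miss[i, ]
    W_o <- fit$W[o, , drop = FALSE]
    Minv <- solve(crossprod(W_o) + fit$sigma2 * diag(q))
    zbar <- Minv %*% crossprod(W_o, X[i, o] - fit$mu[o])
    out[i, !o] <- fit$mu[!o] + fit$W[!o, , drop = FALSE] %*% zbar
  }
  out
}

#' Flatten an imputed window into a feature vector
#'
#' Row-major (week-major) concatenation of the weekly score vectors: entry
#' `4 * (t - 1) + c` is week `t`, channel `c`.
#'
#' @param window_scores width x 4 matrix of (imputed) scores.
#' @return Numeric vector of length `4 * width`.
#' @export
flatten_features <- function(window_scores) {
  as.vector(t(window_scores))
}
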