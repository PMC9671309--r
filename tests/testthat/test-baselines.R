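test_that("naive window means use valid scores with a full-stream fallback", {
  win <- cbind(c(1, -1, 3, rep(-1, 7)), rep(5, 10), rep(50, 10), rep(2, 10))
  expect_equal(naive_features(win)[1], 2)
  full <- cbind(rep(4, 10), rep(5, 10), rep(50, 10), rep(2, 10))
  expect_equal(naive_features(full), c(4, 5, 50, 2))
  # in-window all missing: fall back to the stream mean
  win2 <- win; win2[, 1] <- -1
  stream <- rbind(win2, cbind(rep(7, 5), rep(5, 5), rep(50, 5), rep(2, 5)))
  expect_equal(naive_features(win2, stream)[1], 7)
  allmiss <- win2
  expect_error(naive_features(allmiss, allmiss, participant_id = "px"),
               "px")
})

test_that("KNN imputation copies exact duplicates and respects observed entries", {
  X <- rbind(c(1, 2, 3, 4), c(1, 2, NA, 4), c(9, 9, 9, 9))
  out <- knn_impute(X, K = 1)
  expect_equal(out[2, 3], 3)          # unique nearest neighbour is row 1
  expect_equal(out[!is.na(X)], X[!is.na(X)])
  # duplicated row with a hole is filled with the duplicate's value exactly
  Y <- rbind(c(5, 5, 5, 5), c(5, 5, 5, NA), c(0, 0, 0, 0))
  expect_equal(knn_impute(Y, K = 1)[2, 4], 5)
  # no missing entries: untouched
  Z <- matrix(1:16, 4)
  expect_identical(knn_impute(Z), Z)
})

test_that("KNN recovers a linear inter-channel relation from neighbours", {
  set.seed(41)
  x1 <- runif(200, 1, 10)
  X <- cbind(x1, 2 * x1, runif(200, 0, 0.1), runif(200, 0, 0.1))
  holes <- sample(200, 40)
  Xm <- X
  Xm[holes, 2] <- NA
  out <- knn_impute(Xm, K = 5)
  rel_err <- abs(out[holes, 2] - X[holes, 2]) / X[holes, 2]
  expect_lt(max(rel_err), 0.10)
})

test_that("a fully missing week falls back to pool column means", {
  X <- rbind(c(1, 2, 3, 4), c(3, 4, 5, 6), c(NA, NA, NA, NA))
  out <- knn_impute(X, K = 1)
  expect_equal(out[3, ], c(2, 3, 4, 5))
})

test_that("PPCA-EM completes a rank-1 matrix and never decreases the likelihood", {
  set.seed(42)
  u <- runif(60, 1, 2)
  v <- c(1, 2, 3, 4)
  X <- outer(u, v)
  holes <- sample(length(X), round(0.05 * length(X)))
  Xm <- X
  Xm[holes] <- NA
  fit <- ppca_impute(Xm, n_components = 1, tol = 1e-10, max_iter = 2000)
  rel <- abs(fit$completed[holes] - X[holes]) / abs(X[holes])
  expect_lt(max(rel), 1e-3)
  expect_true(all(diff(fit$loglik) > -1e-6))
  expect_equal(fit$completed[-holes], X[-holes])
  # complete input is returned unchanged
  fit2 <- ppca_impute(X, n_components = 2)
  expect_identical(fit2$completed, X)
})

test_that("PPCA stays stable on pure noise", {
  set.seed(43)
  X <- matrix(rnorm(400), ncol = 4)
  X[sample(400, 60)] <- NA
  fit <- ppca_impute(X, n_components = 2, tol = 1e-7, max_iter = 500)
  expect_true(fit$converged)
  rng <- range(X, na.rm = TRUE)
  s <- stats::sd(X, na.rm = TRUE)
  filled <- fit$completed[is.na(X)]
  expect_true(all(filled > rng[1] - 3 * s & filled < rng[2] + 3 * s))
  expect_true(all(diff(fit$loglik) > -1e-6))
})

test_that("flattening is week-major and deterministic", {
  w <- matrix(0, 10, 4)
  expect_equal(flatten_features(w), rep(0, 40))
  w2 <- matrix(seq_len(40), 10, 4, byrow = TRUE)
  fl <- flatten_features(w2)
  for (t in 1:10) for (c in 1:4) expect_equal(fl[4 * (t - 1) + c], w2[t, c])
  expect_identical(flatten_features(w2), flatten_features(w2))
})

test_that("on a complete cohort the imputation baselines reduce to flattening", {
  coh <- separable_cohort(n_per_group = 4, W = 12)
  wi <- moodsig:::.window_index(coh, window_spec())
  X <- wi$weekly$X
  expect_false(anyNA(X))
  expect_identical(knn_impute(X), X)
  expect_identical(ppca_impute(X, 2)$completed, X)
})

test_that("baselines share the MRLSM fold assignment in paired runs", {
  coh <- separable_cohort(n_per_group = 4, W = 12)
  fit <- mrlsm(coh, rf = rf_control(ntree = 60), boot_B = 50, seed = 5)
  fn <- mrlsm(coh, method = "naive", folds = fit$folds,
              rf = rf_control(ntree = 60), boot_B = 50, seed = 5)
  expect_identical(fit$folds, fn$folds)
})
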