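test_that("segment signature matches the tensor-exponential closed form", {
  # 1-D: level k is a^k / k!
  s <- segment_signature(2, p = 3)
  expect_equal(unlist(s$levels), c(1, 2, 2, 4 / 3))
  # 2-D diagonal increment: all level-2 entries are 1/2
  s2 <- segment_signature(c(1, 1), p = 2)
  expect_equal(s2$levels[[3]], rep(0.5, 4))
  expect_equal(tensor_coefficient(s2, c(1, 2)), 0.5)
  # zero increment gives the identity tensor
  s0 <- segment_signature(c(0, 0, 0), p = 3)
  expect_equal(s0$levels, tensor_identity(3, 3)$levels)
  expect_error(segment_signature(numeric(0), 2), "non-empty")
  expect_error(segment_signature(1, 0), "'p'")
})

test_that("tensor_mul is the Chen product: neutral element, worked case, associativity", {
  set.seed(1)
  B <- path_signature(random_path(2, 3), 2)
  I <- tensor_identity(2, 2)
  expect_equal(tensor_mul(I, B)$levels, B$levels)
  expect_equal(tensor_mul(B, I)$levels, B$levels)
  # hand-multiplied (1 + e1 + e1e1/2)(1 + e2 + e2e2/2)
  P <- tensor_mul(segment_signature(c(1, 0), 2), segment_signature(c(0, 1), 2))
  expect_equal(P$levels[[3]], c(0.5, 1, 0, 0.5))
  # associativity on random tensors
  for (i in 1:5) {
    A <- path_signature(random_path(3, 2), 3)
    B <- path_signature(random_path(3, 2), 3)
    C <- path_signature(random_path(3, 2), 3)
    lhs <- tensor_mul(tensor_mul(A, B), C)
    rhs <- tensor_mul(A, tensor_mul(B, C))
    expect_equal(lhs$levels, rhs$levels, tolerance = 1e-12)
  }
  expect_error(tensor_mul(tensor_identity(2, 2), tensor_identity(3, 2)),
               "share")
})

test_that("path signature: 1-D collapse, worked 2-D values, subdivision invariance", {
  # a 1-D path depends only on its total increment
  s_two <- path_signature(cbind(c(0, 1, 3)), 3)
  s_one <- path_signature(cbind(c(0, 3)), 3)
  expect_equal(s_two$levels, s_one$levels, tolerance = 1e-12)
  # L-shaped path: S^1 = 1, S^2 = 1, S^11 = .5, S^12 = 1, S^21 = 0, S^22 = .5
  L <- rbind(c(0, 0), c(1, 0), c(1, 1))
  S <- path_signature(L, 2)
  expect_equal(S$levels[[2]], c(1, 1))
  expect_equal(S$levels[[3]], c(0.5, 1, 0, 0.5), tolerance = 1e-12)
  # level 1 is always the total increment
  set.seed(2)
  p1 <- random_path(3, 4)
  expect_equal(path_signature(p1, 2)$levels[[2]],
               unname(p1[nrow(p1), ] - p1[1, ]))
  # inserting a midpoint changes nothing (reparameterisation invariance)
  mid <- (p1[2, ] + p1[3, ]) / 2
  p1b <- rbind(p1[1:2, ], mid, p1[3:nrow(p1), ])
  expect_equal(path_signature(p1b, 3)$levels, path_signature(p1, 3)$levels,
               tolerance = 1e-10)
  # truncating a deeper computation equals computing shallow
  expect_equal(truncate_tensor(path_signature(p1, 3), 2)$levels,
               path_signature(p1, 2)$levels, tolerance = 1e-12)
  expect_error(path_signature(rbind(c(0, 0)), 2), "at least 2")
})

test_that("tensor log and exp invert each other and kill non-primitive levels", {
  lg <- tensor_log(segment_signature(c(0.3, -0.7), 3))
  expect_equal(lg$levels[[2]], c(0.3, -0.7))
  expect_equal(lg$levels[[3]], numeric(4), tolerance = 1e-12)
  expect_equal(lg$levels[[4]], numeric(8), tolerance = 1e-12)
  expect_equal(tensor_log(tensor_identity(2, 2))$levels[[2]], c(0, 0))
  set.seed(3)
  S <- path_signature(random_path(3, 3), 3)
  back <- tensor_exp(tensor_log(S))
  expect_lt(max(abs(unlist(back$levels) - unlist(S$levels))), 1e-12)
  bad <- tensor_identity(2, 2); bad$levels[[1]] <- 2
  expect_error(tensor_log(bad), "level-0")
})

test_that("brute-force iterated integrals agree with closed forms and Chen values", {
  L <- rbind(c(0, 0), c(1, 0), c(1, 1))
  expect_equal(brute_force_coefficient(L, 1, 500), 1)
  expect_lt(abs(brute_force_coefficient(L, c(2, 1), 10000)), 1e-3)
  expect_equal(brute_force_coefficient(cbind(c(0, 3)), c(1, 1), 5000),
               9 / 2, tolerance = 1e-3)
})

test_that("level-2 shuffle relation S^i S^j = S^ij + S^ji holds", {
  set.seed(4)
  for (r in 1:10) {
    S <- path_signature(random_path(3, 4), 2)
    for (i in 1:3) for (j in 1:3) {
      lhs <- tensor_coefficient(S, i) * tensor_coefficient(S, j)
      rhs <- tensor_coefficient(S, c(i, j)) + tensor_coefficient(S, c(j, i))
      expect_lt(abs(lhs - rhs), 1e-10)
    }
  }
})
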