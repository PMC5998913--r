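klein <- median_example("klein")
cyc3 <- median_example("cycle3")

test_that("invariants reproduce the worked examples", {
  k <- klein$perms
  expect_equal(beta_invariant(k[[1]], k[[2]], k[[3]]), 3L)
  expect_equal(alpha_invariant(k[[1]], k[[2]], k[[3]]), 1L)
  expect_equal(delta_invariant(k[[1]], k[[2]], k[[3]]), 0L)
  p <- cyc3$perms
  expect_equal(beta_invariant(p[[1]], p[[2]], p[[3]]), 3L)
  expect_equal(alpha_invariant(p[[1]], p[[2]], p[[3]]), 1L)
  expect_equal(delta_invariant(p[[1]], p[[2]], p[[3]]), 1L)
  id <- perm_identity(5)
  expect_equal(beta_invariant(id, id, id), 0L)
  expect_equal(alpha_invariant(id, id, id), 5L)
  expect_equal(delta_invariant(id, id, id), 0L)
  expect_error(beta_invariant(id, id, perm_identity(4)), "mismatch")
})

test_that("beta matches half the pairwise rank-distance sum", {
  set.seed(41)
  for (it in 1:10) {
    n <- sample(3:25, 1)
    ps <- lapply(1:3, function(k) random_permutation(n))
    ms <- lapply(ps, perm_to_matrix)
    direct <- (numeric_rank_oracle(ms[[1]] - ms[[2]]) +
               numeric_rank_oracle(ms[[2]] - ms[[3]]) +
               numeric_rank_oracle(ms[[3]] - ms[[1]])) / 2
    expect_equal(beta_invariant(ps[[1]], ps[[2]], ps[[3]]), direct)
  }
})

test_that("alpha equals the triple-agreement nullspace dimension", {
  set.seed(42)
  for (n in c(5, 12, 30, 50)) {
    ps <- lapply(1:3, function(k) random_permutation(n))
    ms <- lapply(ps, perm_to_matrix)
    stacked <- rbind(ms[[1]] - ms[[2]], ms[[2]] - ms[[3]])
    expect_equal(alpha_invariant(ps[[1]], ps[[2]], ps[[3]]),
                 n - numeric_rank_oracle(stacked))
  }
})

test_that("invariants are symmetric in arguments and under relabeling", {
  set.seed(43)
  ps <- lapply(1:3, function(k) random_permutation(10))
  b <- beta_invariant(ps[[1]], ps[[2]], ps[[3]])
  a <- alpha_invariant(ps[[1]], ps[[2]], ps[[3]])
  for (ord in list(c(1, 3, 2), c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(beta_invariant(ps[[ord[1]]], ps[[ord[2]]], ps[[ord[3]]]), b)
    expect_equal(alpha_invariant(ps[[ord[1]]], ps[[ord[2]]], ps[[ord[3]]]), a)
  }
  # common row/column relabeling: X -> P X Q^T
  P <- random_permutation(10); Q <- random_permutation(10)
  rel <- lapply(ps, function(x) {
    matrix_to_perm(perm_to_matrix(P) %*% perm_to_matrix(x) %*% t(perm_to_matrix(Q)))
  })
  expect_equal(beta_invariant(rel[[1]], rel[[2]], rel[[3]]), b)
  expect_equal(alpha_invariant(rel[[1]], rel[[2]], rel[[3]]), a)
})

test_that("beta is integral and delta non-negative for permutations", {
  set.seed(44)
  for (it in 1:30) {
    n <- sample(3:30, 1)
    inv <- median_invariants(random_permutation(n), random_permutation(n),
                             random_permutation(n))
    expect_true(inv$beta == round(inv$beta))
    expect_gte(inv$delta, 0L)
  }
})

test_that("subspace dimensions sum to n with dim V5 = 2 delta", {
  k <- klein$perms
  expect_equal(subspace_dims(k[[1]], k[[2]], k[[3]]), c(1L, 1L, 1L, 1L, 0L))
  id <- perm_identity(6)
  expect_equal(subspace_dims(id, id, id), c(6L, 0L, 0L, 0L, 0L))
  # n=3 triple: pairwise quotients are 3-cycles, so V2 = V3 = V4 = 0 and
  # V5 = 2 delta = 2 (confirmed by the nullspace oracle below)
  p <- cyc3$perms
  dims <- subspace_dims(p[[1]], p[[2]], p[[3]])
  expect_equal(dims, c(1L, 0L, 0L, 0L, 2L))
  ms <- lapply(p, perm_to_matrix)
  expect_equal(dims[2], 3L - numeric_rank_oracle(ms[[1]] - ms[[2]]) - dims[1])
  set.seed(45)
  for (it in 1:10) {
    n <- sample(4:30, 1)
    ps <- lapply(1:3, function(k) random_permutation(n))
    dims <- subspace_dims(ps[[1]], ps[[2]], ps[[3]])
    inv <- median_invariants(ps[[1]], ps[[2]], ps[[3]])
    expect_equal(sum(dims), n)
    expect_equal(dims[5], 2L * inv$delta)
    expect_equal(dims[1], inv$alpha)
  }
})

test_that("scores of the printed candidates match", {
  k <- klein
  A <- k$matrices[[1]]; B <- k$matrices[[2]]; C <- k$matrices[[3]]
  expect_equal(median_score(A, A, B, C)$score, 4L)
  expect_equal(median_score(diag(4), A, B, C)$score, 6L)
  half <- median_score(k$median, A, B, C)
  expect_equal(half$score, 3L)
  expect_equal(half$gap, 0)
  expect_error(median_score(diag(3), A, B, C), "mismatch")
})

test_that("the best input is within 4/3 of the lower bound", {
  set.seed(46)
  for (it in 1:20) {
    n <- sample(3:25, 1)
    ps <- lapply(1:3, function(k) random_permutation(n))
    ms <- lapply(ps, perm_to_matrix)
    b <- beta_invariant(ps[[1]], ps[[2]], ps[[3]])
    best <- min(vapply(ms, function(X) {
      median_score(X, ms[[1]], ms[[2]], ms[[3]])$score
    }, integer(1)))
    expect_lte(best, 4 / 3 * b)
    expect_gte(best, b)
  }
})
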