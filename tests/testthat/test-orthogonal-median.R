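klein <- median_example("klein")

test_that("betweenness detection is exact for permutations and geodesics", {
  A <- klein$matrices[[1]]; B <- klein$matrices[[2]]; C <- klein$matrices[[3]]
  expect_true(is_between(A, A, C))
  expect_false(is_between(A, B, C))      # all pairwise distances are 2
  set.seed(71)
  n <- 10
  Ao <- random_orthogonal(n); Co <- random_orthogonal(n)
  s <- svd(Co - Ao)
  P <- s$u[, 1:4] %*% t(s$u[, 1:4])
  Bo <- Ao + P %*% (Co - Ao)             # constructed geodesic point
  expect_true(is_between(Ao, Bo, Co))
})

test_that("intersection bases are non-trivial off the geodesic", {
  set.seed(72)
  n <- 8
  A <- random_orthogonal(n); B <- random_orthogonal(n)
  basis <- intersection_basis(A, B, A)   # A = C != B: intersection is im(A-B)
  expect_equal(ncol(basis), rank_distance_matrix(A, B, 1e-6))
  k <- klein$matrices
  expect_gte(ncol(intersection_basis(k[[1]], k[[2]], k[[3]])), 1L)
  # Grassmann dimension identity on random orthogonal triples
  for (it in 1:5) {
    A <- random_orthogonal(n); B <- random_orthogonal(n); C <- random_orthogonal(n)
    d1 <- numeric_rank_oracle(A - B); d2 <- numeric_rank_oracle(C - B)
    dsum <- numeric_rank_oracle(cbind(A - B, C - B))
    expect_equal(ncol(intersection_basis(A, B, C)), d1 + d2 - dsum)
  }
})

test_that("rank-one steps stay orthogonal at rank distance one", {
  expect_equal(rank_one_step(diag(3), c(1, 0, 0)),
               diag(c(-1, 1, 1)))
  set.seed(73)
  for (it in 1:6) {
    n <- sample(3:15, 1)
    B <- random_orthogonal(n)
    u <- rnorm(n)
    B2 <- rank_one_step(B, u)
    expect_lt(max(abs(crossprod(B2) - diag(n))), 1e-9)
    expect_equal(numeric_rank_oracle(B2 - B), 1L)
  }
  expect_error(rank_one_step(diag(2), c(0, 0)), "non-zero")
})

test_that("the transposition fast path moves both distances down by one", {
  a <- unclass(klein$perms[[1]])
  expect_null(permutation_step(a, a, unclass(klein$perms[[3]])))
  # the Klein triple has no shared pair: its unique median is fractional, so
  # no transposition walk can reach it and the generic rank-1 step takes over
  expect_null(permutation_step(a, unclass(klein$perms[[2]]),
                               unclass(klein$perms[[3]])))
  set.seed(74)
  for (it in 1:12) {
    n <- sample(4:30, 1)
    a <- sample.int(n); b <- sample.int(n); cc <- sample.int(n)
    pair <- permutation_step(a, b, cc)
    if (is.null(pair)) next
    b2 <- rankmedian:::apply_transposition(b, pair)
    expect_equal(rank_distance_perm(a, b2), rank_distance_perm(a, b) - 1L)
    expect_equal(rank_distance_perm(cc, b2), rank_distance_perm(cc, b) - 1L)
  }
})

test_that("the walk reproduces the closed-form medians", {
  k <- klein$matrices
  res <- orthogonal_median(k[[1]], k[[2]], k[[3]])
  expect_equal(res$matrix, klein$median, tolerance = 1e-9)
  expect_equal(res$score, 3L)
  p <- median_example("cycle3")
  res <- orthogonal_median(p$matrices[[1]], p$matrices[[2]], p$matrices[[3]])
  expect_equal(res$score, 3L)
  expect_equal(res$gap, 0)
  # a between B is returned unchanged with zero iterations
  res <- orthogonal_median(k[[1]], k[[1]], k[[3]])
  expect_equal(res$matrix, k[[1]])
  expect_equal(res$iterations, 0L)
  expect_error(orthogonal_median(diag(2) * 2, diag(2), diag(2)), "orthogonal")
})

test_that("the walk attains the lower bound on random permutation triples", {
  set.seed(75)
  for (n in c(8, 20, 60, 150)) {
    ps <- lapply(1:3, function(j) sample.int(n))
    res <- orthogonal_median(ps[[1]], ps[[2]], ps[[3]])
    expect_equal(res$gap, 0)
    d <- c(rank_distance_perm(ps[[1]], ps[[2]]),
           rank_distance_perm(ps[[2]], ps[[3]]),
           rank_distance_perm(ps[[1]], ps[[3]]))
    expect_equal(res$iterations, (d[1] + d[2] - d[3]) / 2)
    expect_lt(max(abs(crossprod(res$matrix) - diag(n))), 1e-6)
  }
})

test_that("the walk attains the lower bound on random orthogonal triples", {
  set.seed(76)
  for (n in c(10, 25, 50)) {
    ms <- lapply(1:3, function(j) random_orthogonal(n))
    res <- orthogonal_median(ms[[1]], ms[[2]], ms[[3]])
    expect_equal(res$gap, 0)
    expect_lt(max(abs(crossprod(res$matrix) - diag(n))), 1e-5)
    d <- c(rank_distance_matrix(ms[[1]], ms[[2]], 1e-6),
           rank_distance_matrix(ms[[2]], ms[[3]], 1e-6),
           rank_distance_matrix(ms[[1]], ms[[3]], 1e-6))
    expect_equal(res$iterations, (d[1] + d[2] - d[3]) / 2)
  }
})

test_that("generic and fast-path walks agree in score for permutation inputs", {
  set.seed(77)
  for (it in 1:4) {
    n <- 10
    ps <- lapply(1:3, function(j) sample.int(n))
    fast <- orthogonal_median(ps[[1]], ps[[2]], ps[[3]])
    # tiny rotation makes the inputs non-binary, forcing the generic path
    theta <- 1e-4
    Rz <- diag(n); Rz[1:2, 1:2] <- matrix(c(cos(theta), sin(theta),
                                            -sin(theta), cos(theta)), 2)
    ms <- lapply(ps, function(p) perm_to_matrix(p) %*% Rz)
    generic <- orthogonal_median(ms[[1]], ms[[2]], ms[[3]], tol = 1e-6)
    expect_equal(fast$gap, 0)
    expect_equal(generic$gap, 0)
    expect_equal(generic$beta, fast$beta)
  }
})
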