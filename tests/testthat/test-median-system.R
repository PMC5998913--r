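klein <- median_example("klein")
cyc3 <- median_example("cycle3")

test_that("the reduced system has 2(n - alpha) equations in 2 beta unknowns", {
  k <- klein$perms
  sys <- build_difference_system(k[[1]], k[[2]], k[[3]])
  expect_equal(dim(sys$L), c(6L, 6L))          # Klein: square, nonsingular
  expect_equal(Matrix::rankMatrix(as.matrix(sys$L))[1], 6)
  expect_true(all(as.matrix(sys$L) %in% c(-1, 0, 1)))
  p <- cyc3$perms
  sys <- build_difference_system(p[[1]], p[[2]], p[[3]])
  expect_equal(dim(sys$L), c(4L, 6L))          # under-constrained when delta > 0
  id <- perm_identity(4)
  sys <- build_difference_system(id, id, id)
  expect_equal(dim(sys$L), c(0L, 0L))   # identical triple: nothing to solve
  set.seed(61)
  for (it in 1:6) {
    n <- sample(4:20, 1)
    ps <- lapply(1:3, function(j) random_permutation(n))
    inv <- median_invariants(ps[[1]], ps[[2]], ps[[3]])
    sys <- build_difference_system(ps[[1]], ps[[2]], ps[[3]])
    expect_equal(dim(sys$L), c(2L * (n - inv$alpha), 2L * inv$beta))
  }
})

test_that("the first-row solution of the Klein system matches the printed one", {
  k <- klein$perms
  tr <- lapply(k, unclass)
  sys <- build_difference_system(k[[1]], k[[2]], k[[3]])
  R <- rankmedian:::system_rhs(sys, tr)
  X <- as.matrix(Matrix::solve(sys$L, R))
  # variables ordered s'1, s'2, t'1, t'2, u'1, u'2
  expect_equal(unname(X[, 1]), c(-0.5, -0.5, -0.5, -0.5, -0.5, 0.5))
})

test_that("the deficiency-zero solver finds the unique median", {
  k <- klein$perms
  res <- solve_special_case(k[[1]], k[[2]], k[[3]])
  expect_equal(res$matrix, klein$median, tolerance = 1e-12)
  expect_equal(res$score, 3L)
  expect_equal(res$gap, 0)
  expect_equal(res$classification, "fractional")
  id <- perm_identity(5)
  expect_equal(solve_special_case(id, id, id)$matrix, diag(5))
  p <- cyc3$perms
  expect_error(solve_special_case(p[[1]], p[[2]], p[[3]]), "delta")
})

test_that("exact rational mode agrees with the float path bit for bit on halves", {
  k <- klein$perms
  res_f <- solve_special_case(k[[1]], k[[2]], k[[3]])
  res_q <- solve_special_case(k[[1]], k[[2]], k[[3]], exact = TRUE)
  expect_identical(res_q$matrix, klein$median)
  expect_equal(res_f$matrix, res_q$matrix, tolerance = 1e-12)
  set.seed(62)
  for (it in 1:3) {
    ps <- random_delta0_involutions(8, 0.15)
    res_f <- solve_special_case(ps[[1]], ps[[2]], ps[[3]])
    res_q <- solve_special_case(ps[[1]], ps[[2]], ps[[3]], exact = TRUE)
    expect_equal(res_f$matrix, res_q$matrix, tolerance = 1e-9)
    # entries are small-denominator rationals
    ent <- unique(as.vector(res_q$matrix))
    den <- vapply(ent, function(e) {
      which(abs(e * (1:24) - round(e * (1:24))) < 1e-9)[1]
    }, numeric(1))
    expect_true(all(!is.na(den)))
  }
})

test_that("the special-case median scores beta and equals the candidate", {
  set.seed(63)
  sizes <- c(10, 25, 100)
  for (genes in sizes) {
    ps <- random_delta0_involutions(genes, 0.1)
    res <- solve_special_case(ps[[1]], ps[[2]], ps[[3]])
    expect_equal(res$score, res$beta)
    MA <- candidate_median(ps[[1]], ps[[2]], ps[[3]], "A")
    expect_lt(max(abs(res$matrix - MA)), 1e-9)
  }
  # and for non-involution permutations
  for (it in 1:3) {
    ps <- random_delta0_perms(6)
    res <- solve_special_case(ps[[1]], ps[[2]], ps[[3]])
    expect_equal(res$score, res$beta)
    expect_lt(max(abs(res$matrix -
                      candidate_median(ps[[1]], ps[[2]], ps[[3]], "A"))), 1e-9)
  }
})

test_that("the three median expressions agree on solved systems", {
  set.seed(64)
  for (it in 1:4) {
    ps <- random_delta0_involutions(12, 0.1)
    tr <- lapply(ps, unclass)
    sys <- build_difference_system(ps[[1]], ps[[2]], ps[[3]])
    R <- rankmedian:::system_rhs(sys, tr)
    X <- as.matrix(Matrix::solve(sys$L, R))
    MS <- reconstruct_median(sys, X, ps[[1]], ps[[2]], ps[[3]], family = "S")
    MT <- reconstruct_median(sys, X, ps[[1]], ps[[2]], ps[[3]], family = "T")
    MU <- reconstruct_median(sys, X, ps[[1]], ps[[2]], ps[[3]], family = "U")
    expect_lt(max(abs(MS - MT)), 1e-9)
    expect_lt(max(abs(MS - MU)), 1e-9)
  }
  # the zero solution reconstructs the base matrix of each expression
  id <- perm_identity(4); swap <- as_perm("(1 2)", n = 4)
  sys <- build_difference_system(swap, id, id)
  X0 <- matrix(0, ncol(sys$L), 4)
  expect_equal(reconstruct_median(sys, X0, swap, id, id), perm_to_matrix(swap))
})

test_that("common adjacencies are inherited by the deficiency-zero median", {
  set.seed(65)
  for (it in 1:5) {
    ps <- random_delta0_involutions(12, 0.1)
    gs <- lapply(ps, involution_to_genome)
    common <- intersect(intersect(
      apply(gs[[1]]$adjacencies, 1, paste, collapse = ","),
      apply(gs[[2]]$adjacencies, 1, paste, collapse = ",")),
      apply(gs[[3]]$adjacencies, 1, paste, collapse = ","))
    if (length(common) == 0L) next
    M <- solve_special_case(ps[[1]], ps[[2]], ps[[3]])$matrix
    for (key in common) {
      ij <- as.integer(strsplit(key, ",")[[1]])
      ei <- rep(0, nrow(M)); ei[ij[1]] <- 1
      ej <- rep(0, nrow(M)); ej[ij[2]] <- 1
      expect_lt(max(abs(M %*% ei - ej)), 1e-9)
    }
  }
})

test_that("the L1 program solves the printed row and CS behaves as documented", {
  p <- cyc3$perms
  sys <- build_difference_system(p[[1]], p[[2]], p[[3]])
  R <- rankmedian:::system_rhs(sys, lapply(p, unclass))
  # row j = 1: printed right-hand sides (0, 1, -1, 0) after elimination
  expect_equal(unname(R[, 1]), c(0, 1, -1, 0))
  x <- l1_min_solve(sys$L, R[, 1])
  expect_equal(sum(abs(x)), 2)           # the printed optimum has L1 norm 2
  expect_lt(max(abs(as.matrix(sys$L) %*% x - R[, 1])), 1e-9)
  # the printed CS output [0 0 e] scores 6, above the bound beta = 3
  sc <- median_score(cyc3$cs_printed, cyc3$matrices[[1]], cyc3$matrices[[2]],
                     cyc3$matrices[[3]])
  expect_equal(sc$score, 6L)
  res <- compressed_sensing_median(p[[1]], p[[2]], p[[3]])
  expect_gte(res$score, res$beta)
  # delta = 0 inputs dispatch to the exact branch
  k <- klein$perms
  res <- compressed_sensing_median(k[[1]], k[[2]], k[[3]])
  expect_equal(res$method, "exact-special")
  expect_equal(res$matrix, klein$median, tolerance = 1e-12)
})

test_that("compressed sensing never scores below beta on random triples", {
  set.seed(66)
  for (it in 1:6) {
    n <- sample(4:10, 1)
    ps <- lapply(1:3, function(j) random_permutation(n))
    res <- compressed_sensing_median(ps[[1]], ps[[2]], ps[[3]])
    expect_gte(res$score, res$beta)
    expect_equal(res$gap, res$score - res$beta)
  }
})

test_that("rank_median dispatches by method and deficiency", {
  k <- klein$perms
  expect_equal(rank_median(k[[1]], k[[2]], k[[3]], "auto")$method, "exact-special")
  p <- cyc3$perms
  auto <- rank_median(p[[1]], p[[2]], p[[3]], "auto")
  expect_equal(auto$gap, 0)              # the orthogonal walk rescues CS here
  expect_equal(rank_median(p[[1]], p[[2]], p[[3]], "cs")$method,
               "compressed-sensing")
  expect_equal(rank_median(p[[1]], p[[2]], p[[3]], "orthogonal")$score, 3L)
  expect_error(rank_median(p[[1]], p[[2]], p[[3]], "exact-special"), "delta")
})
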