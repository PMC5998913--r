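#' Betweenness under the rank distance
#'
#' \code{TRUE} iff \code{d(A,B) + d(B,C) == d(A,C)}, i.e. \code{B} lies on a
#' geodesic between \code{A} and \code{C}. Combinatorial cycle counting is
#' used when all three are permutation matrices; numerical ranks at
#' \code{tol} otherwise.
#'
#' @param A,B,C square matrices of the same size.
#' @param tol rank tolerance.
#' @export
is_between <- function(A, B, C, tol = 1e-6) {
  perms <- lapply(list(A, B, C), try_as_perm)
  if (!any(vapply(perms, is.null, logical(1)))) {
    return(rank_distance_perm(perms[[1]], perms[[2]]) +
           rank_distance_perm(perms[[2]], perms[[3]]) ==
           rank_distance_perm(perms[[1]], perms[[3]]))
  }
  numeric_rank(A - B, tol) + numeric_rank(B - C, tol) == numeric_rank(A - C, tol)
}

# orthonormal basis of the nullspace of X (columns), at relative tolerance
nullspace_basis <- function(X, tol = 1e-6) {
  n <- ncol(X)
  s <- svd(X, nu = 0, nv = n)
  d <- c(s$d, rep(0, n - length(s$d)))
  keep <- d <= tol * max(d, 1)
  s$v[, keep, drop = FALSE]
}

orth_basis <- function(X, tol = 1e-6) {
  if (ncol(X) == 0L) return(X)
  s <- svd(X)
  r <- sum(s$d > tol * max(s$d, 1))
  s$u[, seq_len(r), drop = FALSE]
}

#' Basis of the image intersection im(A-B) intersect im(C-B)
#'
#' Primary formula: the nullspace of the stacked nullspace transposes,
#' \code{Null([Null((A-B)')'; Null((C-B)')'])}. When \code{B} is not between
#' \code{A} and \code{C} this intersection is provably non-trivial, but the
#' primary formula can be numerically unstable and return dimension 0; in
#' that case the fallback \code{Orth((A-B) * Null([A-B C-B])[1:n, ])} is
#' used. If both fail an error with diagnostics is raised.
#'
#' @inheritParams is_between
#' @return matrix whose columns form a basis (possibly 0 columns when
#'   \code{B} is between \code{A} and \code{C}).
#' @export
intersection_basis <- function(A, B, C, tol = 1e-6) {
  n1 <- nullspace_basis(t(A - B), tol)   # ker((A-B)^T) = im(A-B)^perp
  n2 <- nullspace_basis(t(C - B), tol)
  stacked <- rbind(t(n1), t(n2))
  meet <- if (nrow(stacked) == 0L) diag(nrow(A)) else nullspace_basis(stacked, tol)
  if (ncol(meet) > 0L) return(meet)
  # fallback: x in ker([A-B  C-B]) gives (A-B) x1 = -(C-B) x2
  K <- nullspace_basis(cbind(A - B, C - B), tol)
  if (ncol(K) > 0L) {
    cand <- orth_basis((A - B) %*% K[seq_len(nrow(A)), , drop = FALSE], tol)
    if (ncol(cand) > 0L) return(cand)
  }
  if (is_between(A, B, C, tol)) return(matrix(0, nrow(A), 0L))
  stop("numerical failure: both intersection-subspace formulas returned ",
       "dimension 0 while B is not between A and C (n = ", nrow(A), ")")
}

#' One orthogonal rank-1 step
#'
#' Returns \code{B + H} with \code{H = -2 u u' B / (u'u)}: a reflection that
#' keeps the matrix orthogonal and is at rank distance exactly 1 from
#' \code{B}.
#'
#' @param B orthogonal matrix.
#' @param u non-zero direction vector.
#' @export
rank_one_step <- function(B, u) {
  u <- as.numeric(u)
  nu <- sum(u * u)
  if (nu == 0) stop("u must be non-zero")
  B - (2 / nu) * (u %*% (crossprod(u, B)))
}

#' Fast-path step for permutation inputs
#'
#' Finds the lexicographically smallest pair \code{(i, j)} lying in the same
#' cycle of the pairwise permutation of \code{(A, B)} and in the same cycle
#' of that of \code{(C, B)} -- i.e. a transposition that moves \code{B} one
#' rank-distance unit closer to both \code{A} and \code{C} simultaneously.
#' Returns \code{NULL} when no such pair exists. A between \code{B} never has
#' a pair, but the converse can fail: occasionally no shared pair exists even
#' though \code{B} is not yet between, and the walk falls back to the generic
#' rank-1 step (the image intersection is still provably non-trivial, just
#' not spanned by a two-point cycle overlap).
#'
#' @param a,b,cc permutations (image vectors) of the three inputs, \code{b}
#'   being the walking one.
#' @return integer pair \code{c(i, j)} or \code{NULL}.
#' @export
permutation_step <- function(a, b, cc) {
  a <- unclass_perm(a); b <- unclass_perm(b); cc <- unclass_perm(cc)
  lab1 <- agreement_partition(a, b)
  lab2 <- agreement_partition(cc, b)
  key <- paste(lab1, lab2)
  best <- NULL
  tab <- split(seq_along(key), key)
  for (grp in tab) {
    if (length(grp) < 2L) next
    cand <- c(grp[1], grp[2])
    if (is.null(best) || cand[1] < best[1] ||
        (cand[1] == best[1] && cand[2] < best[2])) {
      best <- cand
    }
  }
  best
}

# apply transposition (i j) to walking permutation b: swap the values i and j
apply_transposition <- function(b, pair) {
  pos_i <- which(b == pair[1]); pos_j <- which(b == pair[2])
  b[pos_i] <- pair[2]; b[pos_j] <- pair[1]
  b
}

#' Exact median of three orthogonal matrices
#'
#' "Walks towards the median": while \code{B} is not on a geodesic between
#' \code{A} and \code{C}, pick a non-zero \code{u} in
#' \code{im(A-B) intersect im(C-B)} and replace \code{B} by the orthogonal
#' rank-1 update \code{B + H}; each step decreases both \code{d(A, B)} and
#' \code{d(C, B)} by exactly 1, so the walk terminates after
#' \code{(d(A,B) + d(B,C) - d(A,C)) / 2} steps at an orthogonal median
#' attaining the lower bound \code{beta}. When all three inputs are
#' permutation matrices the step is the O(n) transposition fast path and all
#' intermediate states remain permutation matrices.
#'
#' @param A,B,C orthogonal matrices (checked; permutations and genomes are
#'   accepted and converted).
#' @param tol rank tolerance for all numerical rank computations.
#' @return a \code{"median_result"} whose matrix is orthogonal and whose
#'   score equals \code{beta}.
#' @export
orthogonal_median <- function(A, B, C, tol = 1e-6) {
  mats <- lapply(list(A, B, C), as_input_matrix)
  n <- nrow(mats[[1]])
  for (X in mats) {
    if (max(abs(crossprod(X) - diag(n))) > 10 * tol) {
      stop("input matrix is not orthogonal")
    }
  }
  perms <- lapply(mats, try_as_perm)
  iterations <- 0L
  Bk <- mats[[2]]
  if (!any(vapply(perms, is.null, logical(1)))) {
    a <- unclass_perm(perms[[1]]); b <- unclass_perm(perms[[2]])
    cc <- unclass_perm(perms[[3]])
    repeat {
      pair <- permutation_step(a, b, cc)
      if (is.null(pair)) break
      b <- apply_transposition(b, pair)
      iterations <- iterations + 1L
    }
    if (rank_distance_perm(a, b) + rank_distance_perm(b, cc) ==
        rank_distance_perm(a, cc)) {
      return(as_median_result(perm_to_matrix(b), perms,
                              method = "orthogonal-walk",
                              iterations = iterations))
    }
    # no shared transposition pair left but B is not yet between A and C:
    # continue with the generic rank-1 walk from the current state
    Bk <- perm_to_matrix(b)
  }
  while (!is_between(mats[[1]], Bk, mats[[3]], tol)) {
    u <- intersection_basis(mats[[1]], Bk, mats[[3]], tol)[, 1]
    Bk <- rank_one_step(Bk, u)
    iterations <- iterations + 1L
    drift <- max(abs(crossprod(Bk) - diag(n)))
    if (drift > 1e3 * tol) {
      s <- svd(Bk)
      Bk <- s$u %*% t(s$v)
    }
    if (iterations > n + 1L) {
      stop("numerical failure: walk did not terminate within n iterations")
    }
  }
  res <- as_median_result(Bk, mats, method = "orthogonal-walk",
                          iterations = iterations, tol = tol)
  res
}
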