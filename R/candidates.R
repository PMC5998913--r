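#' Orthonormal bases of the five-subspace decomposition
#'
#' Builds orthonormal basis blocks for \code{V1} (triple agreement),
#' \code{V2, V3, V4} (pairwise agreement modulo \code{V1}) and \code{V5}
#' (the orthogonal complement of the first four). For permutation inputs the
#' starting vectors are combinatorial: component indicators of the union
#' graph for \code{V1} and cycle indicators of the pairwise-agreement
#' permutations for \code{V2..V4}, projected off \code{V1} and
#' orthonormalized. The block dimensions must agree with
#' \code{\link{subspace_dims}}; any mismatch raises an internal consistency
#' error.
#'
#' @inheritParams beta_invariant
#' @param tol rank tolerance for the orthonormalization.
#' @return a list of five matrices (columns are basis vectors; dimension-0
#'   blocks have zero columns).
#' @export
subspace_bases <- function(rho, sigma, tau, tol = 1e-6) {
  tr <- as_perm_triple(rho, sigma, tau)
  n <- length(tr[[1]])
  dims <- subspace_dims(tr[[1]], tr[[2]], tr[[3]])

  v1 <- indicator_basis(union_components(tr), n)
  pair_parts <- list(agreement_partition(tr[[1]], tr[[2]]),
                     agreement_partition(tr[[2]], tr[[3]]),
                     agreement_partition(tr[[3]], tr[[1]]))
  blocks <- vector("list", 5L)
  blocks[[1]] <- orthonormalize(v1, tol = tol)
  for (k in 1:3) {
    full <- indicator_basis(pair_parts[[k]], n)
    resid <- full - blocks[[1]] %*% (t(blocks[[1]]) %*% full)
    blocks[[k + 1L]] <- orthonormalize(resid, tol = tol)
  }
  first4 <- do.call(cbind, blocks[1:4])
  blocks[[5]] <- orth_complement(first4, n, tol = tol)
  got <- vapply(blocks, ncol, integer(1))
  if (!all(got == dims)) {
    stop("internal consistency error: subspace dims ", paste(got, collapse = ","),
         " != ", paste(dims, collapse = ","))
  }
  names(blocks) <- paste0("V", 1:5)
  blocks
}

# membership vector of the partition {x : Ax = Bx} i.e. components of the
# graph with edges {rho(i), sigma(i)}
agreement_partition <- function(p, q) {
  n <- length(p)
  edges <- cbind(p, q)
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  components_membership(edges, n)
}

union_components <- function(tr) {
  n <- length(tr[[1]])
  edges <- rbind(cbind(tr[[1]], tr[[2]]), cbind(tr[[2]], tr[[3]]))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  components_membership(edges, n)
}

components_membership <- function(edges, n) {
  if (nrow(edges) == 0L) return(seq_len(n))
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(gr) < n) gr <- igraph::add_vertices(gr, n - igraph::vcount(gr))
  as.integer(igraph::components(gr)$membership)
}

indicator_basis <- function(membership, n) {
  ids <- sort(unique(membership))
  B <- matrix(0, n, length(ids))
  for (k in seq_along(ids)) {
    idx <- membership == ids[k]
    B[idx, k] <- 1 / sqrt(sum(idx))
  }
  B
}

orthonormalize <- function(X, tol = 1e-6) {
  if (is.null(X) || ncol(X) == 0L) return(matrix(0, nrow(X), 0L))
  s <- svd(X)
  r <- sum(s$d > tol * max(s$d, 1))
  s$u[, seq_len(r), drop = FALSE]
}

orth_complement <- function(X, n, tol = 1e-6) {
  if (ncol(X) == 0L) return(diag(n))
  s <- svd(X, nu = n)
  r <- sum(s$d > tol * max(s$d, 1))
  if (r == n) return(matrix(0, n, 0L))
  s$u[, (r + 1L):n, drop = FALSE]
}

#' Projection-based median candidates
#'
#' The candidate \code{M_A} acts as the agreed value on the agreement
#' subspaces \code{V1..V4} and as \code{A} on the remainder \code{V5}. Since
#' \code{A} already provides the agreed value on \code{V1}, \code{V2} (A=B)
#' and \code{V4} (C=A), this is the compact form
#' \code{M_A = A (I - P3) + B P3}, where \code{P3} is the projector onto the
#' B=C agreement block \code{V3} *along* the direct sum of the other four
#' subspaces (the decomposition is direct but not orthogonal, so \code{P3}
#' is oblique). Its score is exactly \code{beta + delta}, which makes it a
#' true median precisely when \code{delta = 0}; in that case all three
#' candidates coincide. \code{M_B} and \code{M_C} rotate the roles.
#'
#' @inheritParams beta_invariant
#' @param pick which of the three candidates to return (\code{"A"},
#'   \code{"B"} or \code{"C"}).
#' @param tol rank tolerance passed to \code{\link{subspace_bases}}.
#' @return a real matrix.
#' @export
candidate_median <- function(rho, sigma, tau, pick = c("A", "B", "C"),
                             tol = 1e-6) {
  pick <- match.arg(pick)
  tr <- as_perm_triple(rho, sigma, tau)
  n <- length(tr[[1]])
  bases <- subspace_bases(tr[[1]], tr[[2]], tr[[3]], tol = tol)
  # block of the disagreeing pair: V3 for M_A (B=C), V4 for M_B (C=A),
  # V2 for M_C (A=B); replace the acting matrix there by the agreed one
  spec <- switch(pick,
                 A = list(block = 3L, act = tr[[1]], agree = tr[[2]]),
                 B = list(block = 4L, act = tr[[2]], agree = tr[[3]]),
                 C = list(block = 2L, act = tr[[3]], agree = tr[[1]]))
  P <- oblique_projector(bases, spec$block)
  X <- perm_to_matrix(spec$act)
  Y <- perm_to_matrix(spec$agree)
  X %*% (diag(n) - P) + Y %*% P
}

# projector onto block k of a direct-sum basis list, along the other blocks
oblique_projector <- function(bases, k) {
  n <- nrow(bases[[1]])
  full <- do.call(cbind, bases)
  if (ncol(bases[[k]]) == 0L) return(matrix(0, n, n))
  coef <- solve(full)               # coordinates in the direct-sum basis
  pre <- sum(vapply(bases[seq_len(k - 1L)], ncol, integer(1)))
  idx <- pre + seq_len(ncol(bases[[k]]))
  bases[[k]] %*% coef[idx, , drop = FALSE]
}
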