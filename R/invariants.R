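#' Invariants of the median-of-three problem
#'
#' For permutations \code{rho, sigma, tau} (matrices \code{A, B, C} under the
#' convention \code{M[i, rho(i)] = 1}):
#' \itemize{
#'   \item \code{beta}: half the sum of the three pairwise rank distances,
#'     \code{(3n - [c(rho^-1 sigma) + c(sigma^-1 tau) + c(tau^-1 rho)]) / 2};
#'     the universal lower bound for the median score.
#'   \item \code{alpha}: the dimension of the triple-agreement subspace
#'     \code{V1 = {x : Ax = Bx = Cx}}, computed combinatorially as the number
#'     of connected components of the union graph with edges
#'     \code{{rho(i), sigma(i)}} and \code{{sigma(i), tau(i)}}.
#'   \item \code{delta = alpha + beta - n}: the deficiency. It is a
#'     non-negative integer for permutation inputs, and \code{delta == 0}
#'     characterizes the unique-median special case.
#' }
#' All three run in O(n).
#'
#' Inputs may be \code{"perm"} objects, image vectors, or \code{"genome"}
#' objects (converted to their involutions).
#'
#' @param rho,sigma,tau permutations (or genomes) on the same ground set.
#' @return an integer.
#' @rdname invariants
#' @export
beta_invariant <- function(rho, sigma, tau) {
  tr <- as_perm_triple(rho, sigma, tau)
  n <- length(tr[[1]])
  cc <- pairwise_cycle_counts(tr)
  as.integer((3L * n - sum(cc)) / 2)
}

#' @rdname invariants
#' @export
alpha_invariant <- function(rho, sigma, tau) {
  tr <- as_perm_triple(rho, sigma, tau)
  n <- length(tr[[1]])
  edges <- rbind(cbind(tr[[1]], tr[[2]]), cbind(tr[[2]], tr[[3]]))
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  if (nrow(edges) == 0L) return(n)
  gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(gr) < n) gr <- igraph::add_vertices(gr, n - igraph::vcount(gr))
  as.integer(igraph::components(gr)$no)
}

#' @rdname invariants
#' @export
delta_invariant <- function(rho, sigma, tau) {
  alpha_invariant(rho, sigma, tau) + beta_invariant(rho, sigma, tau) -
    length(as_perm_triple(rho, sigma, tau)[[1]])
}

as_perm_one <- function(x) {
  if (is_genome(x)) return(unclass_perm(genome_to_involution(x)))
  unclass_perm(x)
}

as_perm_triple <- function(rho, sigma, tau) {
  tr <- list(as_perm_one(rho), as_perm_one(sigma), as_perm_one(tau))
  nn <- vapply(tr, length, integer(1))
  if (length(unique(nn)) != 1L) stop("size mismatch: ", paste(nn, collapse = ", "))
  tr
}

# cycle counts of the three pair permutations rho^-1 sigma, sigma^-1 tau,
# tau^-1 rho (cycle counts are conjugation-invariant, so the composition
# order does not matter here)
pairwise_cycle_counts <- function(tr) {
  c(cycle_count(tr[[2]][perm_inverse(tr[[1]])]),
    cycle_count(tr[[3]][perm_inverse(tr[[2]])]),
    cycle_count(tr[[1]][perm_inverse(tr[[3]])]))
}

#' All three invariants at once
#'
#' @inheritParams beta_invariant
#' @return a list with \code{alpha}, \code{beta}, \code{delta}, \code{n} and
#'   the three pairwise cycle counts.
#' @export
median_invariants <- function(rho, sigma, tau) {
  tr <- as_perm_triple(rho, sigma, tau)
  n <- length(tr[[1]])
  cc <- pairwise_cycle_counts(tr)
  beta <- as.integer((3L * n - sum(cc)) / 2)
  alpha <- alpha_invariant(tr[[1]], tr[[2]], tr[[3]])
  list(alpha = alpha, beta = beta, delta = alpha + beta - n, n = n,
       cycle_counts = cc)
}

#' Dimensions of the five-subspace decomposition
#'
#' \code{R^n = V1 + V2 + V3 + V4 + V5} (direct sum), with \code{V1} the
#' triple-agreement subspace, \code{V2/V3/V4} the pairwise-agreement
#' subspaces (A=B, B=C, C=A) modulo \code{V1}, and \code{V5} the remainder.
#' Dimensions in terms of invariants: \code{dim V1 = alpha},
#' \code{dim V2 = c(rho^-1 sigma) - alpha} (similarly V3, V4) and
#' \code{dim V5 = 2 delta}.
#'
#' @inheritParams beta_invariant
#' @return integer vector of length 5.
#' @export
subspace_dims <- function(rho, sigma, tau) {
  inv <- median_invariants(rho, sigma, tau)
  dims <- c(inv$alpha, inv$cycle_counts - inv$alpha)
  c(dims, inv$n - sum(dims))
}

#' Median score of a candidate matrix
#'
#' The sum of the three rank distances \code{d(A, M) + d(B, M) + d(C, M)}.
#' When \code{M} and all three inputs are permutation matrices (within
#' \code{tol} of integers) the score is computed combinatorially via cycle
#' counts, with no rank computation; otherwise the numerical rank at
#' tolerance \code{tol} is used.
#'
#' @param M candidate matrix.
#' @param A,B,C input matrices (or permutations/genomes, which are converted).
#' @param tol rank/rounding tolerance.
#' @return a list with \code{score}, \code{beta} (when the inputs are
#'   permutations; otherwise the numerical half pairwise-distance sum) and
#'   \code{gap = score - beta}.
#' @export
median_score <- function(M, A, B, C, tol = 1e-12) {
  mats <- lapply(list(A, B, C), as_input_matrix)
  n <- nrow(mats[[1]])
  if (!all(vapply(mats, function(x) all(dim(x) == c(n, n)), logical(1))) ||
      !all(dim(M) == c(n, n))) {
    stop("shape mismatch")
  }
  perms <- lapply(mats, try_as_perm, tol = tol)
  pm <- try_as_perm(M, tol = tol)
  if (!any(vapply(c(perms, list(pm)), is.null, logical(1)))) {
    sc <- sum(vapply(perms, function(p) rank_distance_perm(p, pm), numeric(1)))
    beta <- beta_invariant(perms[[1]], perms[[2]], perms[[3]])
  } else {
    sc <- sum(vapply(mats, function(X) numeric_rank(X - M, tol = tol), integer(1)))
    beta <- (numeric_rank(mats[[1]] - mats[[2]], tol = tol) +
             numeric_rank(mats[[2]] - mats[[3]], tol = tol) +
             numeric_rank(mats[[3]] - mats[[1]], tol = tol)) / 2
  }
  list(score = as.integer(sc), beta = beta, gap = sc - beta)
}

as_input_matrix <- function(x) {
  if (is_genome(x)) return(genome_to_matrix(x))
  if (inherits(x, "perm") || (is.atomic(x) && !is.matrix(x))) {
    return(perm_to_matrix(x))
  }
  as.matrix(x)
}

try_as_perm <- function(M, tol = 1e-8) {
  out <- tryCatch(matrix_to_perm(M, tol = max(tol, 1e-8)), error = function(e) NULL)
  out
}

#' Lower bound on the median score
#'
#' Alias for \code{\link{beta_invariant}}: no matrix can score below
#' \code{beta}, and any matrix attaining it is a median.
#'
#' @inheritParams beta_invariant
#' @export
median_lower_bound <- beta_invariant
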