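#' Reduced difference-variable system for the median equations
#'
#' A matrix \code{M} attaining the lower bound \code{beta} must satisfy
#' \code{M = A + S(B - A) = B + T(C - B) = C + U(A - C)} for some matrices
#' \code{S, T, U}. Writing each column of \code{S(B - A)} (and the T and U
#' analogues) in terms of "difference variables" -- one free variable per
#' column, except that the columns belonging to one cycle of the pairwise
#' permutation sum to zero, so the column at the highest element of each
#' cycle is the negated sum of the others -- turns the equalities into
#' \code{n} independent linear systems (one per row of \code{M}) with a
#' shared left-hand side of \code{2(n - alpha)} equations in \code{2 beta}
#' unknowns. Redundant equations (one per connected component of the union
#' graph, at its highest element, in each half-system) are dropped.
#'
#' Under the matrix convention \code{M[i, rho(i)] = 1}, column \code{i} of
#' \code{S(B - A)} is \code{s[sigma^-1(i)] - s[rho^-1(i)]}; the columns are
#' grouped by the cycles of \code{rho o sigma^-1} (for involutions this
#' reduces to the familiar \code{rho^-1 sigma}).
#'
#' @inheritParams beta_invariant
#' @return an object of class \code{"median_system"}: the sparse coefficient
#'   matrix \code{L} (entries in -1/0/1), a variable table (family S/T/U,
#'   cycle, column index), the kept equation indices for each half, the
#'   per-family column-expression matrices used for reconstruction, and the
#'   invariants.
#' @export
build_difference_system <- function(rho, sigma, tau) {
  tr <- as_perm_triple(rho, sigma, tau)
  n <- length(tr[[1]])
  inv <- median_invariants(tr[[1]], tr[[2]], tr[[3]])

  # per-family block: columns of S(B-A) grouped by cycles of rho o sigma^-1
  blocks <- list(
    S = family_block(tr[[1]], tr[[2]]),
    T = family_block(tr[[2]], tr[[3]]),
    U = family_block(tr[[3]], tr[[1]])
  )
  nvars <- vapply(blocks, function(b) b$nvar, integer(1))
  offs <- cumsum(c(0L, nvars))[1:3]
  names(offs) <- names(blocks)
  p <- sum(nvars)
  stopifnot(p == 2L * inv$beta)

  # equations kept: drop the highest element of each union-graph component
  memb <- union_components(tr)
  drop_idx <- vapply(split(seq_len(n), memb), max, integer(1))
  keep <- setdiff(seq_len(n), drop_idx)

  # L has one row per kept equation in each half:
  #   half 1 (col i): T-expr(i) - S-expr(i) = (A - B)[j, i]
  #   half 2 (col i): U-expr(i) - T-expr(i) = (B - C)[j, i]
  half_rows <- function(plus, minus, off_plus, off_minus) {
    rows <- list()
    for (i in keep) {
      ip <- plus$expr[[i]]
      im <- minus$expr[[i]]
      rows[[length(rows) + 1L]] <- rbind(
        cbind(off_plus + ip$var, ip$coef),
        cbind(off_minus + im$var, -im$coef)
      )
    }
    rows
  }
  rows1 <- half_rows(blocks$T, blocks$S, offs["T"], offs["S"])
  rows2 <- half_rows(blocks$U, blocks$T, offs["U"], offs["T"])
  all_rows <- c(rows1, rows2)
  m_eq <- length(all_rows)
  ii <- rep(seq_len(m_eq), vapply(all_rows, nrow, integer(1)))
  ent <- do.call(rbind, all_rows)
  L <- if (length(ii) == 0L) {
    Matrix::Matrix(0, m_eq, p, sparse = TRUE)
  } else {
    Matrix::sparseMatrix(i = ii, j = ent[, 1], x = ent[, 2], dims = c(m_eq, p))
  }

  var_table <- do.call(rbind, lapply(names(blocks), function(f) {
    b <- blocks[[f]]
    if (b$nvar == 0L) return(NULL)
    data.frame(family = f, var = seq_len(b$nvar) + offs[f],
               column = b$var_column, cycle = b$var_cycle)
  }))

  structure(list(L = L, n = n, invariants = inv, blocks = blocks,
                 offsets = offs, keep = keep, dropped = sort(drop_idx),
                 variables = var_table),
            class = "median_system")
}

# For M = X + S(Y - X) with X, Y the matrices of perms x, y:
# column i of S(Y - X) is s[yinv(i)] - s[xinv(i)]; columns grouped by cycles
# of pi = x o y^-1; within each cycle the column at the highest element is
# -(sum of the others); free variables are numbered by cycles in order of
# smallest element, then by increasing column index.
family_block <- function(x, y) {
  n <- length(x)
  yinv <- perm_inverse(y)
  pi_vec <- x[yinv]                  # pi(i) = x(y^-1(i))
  cyc <- cycle_decomposition(pi_vec)
  expr <- vector("list", n)
  var_column <- integer(0); var_cycle <- integer(0)
  nv <- 0L
  for (k in seq_along(cyc$cycles)) {
    cy <- sort(cyc$cycles[[k]])
    if (length(cy) == 1L) next      # fixed column: identically zero
    free <- cy[-length(cy)]          # all but the highest element
    ids <- nv + seq_along(free)
    for (j in seq_along(free)) {
      expr[[free[j]]] <- list(var = ids[j], coef = 1)
    }
    expr[[cy[length(cy)]]] <- list(var = ids, coef = rep(-1, length(ids)))
    var_column <- c(var_column, free)
    var_cycle <- c(var_cycle, rep(k, length(free)))
    nv <- nv + length(free)
  }
  for (i in seq_len(n)) {
    if (is.null(expr[[i]])) expr[[i]] <- list(var = integer(0), coef = numeric(0))
  }
  list(nvar = nv, expr = expr, var_column = var_column, var_cycle = var_cycle,
       pi = pi_vec)
}

#' @export
print.median_system <- function(x, ...) {
  cat("median difference system: ", nrow(x$L), " equations, ", ncol(x$L),
      " unknowns (n = ", x$n, ", alpha = ", x$invariants$alpha,
      ", beta = ", x$invariants$beta, ", delta = ", x$invariants$delta, ")\n",
      sep = "")
  invisible(x)
}

# right-hand sides, one column per row index j of the median:
# rbind over kept equations of t(A - B) then t(B - C)
system_rhs <- function(sys, tr) {
  A <- perm_to_matrix(tr[[1]]); B <- perm_to_matrix(tr[[2]]); C <- perm_to_matrix(tr[[3]])
  rbind(t(A - B)[sys$keep, , drop = FALSE],
        t(B - C)[sys$keep, , drop = FALSE])
}

# assemble the median from the per-row solutions X (p x n, column j = the
# solution for row j). family "S" evaluates M = A + S(B-A); "T" evaluates
# M = B + T(C-B); "U" evaluates M = C + U(A-C) -- all three must agree on a
# valid solution, which the cross-check property test exercises
reconstruct_from_solutions <- function(sys, tr, X, family = "S") {
  n <- sys$n
  base <- switch(family, S = tr[[1]], T = tr[[2]], U = tr[[3]])
  blk <- sys$blocks[[family]]
  base_mat <- perm_to_matrix(base)
  if (blk$nvar == 0L) return(base_mat)
  CF <- matrix(0, n, blk$nvar)            # CF[i, v]: coef of var v in column i
  for (i in seq_len(n)) {
    e <- blk$expr[[i]]
    if (length(e$var)) CF[i, e$var] <- e$coef
  }
  Xf <- t(X[sys$offsets[family] + seq_len(blk$nvar), , drop = FALSE])  # n x nvar
  base_mat + Xf %*% t(CF)
}

#' Reconstruct a median matrix from per-row difference-variable solutions
#'
#' Evaluates \code{M = A + S(B - A)} columnwise: column \code{i} of
#' \code{S(B - A)} is the (sign-corrected) expression of the difference
#' variables of the cycle containing \code{i}, including the substituted
#' composite variable at the cycle's highest element.
#'
#' @param sys a \code{"median_system"}.
#' @param solutions matrix with one column per median row \code{j}, each the
#'   solution vector of the reduced system for that row.
#' @param family which expression of the median to evaluate: \code{"S"}
#'   (\code{A + S(B-A)}, the default), \code{"T"} (\code{B + T(C-B)}) or
#'   \code{"U"} (\code{C + U(A-C)}); they agree on any solution of the full
#'   system.
#' @inheritParams beta_invariant
#' @export
reconstruct_median <- function(sys, solutions, rho, sigma, tau, family = "S") {
  tr <- as_perm_triple(rho, sigma, tau)
  reconstruct_from_solutions(sys, tr, solutions, family = family)
}

#' Exact median for the deficiency-zero special case
#'
#' When \code{delta(A, B, C) = 0} the reduced system is square and
#' nonsingular, so the median is unique: the shared left-hand side is
#' factorized once and solved against all \code{n} right-hand sides. The
#' result always scores exactly \code{beta} and equals the projection
#' candidate \code{M_A}.
#'
#' @inheritParams beta_invariant
#' @param exact use exact rational Gaussian elimination instead of the sparse
#'   LU float path; bit-exact small fractions, slower, dense.
#' @return a \code{"median_result"} (see \code{\link{as_median_result}}).
#' @export
solve_special_case <- function(rho, sigma, tau, exact = FALSE) {
  tr <- as_perm_triple(rho, sigma, tau)
  sys <- build_difference_system(tr[[1]], tr[[2]], tr[[3]])
  if (sys$invariants$delta != 0L) {
    stop("delta = ", sys$invariants$delta, " != 0: the special-case solver ",
         "requires a deficiency-zero triple")
  }
  R <- system_rhs(sys, tr)
  if (ncol(sys$L) == 0L) {
    M <- perm_to_matrix(tr[[1]])
  } else if (exact) {
    X <- rational_solve(as.matrix(sys$L), R)
    M <- reconstruct_from_solutions(sys, tr, X)
  } else {
    X <- as.matrix(Matrix::solve(sys$L, R))
    M <- reconstruct_from_solutions(sys, tr, X)
  }
  M <- round_near_integers(M)
  as_median_result(M, tr, method = "exact-special")
}

#' Compressed-sensing median heuristic
#'
#' For \code{delta > 0} the reduced system is under-constrained; for every
#' row the solution of minimum L1 norm is sought (a sparse solution tends to
#' give a low-rank, often genomic, median). Each row's problem is the linear
#' program \code{min sum(y)} subject to \code{-y <= x <= y}, \code{L x = b},
#' solved here in the standard split form \code{x = u - v}, \code{u, v >= 0}.
#' Rows with identical right-hand sides share one solve. When
#' \code{delta = 0} this dispatches to \code{\link{solve_special_case}}.
#'
#' L1 solutions need not be unique; only the objective value and the
#' resulting score are meaningful, not the particular argmin.
#'
#' @inheritParams beta_invariant
#' @return a \code{"median_result"}.
#' @export
compressed_sensing_median <- function(rho, sigma, tau) {
  tr <- as_perm_triple(rho, sigma, tau)
  sys <- build_difference_system(tr[[1]], tr[[2]], tr[[3]])
  if (sys$invariants$delta == 0L) {
    res <- solve_special_case(tr[[1]], tr[[2]], tr[[3]])
    res$method <- "exact-special"
    return(res)
  }
  R <- system_rhs(sys, tr)
  key <- apply(R, 2L, paste, collapse = ",")
  X <- matrix(0, ncol(sys$L), sys$n)
  for (k in unique(key)) {
    j <- which(key == k)
    X[, j] <- l1_min_solve(sys$L, R[, j[1]])
  }
  M <- round_near_integers(reconstruct_from_solutions(sys, tr, X))
  as_median_result(M, tr, method = "compressed-sensing")
}

#' Minimum-L1 solution of an underdetermined linear system
#'
#' Solves \code{min ||x||_1 s.t. L x = b} by linear programming on the split
#' \code{x = u - v}, \code{u, v >= 0} (objective \code{sum(u + v)}).
#'
#' @param L coefficient matrix (dense or sparse).
#' @param b right-hand side.
#' @return the solution vector \code{x}.
#' @export
l1_min_solve <- function(L, b) {
  Ld <- as.matrix(L)
  p <- ncol(Ld)
  if (p == 0L) return(numeric(0))
  # boot::simplex requires non-negative b: flip rows as needed
  flip <- b < 0
  A3 <- cbind(Ld, -Ld)
  A3[flip, ] <- -A3[flip, , drop = FALSE]
  b3 <- abs(b)
  res <- boot::simplex(a = rep(1, 2L * p), A3 = A3, b3 = b3, maxi = FALSE)
  if (res$solved != 1) stop("internal error: L1 linear program did not solve ",
                            "(status ", res$solved, ")")
  u <- res$soln[seq_len(p)]
  v <- res$soln[p + seq_len(p)]
  u - v
}

#' Rank-distance median of three permutations or genomes
#'
#' Front door for the median machinery: computes the invariants and
#' dispatches to the exact deficiency-zero solver when \code{delta = 0},
#' otherwise to the requested method (compressed sensing by default;
#' \code{"orthogonal"} runs the exact walk of
#' \code{\link{orthogonal_median}}). \code{method = "auto"} runs the
#' compressed-sensing heuristic and, if it does not attain \code{beta}, also
#' the exact orthogonal walk, returning the better-scoring result.
#'
#' @inheritParams beta_invariant
#' @param method one of \code{"auto"}, \code{"exact-special"}, \code{"cs"},
#'   \code{"orthogonal"}.
#' @return a \code{"median_result"}.
#' @export
rank_median <- function(rho, sigma, tau,
                        method = c("auto", "exact-special", "cs", "orthogonal")) {
  method <- match.arg(method)
  tr <- as_perm_triple(rho, sigma, tau)
  inv <- median_invariants(tr[[1]], tr[[2]], tr[[3]])
  if (method == "exact-special" || inv$delta == 0L) {
    if (method %in% c("auto", "exact-special", "cs")) {
      return(solve_special_case(tr[[1]], tr[[2]], tr[[3]]))
    }
  }
  if (method == "cs") return(compressed_sensing_median(tr[[1]], tr[[2]], tr[[3]]))
  if (method == "orthogonal") {
    return(orthogonal_median(perm_to_matrix(tr[[1]]), perm_to_matrix(tr[[2]]),
                             perm_to_matrix(tr[[3]])))
  }
  cs <- compressed_sensing_median(tr[[1]], tr[[2]], tr[[3]])
  if (cs$gap == 0) return(cs)
  ortho <- orthogonal_median(perm_to_matrix(tr[[1]]), perm_to_matrix(tr[[2]]),
                             perm_to_matrix(tr[[3]]))
  if (ortho$score < cs$score) ortho else cs
}

# exact rational Gaussian elimination for systems with small entries;
# numerators/denominators kept as doubles and reduced by gcd at each step
rational_solve <- function(L, R) {
  m <- nrow(L); p <- ncol(L)
  stopifnot(m >= p)
  num <- cbind(L, R)
  den <- matrix(1, nrow(num), ncol(num))
  gcd2 <- function(a, b) {
    a <- abs(a); b <- abs(b)
    while (any(b != 0)) {
      t <- b
      b <- a %% b
      b[is.nan(b)] <- 0
      a <- t
    }
    pmax(a, 1)
  }
  reduce <- function(i) {
    g <- gcd2(num[i, ], den[i, ])
    num[i, ] <<- num[i, ] / g
    den[i, ] <<- den[i, ] / g
    neg <- den[i, ] < 0
    num[i, neg] <<- -num[i, neg]
    den[i, neg] <<- -den[i, neg]
  }
  piv_rows <- integer(0)
  row <- 1L
  for (col in seq_len(p)) {
    pivot <- which(num[row:m, col] != 0)
    if (length(pivot) == 0L) stop("rational solve: singular system")
    pivot <- row + pivot[1] - 1L
    if (pivot != row) {
      tmp <- num[row, ]; num[row, ] <- num[pivot, ]; num[pivot, ] <- tmp
      tmp <- den[row, ]; den[row, ] <- den[pivot, ]; den[pivot, ] <- tmp
    }
    # normalize pivot row to leading 1
    pn <- num[row, col]; pd <- den[row, col]
    num[row, ] <- num[row, ] * pd
    den[row, ] <- den[row, ] * pn
    reduce(row)
    for (r in seq_len(m)) {
      if (r == row || num[r, col] == 0) next
      f_n <- num[r, col]; f_d <- den[r, col]
      # row_r <- row_r - f * row_pivot
      nn <- num[r, ] * den[row, ] * f_d - num[row, ] * den[r, ] * f_n
      dd <- den[r, ] * den[row, ] * f_d
      num[r, ] <- nn; den[r, ] <- dd
      reduce(r)
    }
    piv_rows <- c(piv_rows, row)
    row <- row + 1L
    if (row > m) break
  }
  # remaining rows must be 0 = 0
  X <- num[seq_len(p), p + seq_len(ncol(R)), drop = FALSE] /
       den[seq_len(p), p + seq_len(ncol(R)), drop = FALSE]
  X
}
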