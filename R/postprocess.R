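#' Snap near-integer entries
#'
#' Any entry within \code{eps} of 0, 1 or -1 is rounded to that integer;
#' everything else is untouched. Idempotent.
#'
#' @param M numeric matrix.
#' @param eps snapping tolerance.
#' @export
round_near_integers <- function(M, eps = 1e-12) {
  for (v in c(0, 1, -1)) {
    hit <- abs(M - v) <= eps & M != v
    M[hit] <- v
  }
  M
}

#' Classify a median matrix
#'
#' Taxonomy of median outputs, checked in order:
#' \code{"fractional"} (any non-integer entry), \code{"integer_with_negative"}
#' (integer entries, some negative or outside 0/1),
#' \code{"binary_non_permutation"} (all entries 0/1 but some column without
#' exactly one 1), \code{"permutation_non_genomic"} (permutation matrix that
#' is not symmetric), \code{"genomic"} (symmetric permutation matrix).
#'
#' @param M numeric square matrix.
#' @param eps integrality tolerance.
#' @return a classification label (character).
#' @export
classify_matrix <- function(M, eps = 1e-9) {
  R <- round(M)
  if (max(abs(M - R)) > eps) return("fractional")
  if (any(R < 0) || any(R > 1)) return("integer_with_negative")
  if (any(colSums(R) != 1) || any(rowSums(R) != 1)) return("binary_non_permutation")
  if (any(R != t(R))) return("permutation_non_genomic")
  "genomic"
}

#' Wrap a median matrix with its score, gap and classification
#'
#' @param M median matrix.
#' @param inputs list of three permutations (image vectors) or matrices.
#' @param method label of the producing algorithm.
#' @param iterations iteration count, where meaningful.
#' @param tol scoring tolerance.
#' @return an object of class \code{"median_result"} with fields
#'   \code{matrix}, \code{score}, \code{beta}, \code{delta} (permutation
#'   inputs only), \code{gap}, \code{classification}, \code{method},
#'   \code{iterations}.
#' @export
as_median_result <- function(M, inputs, method = "unspecified",
                             iterations = NA_integer_, tol = 1e-12) {
  mats <- lapply(inputs, as_input_matrix)
  sc <- median_score(M, mats[[1]], mats[[2]], mats[[3]], tol = tol)
  delta <- NA_integer_
  perms <- lapply(mats, try_as_perm)
  if (!any(vapply(perms, is.null, logical(1)))) {
    delta <- delta_invariant(perms[[1]], perms[[2]], perms[[3]])
  }
  structure(list(matrix = M, score = sc$score, beta = sc$beta,
                 delta = delta, gap = sc$gap,
                 classification = classify_matrix(M),
                 method = method, iterations = iterations),
            class = "median_result")
}

#' @export
print.median_result <- function(x, ...) {
  cat("rank-distance median (", x$method, ")\n", sep = "")
  cat("  n = ", nrow(x$matrix), ", score = ", x$score, ", beta = ", x$beta,
      ", gap = ", x$gap, if (!is.na(x$delta)) paste0(", delta = ", x$delta),
      "\n", sep = "")
  cat("  classification:", x$classification, "\n")
  if (!is.na(x$iterations)) cat("  iterations:", x$iterations, "\n")
  invisible(x)
}

#' Sample a genome from an orthogonal median matrix
#'
#' An orthogonal matrix has rows whose squared entries sum to 1, so each row
#' of \code{M o M} (entrywise square) is a probability distribution over the
#' potential partners of that extremity (the diagonal entry being "telomere").
#' Rows are visited in random order; for each still-unassigned extremity a
#' partner is drawn from its row distribution restricted to unassigned
#' extremities (renormalized; uniform fallback when the available mass is 0).
#' A genomic \code{M} is returned unchanged, as every row is a point mass.
#'
#' @param M orthogonal matrix (row sums of \code{M o M} within \code{tol}
#'   of 1).
#' @param avoid_negative zero out probabilities where \code{M[i, j] < 0}
#'   before renormalizing (off by default).
#' @param tol orthogonality tolerance.
#' @return a \code{"genome"}. Randomness is taken from the R RNG; seed it
#'   with \code{set.seed()} for reproducibility.
#' @export
sample_genome <- function(M, avoid_negative = FALSE, tol = 1e-6) {
  n <- nrow(M)
  P <- M * M
  if (max(abs(rowSums(P) - 1)) > tol) {
    stop("matrix is not orthogonal: row sums of M o M deviate from 1")
  }
  assigned <- logical(n)
  adj <- list()
  for (i in sample.int(n)) {
    if (assigned[i]) next
    avail <- which(!assigned)
    pr <- P[i, avail]
    if (avoid_negative) pr[M[i, avail] < 0] <- 0
    if (sum(pr) <= 0) pr <- rep(1, length(avail))
    j <- if (length(avail) == 1L) avail else sample(avail, 1L, prob = pr)
    assigned[i] <- TRUE
    if (j != i) {
      assigned[j] <- TRUE
      adj[[length(adj) + 1L]] <- c(i, j)
    }
  }
  genome(n, if (length(adj)) do.call(rbind, adj) else NULL)
}
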