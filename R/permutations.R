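#' Permutations as 1-based image vectors
#'
#' A permutation on \code{1..n} is stored as an integer vector \code{p} with
#' \code{p[i]} giving the image of \code{i}. The class \code{"perm"} is a thin
#' wrapper used for printing and validation; most internal code works on the
#' bare integer vector.
#'
#' @param mapping integer vector; entry \code{i} is the image of \code{i}.
#'   Must be a rearrangement of \code{1..n}. A cycle-notation string is also
#'   accepted.
#' @param n ground-set size, only used when \code{mapping} is a string.
#' @return an object of class \code{"perm"}.
#' @examples
#' as_perm(c(2, 1, 3))        # the transposition (1 2) on n = 3
#' as_perm("(1 2)(3 4)", n = 4)
#' @export
as_perm <- function(mapping, n = NULL) {
  if (is.character(mapping)) {
    return(parse_cycles(mapping, n = n))
  }
  p <- as.integer(mapping)
  validate_perm(p)
  structure(p, class = "perm")
}

validate_perm <- function(p) {
  n <- length(p)
  if (n == 0L) stop("permutation must have length >= 1")
  if (anyNA(p) || !identical(sort(p), seq_len(n))) {
    stop("entries must be a rearrangement of 1..n")
  }
  invisible(p)
}

#' @export
print.perm <- function(x, ...) {
  cyc <- cycle_decomposition(x)
  lab <- vapply(cyc$cycles, function(cy) paste0("(", paste(cy, collapse = " "), ")"),
                character(1))
  cat("permutation on n =", length(x), ":", paste(lab, collapse = ""), "\n")
  invisible(x)
}

#' Parse cycle notation
#'
#' Reads strings like \code{"(1 2)(3 4)"}. Elements not mentioned are fixed
#' points; \code{n} defaults to the largest element seen.
#'
#' @param text cycle-notation string.
#' @param n size of the ground set (optional).
#' @return a \code{"perm"}.
#' @export
parse_cycles <- function(text, n = NULL) {
  text <- gsub("\\s+", " ", trimws(text))
  chunks <- regmatches(text, gregexpr("\\(([^()]*)\\)", text))[[1]]
  elems <- lapply(chunks, function(ch) {
    inner <- gsub("[(),]", " ", ch)
    v <- suppressWarnings(as.integer(strsplit(trimws(inner), "\\s+")[[1]]))
    if (anyNA(v)) stop("cannot parse cycle: ", ch)
    v
  })
  if (anyDuplicated(unlist(elems))) stop("repeated element across cycles")
  top <- if (length(elems)) max(unlist(elems)) else 0L
  if (is.null(n)) n <- top
  if (n < top) stop("n smaller than largest element in cycles")
  if (n < 1L) stop("empty permutation")
  p <- seq_len(n)
  for (cy in elems) {
    if (length(cy) > 1L) p[cy] <- cy[c(2:length(cy), 1L)]
  }
  as_perm(p)
}

#' Identity permutation
#' @param n size.
#' @export
perm_identity <- function(n) as_perm(seq_len(n))

#' Compose two permutations
#'
#' Returns the permutation \code{i -> q(p(i))}: \code{p} is applied first.
#' This order is chosen so that
#' \code{perm_to_matrix(compose(p, q)) == perm_to_matrix(p) \%*\% perm_to_matrix(q)}.
#'
#' @param p,q permutations on the same ground set.
#' @return a \code{"perm"}.
#' @export
compose <- function(p, q) {
  p <- unclass_perm(p); q <- unclass_perm(q)
  if (length(p) != length(q)) stop("size mismatch: ", length(p), " vs ", length(q))
  structure(q[p], class = "perm")
}

#' Invert a permutation
#' @param p a permutation.
#' @export
perm_inverse <- function(p) {
  p <- unclass_perm(p)
  inv <- integer(length(p))
  inv[p] <- seq_along(p)
  structure(inv, class = "perm")
}

unclass_perm <- function(p) {
  p <- as.integer(p)
  validate_perm(p)
  p
}

#' Disjoint-cycle decomposition
#'
#' Fixed points are kept as length-1 cycles, so cycle lengths always sum to
#' \code{n}. Canonical form: each cycle starts at its smallest element and
#' cycles are sorted by that element.
#'
#' @param p a permutation.
#' @return a list with \code{cycles} (list of integer vectors) and
#'   \code{count}, the cycle counter \code{c(p)}.
#' @export
cycle_decomposition <- function(p) {
  p <- unclass_perm(p)
  n <- length(p)
  seen <- logical(n)
  cycles <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    cy <- i
    j <- p[i]
    seen[i] <- TRUE
    while (j != i) {
      cy <- c(cy, j)
      seen[j] <- TRUE
      j <- p[j]
    }
    cycles[[length(cycles) + 1L]] <- cy
  }
  list(cycles = cycles, count = length(cycles))
}

#' Number of disjoint cycles, counting fixed points
#' @param p a permutation (image vector).
#' @export
cycle_count <- function(p) {
  p <- unclass_perm(p)
  n <- length(p)
  seen <- logical(n)
  cnt <- 0L
  for (i in seq_len(n)) {
    if (seen[i]) next
    cnt <- cnt + 1L
    j <- i
    repeat {
      seen[j] <- TRUE
      j <- p[j]
      if (j == i) break
    }
  }
  cnt
}

#' Permutation matrix of a permutation
#'
#' \code{M[i, j] = 1} iff \code{p(i) = j}, so \code{M x = x[p]} (the image
#' convention of the rank-distance literature).
#'
#' @param p a permutation.
#' @return a dense 0/1 matrix.
#' @export
perm_to_matrix <- function(p) {
  p <- unclass_perm(p)
  n <- length(p)
  M <- matrix(0, n, n)
  M[cbind(seq_len(n), p)] <- 1
  M
}

#' Recover a permutation from a permutation matrix
#'
#' @param M square matrix; entries are rounded at \code{tol} and must form a
#'   permutation matrix.
#' @param tol rounding tolerance for entries.
#' @export
matrix_to_perm <- function(M, tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("M must be square")
  R <- round(M)
  if (max(abs(M - R)) > tol) stop("matrix is not binary within tolerance")
  if (!all(R %in% c(0, 1))) stop("matrix is not binary")
  if (any(rowSums(R) != 1) || any(colSums(R) != 1)) {
    stop("matrix is not a permutation matrix (row/column sums differ from 1)")
  }
  as_perm(apply(R == 1, 1L, which))
}

#' Read and write one-line permutation files
#'
#' Image form: \code{n} space-separated integers on one line. Cycle notation
#' such as \code{"(1 2)(3 4)"} is also accepted on input.
#'
#' @param path file path.
#' @rdname perm_io
#' @export
read_permutation <- function(path) {
  line <- trimws(readLines(path, warn = FALSE))
  line <- line[nzchar(line) & !startsWith(line, "#")]
  if (length(line) == 0L) stop("no permutation found in ", path)
  txt <- line[[1]]
  if (grepl("\\(", txt)) return(parse_cycles(txt))
  as_perm(as.integer(strsplit(txt, "\\s+")[[1]]))
}

#' @param p permutation to write.
#' @rdname perm_io
#' @export
write_permutation <- function(p, path) {
  writeLines(paste(unclass_perm(p), collapse = " "), path)
  invisible(path)
}
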