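#' Multi-genome breakpoint graph of two genomes
#'
#' One vertex per extremity; one edge per adjacency, colored by genome. The
#' components of this multigraph are paths and cycles (isolated vertices --
#' extremities telomeric in both genomes -- are 0-edge paths and contribute
#' nothing to any count). A common adjacency shows up as a 2-cycle of two
#' parallel edges.
#'
#' @param g1,g2 genomes on the same number of extremities.
#' @return an object of class \code{"breakpoint_graph"}: the edge list with
#'   colors and the component summary \code{m} (total edges), \code{c}
#'   (cycles of any length), \code{c2} (2-cycles) and \code{p_odd} (paths
#'   with an odd number of edges).
#' @export
build_breakpoint_graph <- function(g1, g2) {
  stopifnot(is_genome(g1), is_genome(g2))
  if (g1$n != g2$n) stop("size mismatch: ", g1$n, " vs ", g2$n)
  edges <- rbind(g1$adjacencies, g2$adjacencies)
  color <- rep(c(1L, 2L), c(nrow(g1$adjacencies), nrow(g2$adjacencies)))
  m <- nrow(edges)
  c_cycles <- 0L; c2 <- 0L; p_odd <- 0L
  if (m > 0L) {
    gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(gr) < g1$n) gr <- igraph::add_vertices(gr, g1$n - igraph::vcount(gr))
    comp <- igraph::components(gr)
    e_comp <- comp$membership[edges[, 1]]
    n_edges <- tabulate(e_comp, nbins = comp$no)
    n_verts <- comp$csize
    is_cycle <- n_edges > 0L & n_edges == n_verts
    c_cycles <- sum(is_cycle)
    c2 <- sum(is_cycle & n_edges == 2L)
    p_odd <- sum(!is_cycle & n_edges %% 2L == 1L)
  }
  structure(list(n = g1$n, edges = edges, color = color,
                 m = m, c = c_cycles, c2 = c2, p_odd = p_odd),
            class = "breakpoint_graph")
}

#' @export
print.breakpoint_graph <- function(x, ...) {
  cat("breakpoint graph on", x$n, "extremities:",
      "m =", x$m, ", cycles =", x$c, "(2-cycles:", paste0(x$c2, ")"),
      ", odd paths =", x$p_odd, "\n")
  invisible(x)
}

as_genome_pair <- function(g1, g2) {
  if (!is_genome(g1) || !is_genome(g2)) stop("inputs must be genomes")
  if (g1$n != g2$n) stop("size mismatch: ", g1$n, " vs ", g2$n)
  list(g1, g2)
}

#' Rearrangement distances between two genomes
#'
#' Breakpoint-graph formulas: with \code{m} edges, \code{c} cycles, \code{c2}
#' 2-cycles and \code{p_odd} odd paths,
#' \itemize{
#'   \item rank distance: \code{m - 2c} (equals the rank of the difference of
#'     the genomic matrices, and the Cayley distance of the involutions);
#'   \item SCJ distance: \code{m - 2*c2}, the number of adjacencies in exactly
#'     one genome;
#'   \item DCJ distance: \code{m/2 - c + p_odd/2};
#'   \item algebraic distance: half the rank distance.
#' }
#'
#' @param g1,g2 genomes on the same number of extremities.
#' @return a single number (integer for rank and SCJ; DCJ and the algebraic
#'   distance can be half-integers, returned exactly as multiples of 0.5).
#' @rdname genome_distances
#' @export
rank_distance <- function(g1, g2) {
  bg <- build_breakpoint_graph(g1, g2)
  as.integer(bg$m - 2L * bg$c)
}

#' @rdname genome_distances
#' @export
scj_distance <- function(g1, g2) {
  bg <- build_breakpoint_graph(g1, g2)
  as.integer(bg$m - 2L * bg$c2)
}

#' @rdname genome_distances
#' @export
dcj_distance <- function(g1, g2) {
  bg <- build_breakpoint_graph(g1, g2)
  (bg$m - 2L * bg$c + bg$p_odd) / 2
}

#' @rdname genome_distances
#' @export
algebraic_distance <- function(g1, g2) {
  rank_distance(g1, g2) / 2
}

#' Rank distance between permutations (Cayley distance)
#'
#' \code{n - c(rho^-1 sigma)}: the minimum number of transpositions turning
#' one permutation into the other.
#'
#' @param p,q permutations on the same ground set.
#' @export
rank_distance_perm <- function(p, q) {
  p <- unclass_perm(p); q <- unclass_perm(q)
  if (length(p) != length(q)) stop("size mismatch")
  length(p) - cycle_count(q[perm_inverse(p)])
}

#' Rank distance between arbitrary real matrices
#'
#' Numerical rank of \code{A - B} by QR at tolerance \code{tol}.
#'
#' @param A,B matrices of the same shape.
#' @param tol rank tolerance (the scoring default is 1e-12).
#' @export
rank_distance_matrix <- function(A, B, tol = 1e-12) {
  if (!all(dim(A) == dim(B))) stop("shape mismatch")
  numeric_rank(A - B, tol = tol)
}

numeric_rank <- function(X, tol = 1e-12) {
  if (max(abs(X)) == 0) return(0L)
  # SVD rank with the absolute tolerance of the scoring convention; QR-based
  # rank estimates can badly overcount on the exact low-rank differences
  # that arise here
  sum(svd(X, nu = 0, nv = 0)$d > tol)
}
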