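#' Packaged worked examples
#'
#' Small instances used throughout the documentation and tests:
#' \describe{
#'   \item{\code{"klein"}}{the Klein four-group triple on n = 4:
#'     rho = (12)(34), sigma = (13)(24), tau = (14)(23). Genomic, delta = 0,
#'     unique median (J/2 - I) of score beta = 3.}
#'   \item{\code{"cycle3"}}{the n = 3 triple rho = (12), sigma = (13),
#'     tau = (23): alpha = 1, beta = 3, delta = 1; the compressed-sensing
#'     heuristic is suboptimal here while the identity and both 3-cycles
#'     score beta = 3.}
#'   \item{\code{"counterexample2x2"}}{A = -I, B = 0, C = I on n = 2: general
#'     matrices with beta = 3 whose minimum score is 4, showing the lower
#'     bound is not always attained outside the orthogonal class.}
#'   \item{\code{"discussion"}}{the genomic triple A = (12)(34),
#'     B = (14)(23), C = (13)(24) used to illustrate probabilistic genome
#'     projection of the non-genomic median J/2 - I.}
#' }
#'
#' @param which example name.
#' @return a list with fields depending on the example: \code{perms} (list of
#'   three \code{"perm"}), \code{genomes} (for the genomic triples),
#'   \code{matrices} (always), and \code{median}/\code{beta} where the median
#'   is known in closed form.
#' @export
median_example <- function(which = c("klein", "cycle3", "counterexample2x2",
                                     "discussion")) {
  which <- match.arg(which)
  if (which == "klein") {
    perms <- list(as_perm("(1 2)(3 4)"), as_perm("(1 3)(2 4)"),
                  as_perm("(1 4)(2 3)"))
    J <- matrix(1, 4, 4)
    return(list(perms = perms,
                genomes = lapply(perms, involution_to_genome),
                matrices = lapply(perms, perm_to_matrix),
                median = J / 2 - diag(4), beta = 3L))
  }
  if (which == "cycle3") {
    perms <- list(as_perm("(1 2)", n = 3), as_perm("(1 3)", n = 3),
                  as_perm("(2 3)", n = 3))
    return(list(perms = perms,
                matrices = lapply(perms, perm_to_matrix),
                cs_printed = cbind(0, 0, rep(1, 3)),  # the [0 0 e] candidate
                beta = 3L))
  }
  if (which == "counterexample2x2") {
    return(list(matrices = list(-diag(2), matrix(0, 2, 2), diag(2)),
                beta = 3L, min_score = 4L))
  }
  perms <- list(as_perm("(1 2)(3 4)"), as_perm("(1 4)(2 3)"),
                as_perm("(1 3)(2 4)"))
  J <- matrix(1, 4, 4)
  list(perms = perms,
       genomes = lapply(perms, involution_to_genome),
       matrices = lapply(perms, perm_to_matrix),
       median = J / 2 - diag(4), beta = 3L)
}
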