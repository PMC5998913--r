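#' Genomes as partitions of extremities
#'
#' A genome on \code{n} extremities is a perfect partition of \code{1..n} into
#' unordered pairs (adjacencies) and singletons (telomeres). Equivalently it
#' is an involution: the symmetric permutation fixing telomeres and swapping
#' the two ends of each adjacency. Extremity \code{2g - 1} is the tail and
#' \code{2g} the head of gene \code{g} when the genome comes from a gene
#' order, but the matrix machinery accepts any \code{n} (odd included).
#'
#' @param n number of extremities.
#' @param adjacencies two-column matrix (or list of length-2 vectors) of
#'   extremity pairs; may be \code{NULL} for an all-telomere genome.
#' @return an object of class \code{"genome"} with fields \code{n},
#'   \code{adjacencies} (k x 2 matrix, each row sorted, rows ordered by first
#'   element) and \code{telomeres} (sorted integer vector).
#' @examples
#' genome(4, rbind(c(1, 2), c(3, 4)))
#' genome(4, c(3, 4))   # telomeres 1 and 2, one adjacency {3,4}
#' @export
genome <- function(n, adjacencies = NULL) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  adj <- normalize_adjacencies(adjacencies)
  used <- as.vector(adj)
  if (length(used)) {
    if (anyNA(used) || any(used < 1L | used > n)) stop("extremity out of range 1..n")
    if (any(adj[, 1] == adj[, 2])) stop("an adjacency must join two distinct extremities")
    if (anyDuplicated(used)) stop("an extremity appears in more than one adjacency")
  }
  tel <- setdiff(seq_len(n), used)
  structure(list(n = n, adjacencies = adj, telomeres = tel), class = "genome")
}

normalize_adjacencies <- function(adjacencies) {
  if (is.null(adjacencies) || (is.matrix(adjacencies) && nrow(adjacencies) == 0L)) {
    return(matrix(integer(0), 0, 2))
  }
  if (is.list(adjacencies)) adjacencies <- do.call(rbind, adjacencies)
  if (is.vector(adjacencies)) adjacencies <- matrix(adjacencies, ncol = 2, byrow = TRUE)
  adj <- matrix(as.integer(adjacencies), ncol = 2)
  adj <- t(apply(adj, 1L, sort))
  adj <- matrix(as.integer(adj), ncol = 2)
  adj[order(adj[, 1]), , drop = FALSE]
}

#' @export
print.genome <- function(x, ...) {
  a <- apply(x$adjacencies, 1L, function(r) paste0("{", r[1], ",", r[2], "}"))
  cat("genome on n =", x$n, "extremities\n")
  cat("  adjacencies:", if (length(a)) paste(a, collapse = " ") else "(none)", "\n")
  cat("  telomeres:  ", if (length(x$telomeres)) paste(x$telomeres, collapse = " ") else "(none)", "\n")
  invisible(x)
}

#' @export
`==.genome` <- function(e1, e2) {
  e1$n == e2$n && identical(e1$adjacencies, e2$adjacencies)
}

is_genome <- function(x) inherits(x, "genome")

#' Genome to involution and back
#'
#' The involution maps each extremity to its adjacency partner and fixes
#' telomeres; it is its own inverse.
#'
#' @param g a \code{"genome"}.
#' @return a \code{"perm"}.
#' @export
genome_to_involution <- function(g) {
  stopifnot(is_genome(g))
  p <- seq_len(g$n)
  if (nrow(g$adjacencies)) {
    p[g$adjacencies[, 1]] <- g$adjacencies[, 2]
    p[g$adjacencies[, 2]] <- g$adjacencies[, 1]
  }
  as_perm(p)
}

#' @param p an involution (\code{"perm"} equal to its own inverse).
#' @rdname genome_to_involution
#' @export
involution_to_genome <- function(p) {
  p <- unclass_perm(p)
  if (!identical(as.integer(p[p]), seq_along(p))) stop("permutation is not an involution")
  i <- which(p > seq_along(p))
  genome(length(p), cbind(i, p[i]))
}

#' Genomic matrix of a genome
#'
#' Symmetric permutation matrix with \code{M[i, j] = M[j, i] = 1} for each
#' adjacency \code{{i, j}} and \code{M[i, i] = 1} for each telomere.
#'
#' @param g a \code{"genome"}.
#' @export
genome_to_matrix <- function(g) {
  perm_to_matrix(genome_to_involution(g))
}

#' Validate and convert a genomic matrix back to a genome
#'
#' Entries are rounded at \code{tol}; the result must be a symmetric
#' permutation matrix (the rejection message states which property failed).
#'
#' @param M square numeric matrix.
#' @param tol entry rounding tolerance.
#' @export
matrix_to_genome <- function(M, tol = 1e-8) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("not genomic: matrix must be square")
  R <- round(M)
  if (max(abs(M - R)) > tol || !all(R %in% c(0, 1))) {
    stop("not genomic: matrix is not binary (classification: ", classify_matrix(M), ")")
  }
  if (any(rowSums(R) != 1) || any(colSums(R) != 1)) {
    stop("not genomic: not a permutation matrix (classification: ",
         classify_matrix(R), ")")
  }
  if (any(R != t(R))) {
    stop("not genomic: permutation matrix is asymmetric (classification: ",
         classify_matrix(R), ")")
  }
  involution_to_genome(matrix_to_perm(R))
}

#' Gene orders
#'
#' A gene order is a list of chromosomes, each a signed integer vector plus a
#' shape (\code{"linear"} or \code{"circular"}). Every gene id must appear
#' exactly once across chromosomes.
#'
#' @param chromosomes list of signed integer vectors.
#' @param shapes character vector of \code{"linear"}/\code{"circular"}, one
#'   per chromosome (recycled if length 1).
#' @export
gene_order <- function(chromosomes, shapes = "linear") {
  if (!is.list(chromosomes)) chromosomes <- list(chromosomes)
  chromosomes <- lapply(chromosomes, as.integer)
  shapes <- rep_len(match.arg(shapes, c("linear", "circular"), several.ok = TRUE),
                    length(chromosomes))
  genes <- abs(unlist(chromosomes))
  if (length(genes) == 0L) stop("empty gene order")
  if (any(genes < 1L) || any(unlist(chromosomes) == 0L)) stop("gene ids must be nonzero")
  if (anyDuplicated(genes)) stop("duplicate gene id: ", genes[duplicated(genes)][1])
  if (!setequal(genes, seq_len(max(genes)))) {
    stop("missing gene ids: ", paste(setdiff(seq_len(max(genes)), genes), collapse = ", "))
  }
  structure(list(chromosomes = chromosomes, shapes = shapes), class = "gene_order")
}

#' Convert a signed gene order to a genome on extremities
#'
#' Gene \code{g} contributes tail extremity \code{2g - 1} and head \code{2g};
#' a gene read in positive orientation is traversed tail-to-head. Consecutive
#' genes are joined by the adjacency between the outgoing end of the first
#' and the incoming end of the second; linear chromosome ends are telomeres
#' and circular chromosomes join last to first.
#'
#' @param go a \code{"gene_order"}.
#' @return a \code{"genome"} on \code{2 * (number of genes)} extremities.
#' @export
gene_order_to_genome <- function(go) {
  stopifnot(inherits(go, "gene_order"))
  n <- 2L * length(unlist(go$chromosomes))
  adj <- list()
  for (k in seq_along(go$chromosomes)) {
    chr <- go$chromosomes[[k]]
    # incoming/outgoing extremity of each signed gene
    tails <- 2L * abs(chr) - 1L
    heads <- 2L * abs(chr)
    inc <- ifelse(chr > 0L, tails, heads)
    out <- ifelse(chr > 0L, heads, tails)
    m <- length(chr)
    if (m > 1L) {
      for (i in seq_len(m - 1L)) adj[[length(adj) + 1L]] <- c(out[i], inc[i + 1L])
    }
    if (go$shapes[k] == "circular") adj[[length(adj) + 1L]] <- c(out[m], inc[1L])
  }
  genome(n, if (length(adj)) do.call(rbind, adj) else NULL)
}

#' Recover chromosomes from a genome
#'
#' Walks the components of the graph whose edges are the gene edges
#' \code{(2g-1, 2g)} and the genome's adjacencies. Components are linear
#' chromosomes (two telomeric ends) or circular chromosomes.
#'
#' @param g a \code{"genome"} on an even number of extremities.
#' @return a \code{"gene_order"}.
#' @export
genome_to_gene_order <- function(g) {
  stopifnot(is_genome(g))
  if (g$n %% 2L != 0L) stop("genome has odd n; not a gene-extremity encoding")
  ngenes <- g$n %/% 2L
  partner <- unclass_perm(genome_to_involution(g))  # adjacency partner / self
  gene_of <- rep(seq_len(ngenes), each = 2L)
  other_end <- function(e) if (e %% 2L == 1L) e + 1L else e - 1L
  seen <- logical(ngenes)
  chroms <- list(); shapes <- character(0)

  walk <- function(start_ext) {
    # traverse genes starting by entering extremity start_ext
    path <- integer(0)
    e <- start_ext
    repeat {
      gid <- gene_of[e]
      if (seen[gid]) return(list(genes = path, closed = TRUE))
      seen[gid] <<- TRUE
      path <- c(path, if (e %% 2L == 1L) gid else -gid)  # entered at tail => +
      out <- other_end(e)
      nxt <- partner[out]
      if (nxt == out) return(list(genes = path, closed = FALSE))  # telomere
      e <- nxt
    }
  }

  # linear chromosomes: start from telomeric extremities
  for (t in g$telomeres) {
    gid <- gene_of[t]
    if (seen[gid]) next
    res <- walk(t)
    chroms[[length(chroms) + 1L]] <- res$genes
    shapes <- c(shapes, "linear")
  }
  # remaining genes belong to circular chromosomes
  for (gid in seq_len(ngenes)) {
    if (seen[gid]) next
    res <- walk(2L * gid - 1L)
    chroms[[length(chroms) + 1L]] <- res$genes
    shapes <- c(shapes, "circular")
  }
  gene_order(chroms, shapes)
}

#' Read and write gene-order files
#'
#' GRIMM-style dialect: genome names on \code{>} lines, chromosomes as
#' whitespace-separated signed integers terminated by \code{$} (linear) or
#' \code{@} (circular); \code{#} starts a comment. A chromosome may span one
#' line; several chromosomes may share a line.
#'
#' @param path file path.
#' @return named list of \code{"gene_order"} objects.
#' @export
read_gene_orders <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  cur_name <- NULL
  cur_chroms <- list(); cur_shapes <- character(0)
  buffer <- integer(0)
  flush_genome <- function() {
    if (is.null(cur_name)) return()
    if (length(buffer)) stop("unterminated chromosome in genome '", cur_name, "'")
    if (length(cur_chroms) == 0L) stop("genome '", cur_name, "' has no chromosomes")
    out[[cur_name]] <<- gene_order(cur_chroms, cur_shapes)
  }
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush_genome()
      cur_name <- trimws(sub("^>", "", line))
      if (!nzchar(cur_name)) cur_name <- paste0("genome", length(out) + 1L)
      cur_chroms <- list(); cur_shapes <- character(0); buffer <- integer(0)
      next
    }
    if (is.null(cur_name)) {
      cur_name <- paste0("genome", length(out) + 1L)
      cur_chroms <- list(); cur_shapes <- character(0); buffer <- integer(0)
    }
    toks <- strsplit(line, "\\s+")[[1]]
    for (tk in toks) {
      if (tk == "$" || tk == "@") {
        if (length(buffer) == 0L) stop("line ", ln, ": empty chromosome")
        cur_chroms[[length(cur_chroms) + 1L]] <- buffer
        cur_shapes <- c(cur_shapes, if (tk == "$") "linear" else "circular")
        buffer <- integer(0)
      } else {
        v <- suppressWarnings(as.integer(tk))
        if (is.na(v)) stop("line ", ln, ": cannot parse token '", tk, "'")
        buffer <- c(buffer, v)
      }
    }
  }
  flush_genome()
  out
}

#' @param gene_orders named list of \code{"gene_order"} objects (a single
#'   object is wrapped).
#' @rdname read_gene_orders
#' @export
write_gene_orders <- function(gene_orders, path) {
  if (inherits(gene_orders, "gene_order")) gene_orders <- list(genome1 = gene_orders)
  if (is.null(names(gene_orders)) || any(!nzchar(names(gene_orders)))) {
    names(gene_orders) <- paste0("genome", seq_along(gene_orders))
  }
  lines <- character(0)
  for (nm in names(gene_orders)) {
    go <- gene_orders[[nm]]
    lines <- c(lines, paste0(">", nm))
    for (k in seq_along(go$chromosomes)) {
      term <- if (go$shapes[k] == "linear") "$" else "@"
      lines <- c(lines, paste(c(go$chromosomes[[k]], term), collapse = " "))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read one genome from a gene-order file as a genome on extremities
#' @param path gene-order file with at least one genome.
#' @param which index or name of the genome in the file.
#' @export
read_genome <- function(path, which = 1L) {
  gos <- read_gene_orders(path)
  gene_order_to_genome(gos[[which]])
}

#' Dense matrix TSV helpers
#'
#' Row-per-line, tab-separated decimal matrices used for general (orthogonal)
#' inputs and median outputs.
#'
#' @param path file path.
#' @rdname matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' @param M matrix to write.
#' @rdname matrix_tsv
#' @export
write_matrix_tsv <- function(M, path) {
  utils::write.table(M, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
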