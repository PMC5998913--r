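#' Apply one random DCJ operation to a genome
#'
#' Picks two distinct elements of the genome (adjacencies or telomeres)
#' uniformly and performs one uniformly chosen valid reassortment of their
#' extremities:
#' \itemize{
#'   \item two adjacencies \code{{a,b}, {c,d}}: replaced by \code{{a,c},{b,d}}
#'     or \code{{a,d},{b,c}} (a 2-break);
#'   \item an adjacency \code{{a,b}} and a telomere \code{{t}}: replaced by
#'     \code{{a,t}} + telomere \code{b}, or \code{{b,t}} + telomere \code{a}
#'     (single adjacency replacement);
#'   \item two telomeres: joined into one adjacency (creation).
#' }
#' Every outcome changes the genome; the DCJ distance moved is always 1 and
#' the rank distance moved is 1 (creation) or 2 (replacements).
#'
#' Uses the R RNG; seed with \code{set.seed()}.
#'
#' @param g a \code{"genome"} with at least two elements.
#' @return a \code{"genome"}.
#' @export
apply_random_dcj <- function(g) {
  stopifnot(is_genome(g))
  k <- nrow(g$adjacencies)
  t <- length(g$telomeres)
  if (k + t < 2L) stop("genome needs at least two elements (n >= 2)")
  picks <- sample.int(k + t, 2L)
  is_adj <- picks <= k
  adj <- g$adjacencies
  tel <- g$telomeres
  if (all(is_adj)) {
    e1 <- adj[picks[1], ]; e2 <- adj[picks[2], ]
    adj <- adj[-picks, , drop = FALSE]
    if (stats::runif(1) < 0.5) {
      adj <- rbind(adj, c(e1[1], e2[1]), c(e1[2], e2[2]))
    } else {
      adj <- rbind(adj, c(e1[1], e2[2]), c(e1[2], e2[1]))
    }
  } else if (!any(is_adj)) {
    t1 <- tel[picks[1] - k]; t2 <- tel[picks[2] - k]
    adj <- rbind(adj, c(t1, t2))
  } else {
    ai <- picks[is_adj]; ti <- tel[picks[!is_adj] - k]
    e <- adj[ai, ]
    adj <- adj[-ai, , drop = FALSE]
    if (stats::runif(1) < 0.5) {
      adj <- rbind(adj, c(e[1], ti))
    } else {
      adj <- rbind(adj, c(e[2], ti))
    }
  }
  genome(g$n, adj)
}

#' Cut circular chromosomes
#'
#' Removes one uniformly chosen adjacency from every circular chromosome, so
#' the result is an all-linear multi-chromosomal genome.
#'
#' @param g a \code{"genome"} on an even number of extremities.
#' @export
cut_circular_chromosomes <- function(g) {
  go <- genome_to_gene_order(g)
  if (!any(go$shapes == "circular")) return(g)
  adj <- g$adjacencies
  keys <- paste(adj[, 1], adj[, 2])
  for (k in which(go$shapes == "circular")) {
    # adjacencies of this chromosome, in the genome's extremity labels
    chr_adj <- gene_order_to_genome_raw(go$chromosomes[[k]], circular = TRUE)
    pick <- chr_adj[sample.int(nrow(chr_adj), 1L), ]
    keys <- setdiff(keys, paste(min(pick), max(pick)))
  }
  kept <- adj[paste(adj[, 1], adj[, 2]) %in% keys, , drop = FALSE]
  genome(g$n, kept)
}

# adjacency rows of one chromosome given as a signed gene vector, using the
# global extremity labels 2g-1 / 2g
gene_order_to_genome_raw <- function(chr, circular = FALSE) {
  tails <- 2L * abs(chr) - 1L
  heads <- 2L * abs(chr)
  inc <- ifelse(chr > 0L, tails, heads)
  out <- ifelse(chr > 0L, heads, tails)
  m <- length(chr)
  rows <- if (m > 1L) cbind(out[-m], inc[-1L]) else matrix(integer(0), 0, 2)
  if (circular) rows <- rbind(rows, c(out[m], inc[1L]))
  rows
}

#' Simulate a median instance by the DCJ protocol
#'
#' Starts from a unichromosomal linear ancestor with \code{genes} genes in
#' identity order and derives each of three genomes independently by
#' \code{k ~ Uniform{ceil(r n / 2), ..., floor(3 r n / 2)}} random DCJ
#' operations (\code{n = 2 * genes} extremities), then cuts every circular
#' chromosome, so the outputs are multi-chromosomal linear genomes with
#' identical gene content.
#'
#' @param genes number of genes (>= 2).
#' @param r rearrangement rate in (0, 1); \code{r = 0} returns three copies
#'   of the ancestor.
#' @return list of three \code{"genome"} objects plus the ancestor.
#' @export
simulate_instance <- function(genes, r) {
  if (genes < 2L) stop("genes must be >= 2")
  n <- 2L * genes
  ancestor <- gene_order_to_genome(gene_order(list(seq_len(genes)), "linear"))
  lo <- as.integer(ceiling(r * n / 2)); hi <- as.integer(floor(3 * r * n / 2))
  out <- lapply(1:3, function(dummy) {
    k <- if (hi <= lo) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
    g <- ancestor
    if (k > 0L) for (step in seq_len(k)) g <- apply_random_dcj(g)
    cut_circular_chromosomes(g)
  })
  names(out) <- c("g1", "g2", "g3")
  out$ancestor <- ancestor
  out
}

#' Uniform random involution
#'
#' Samples uniformly among all involutions on \code{1..n} (products of
#' disjoint transpositions and fixed points) via the recurrence
#' \code{I(n) = I(n-1) + (n-1) I(n-2)}, carried in ratio form to avoid
#' overflow. With \code{fixed_point_free = TRUE}, a uniform perfect matching
#' is drawn instead (requires even \code{n}).
#'
#' @param n ground-set size.
#' @param fixed_point_free require no fixed points.
#' @return a \code{"perm"} equal to its own inverse.
#' @export
random_involution <- function(n, fixed_point_free = FALSE) {
  n <- as.integer(n)
  if (fixed_point_free && n %% 2L == 1L) {
    stop("fixed-point-free involutions need even n")
  }
  p <- integer(n)
  avail <- seq_len(n)
  if (fixed_point_free) {
    while (length(avail) > 0L) {
      i <- avail[1]
      j <- if (length(avail) == 2L) avail[2] else sample(avail[-1], 1L)
      p[i] <- j; p[j] <- i
      avail <- setdiff(avail, c(i, j))
    }
    return(as_perm(p))
  }
  # ratios r_m = I(m-1) / I(m); 1/r_m = 1 + (m-1) r_{m-1}
  ratios <- numeric(n)
  ratios[1] <- 1
  if (n > 1L) for (m in 2:n) ratios[m] <- 1 / (1 + (m - 1) * ratios[m - 1])
  while (length(avail) > 0L) {
    m <- length(avail)
    i <- avail[m]
    if (m == 1L || stats::runif(1) < ratios[m]) {
      p[i] <- i
      avail <- avail[-m]
    } else {
      j <- if (m == 2L) avail[1] else sample(avail[-m], 1L)
      p[i] <- j; p[j] <- i
      avail <- setdiff(avail, c(i, j))
    }
  }
  as_perm(p)
}

#' Default simulation grid
#'
#' The standard grid: extremity counts \code{n} in 12, 16, 20, 30, 50, 100,
#' 200, 300, 500 (6 to 250 genes), rates 0.05 to 0.3 in steps of 0.05, and
#' 10 replicates per cell -- 540 instances.
#'
#' @param n extremity counts (must be even).
#' @param r rearrangement rates.
#' @param replicates replicates per (n, r) cell.
#' @export
simulation_grid <- function(n = c(12, 16, 20, 30, 50, 100, 200, 300, 500),
                            r = seq(0.05, 0.3, by = 0.05),
                            replicates = 10L) {
  stopifnot(all(n %% 2 == 0))
  list(n = as.integer(n), r = r, replicates = as.integer(replicates))
}

#' Fraction of simulated instances in the deficiency-zero case
#'
#' Regenerates the simulation grid and computes \code{delta} for every
#' instance; reports the overall fraction with \code{delta == 0} and the
#' per-cell table.
#'
#' @param grid a \code{\link{simulation_grid}}.
#' @param seed optional integer seed.
#' @return list with \code{fraction} (in [0, 1]), \code{instances}, and
#'   \code{table}: a data.frame with one row per (n, r) cell.
#' @export
experiment_delta_fraction <- function(grid = simulation_grid(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  total <- 0L; zero <- 0L
  for (nn in grid$n) {
    for (rr in grid$r) {
      z <- 0L
      for (rep in seq_len(grid$replicates)) {
        inst <- simulate_instance(nn %/% 2L, rr)
        d <- delta_invariant(genome_to_involution(inst$g1),
                             genome_to_involution(inst$g2),
                             genome_to_involution(inst$g3))
        if (d == 0L) z <- z + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        n = nn, r = rr, replicates = grid$replicates, delta_zero = z)
      total <- total + grid$replicates
      zero <- zero + z
    }
  }
  list(fraction = zero / total, instances = total,
       table = do.call(rbind, rows))
}

#' DCJ vs rank distance regression
#'
#' For every gene count from 2 to \code{max_genes}, compares a "standard"
#' genome (identity-ordered single linear chromosome) to a uniformly random
#' single-chromosome linear genome on the same genes, and fits an ordinary
#' least-squares line of the DCJ distance against the rank distance. For
#' random linear genomes the slope is statistically indistinguishable from
#' 1/2 with r-squared near 1.
#'
#' @param max_genes largest gene count.
#' @param seed optional integer seed.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared} and the
#'   point table.
#' @export
experiment_dcj_vs_rank <- function(max_genes = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- 2:max_genes
  pts <- lapply(genes, function(G) {
    std <- gene_order_to_genome(gene_order(list(seq_len(G)), "linear"))
    perm <- sample.int(G)
    signs <- sample(c(-1L, 1L), G, replace = TRUE)
    rnd <- gene_order_to_genome(gene_order(list(perm * signs), "linear"))
    data.frame(genes = G,
               rank = rank_distance(std, rnd),
               dcj = dcj_distance(std, rnd))
  })
  pts <- do.call(rbind, pts)
  fit <- stats::lm(dcj ~ rank, data = pts)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       points = pts)
}
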