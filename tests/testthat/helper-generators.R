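# random objects used across the suite (callers set the seed)

random_permutation <- function(n) as_perm(sample.int(n))

random_genome <- function(n) involution_to_genome(random_involution(n))

random_orthogonal <- function(n) qr.Q(qr(matrix(stats::rnorm(n * n), n)))

# all involutions on 1..n, as image vectors
all_involutions <- function(n) {
  out <- list()
  grow <- function(p, avail) {
    if (length(avail) == 0L) {
      out[[length(out) + 1L]] <<- p
      return(invisible())
    }
    i <- avail[1]
    grow(p, avail[-1])                       # i is a fixed point
    for (j in avail[-1]) {                   # i paired with j
      q <- p; q[i] <- j; q[j] <- i
      grow(q, setdiff(avail, c(i, j)))
    }
  }
  grow(seq_len(n), seq_len(n))
  out
}

# keep drawing simulated instances until one with delta == 0 appears
random_delta0_involutions <- function(genes, r = 0.1, max_tries = 200) {
  for (i in seq_len(max_tries)) {
    inst <- simulate_instance(genes, r)
    ps <- lapply(inst[1:3], genome_to_involution)
    if (delta_invariant(ps[[1]], ps[[2]], ps[[3]]) == 0L) return(ps)
  }
  stop("no delta=0 instance found")
}

# delta=0 triples of general (non-involution) permutations, by rejection
random_delta0_perms <- function(n, max_tries = 5000) {
  for (i in seq_len(max_tries)) {
    ps <- lapply(1:3, function(k) sample.int(n))
    if (delta_invariant(ps[[1]], ps[[2]], ps[[3]]) == 0L) return(ps)
  }
  stop("no delta=0 permutation triple found")
}

klein_fixture_path <- function() {
  testthat::test_path("fixtures", "klein.txt")
}

# independent rank oracle (LAPACK QR with column pivoting)
numeric_rank_oracle <- function(X, tol = 1e-9) {
  if (max(abs(X)) == 0) return(0L)
  sum(abs(diag(qr(X, LAPACK = TRUE)$qr)) > tol)
}

# union-find membership for edges {p[i], q[i]} over 1..n
pair_membership <- function(p, q) {
  n <- length(p)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n)) {
    a <- find(p[i]); b <- find(q[i])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

# membership for an arbitrary edge list over 1..n
edge_membership <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1]); b <- find(edges[k, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}
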