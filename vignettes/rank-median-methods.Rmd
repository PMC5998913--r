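---
title: "Rank-distance medians of three genomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-distance medians of three genomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankmedian)
```

## The model

A genome with gene content fixed is described by how consecutive syntenic
regions are joined. Each gene `g` contributes two *extremities* (tail
`2g - 1`, head `2g`); an *adjacency* is an unordered pair of extremities
joined in the genome and a *telomere* is an extremity at a chromosome end.
A genome is therefore a perfect partition of `1..n` into pairs and
singletons — equivalently an involution, or a symmetric permutation matrix
`M` with `M[i, j] = 1` for adjacencies and `M[i, i] = 1` for telomeres.

The *rank distance* between two matrices is `d(A, B) = rank(A - B)`. For
permutation matrices it coincides with the Cayley (minimum-transposition)
distance, and for genomic matrices it equals the minimum total weight of a
rearrangement scenario in which adjacency creations/destructions cost 1 and
single or double adjacency replacements (including inversions,
translocations and other 2-breaks) cost 2. On the breakpoint graph of two
genomes — the multigraph whose edges are the two adjacency sets — all four
distances handled here have closed forms in the edge count `m`, cycle count
`c`, 2-cycle count `c2` and odd-path count `p_odd`:

* rank: `m - 2c` (ranks of matrix differences, computed combinatorially),
* SCJ: `m - 2*c2` (symmetric difference of adjacency sets),
* DCJ: `m/2 - c + p_odd/2`,
* algebraic: half the rank distance.

Extremities telomeric in both genomes are zero-edge components and count
toward nothing; this convention is what makes `m - 2c` equal the matrix
rank, and is pinned by an exhaustive small-`n` sweep against a numerical
rank oracle in the tests.

## The median problem and its invariants

The median of three matrices minimizes the score
`d(A, M) + d(B, M) + d(C, M)`. The triangle inequality gives the universal
lower bound `beta = (d(A,B) + d(B,C) + d(C,A)) / 2`. Two further
invariants complete the picture:

* `alpha`, the dimension of the triple-agreement subspace
  `{x : Ax = Bx = Cx}`. For permutations it is the number of connected
  components of the union graph with edges `{rho(i), sigma(i)}` and
  `{sigma(i), tau(i)}` — an O(n) computation.
* `delta = alpha + beta - n`, the *deficiency*, a non-negative integer for
  permutation (hence genomic) inputs.

`R^n` splits into a direct sum `V1 .. V5` of agreement subspaces with
`dim V5 = 2 delta`. The classical candidates `M_A, M_B, M_C` take the
agreed value on `V1..V4` and act as the respective input on `V5`; each
scores exactly `beta + delta`. One subtlety is easy to get wrong: the
decomposition is direct but **not** orthogonal — `V2, V3, V4` are each
orthogonal to `V1` but not to one another — so `M_A` is assembled with the
projector onto `V3` *along* the other four subspaces (an oblique
projector), not the orthogonal one. Using the orthogonal projector yields a
matrix that misses `beta + delta`; the per-pick distance identities
`d(A, M_A) = dim V3`, `d(B, M_A) = dim V4 + dim V5`,
`d(C, M_A) = dim V2 + dim V5` are asserted in the test suite and pin the
construction.

## The difference-variable system and the deficiency-zero solver

Any matrix attaining `beta` must satisfy
`M = A + S(B-A) = B + T(C-B) = C + U(A-C)` for some `S, T, U`. Writing the
columns of `S(B-A)` in *difference variables* — the columns belonging to
one cycle of the pairwise permutation sum to zero, so the column at the
cycle's highest element is eliminated as the negated sum of the others —
and dropping one redundant equation per union-graph component (again at the
highest element) leaves `2(n - alpha)` equations in `2 beta` unknowns with
coefficients in `{-1, 0, 1}`. The left-hand side is shared by all `n` rows
of `M`, so it is factorized once (sparse LU from the Matrix package) and
solved against `n` right-hand sides.

When `delta = 0` the system is square and nonsingular: the median is
*unique*, equals `M_A`, and scores exactly `beta`. An exact rational
Gaussian elimination (numerators and denominators carried as reduced
integer pairs) is available via `solve_special_case(..., exact = TRUE)` for
bit-reproducible small fractions such as ±1/2 and ±1/3; the float path is
the default and is what the scale tests exercise.

A note on conventions: with the matrix convention `M[i, rho(i)] = 1`
(so `Mx = x[rho]`), the `i`-th column of `SA` is `s[rho^-1(i)]`. The
difference-variable bookkeeping is therefore built on the inverse
permutations; for involutions — all genomic inputs, and all the worked
examples — the two readings coincide, and the convention is pinned by the
printed first-row solution of the Klein-group system
(`s'1 = s'2 = t'1 = t'2 = u'1 = -1/2, u'2 = +1/2`), which the tests
reproduce.

## The compressed-sensing heuristic

For `delta > 0` the system is under-constrained, and we look for sparse
solutions by per-row L1 minimization: `min sum |x_i|` subject to
`Lx = b_j`, the standard surrogate for the (hard) sparsest-solution
problem. Each row's program is solved as a linear program on the split
`x = u - v, u, v >= 0` with `boot::simplex`; rows with equal right-hand
sides share one solve. L1 solutions are not unique, so tests only ever
assert objective values and scores, never argmins. The heuristic can be
suboptimal — on the triple `(12), (13), (23)` it returns a binary
non-permutation matrix of score 6 against the bound `beta = 3` — which is
why `rank_median(method = "auto")` falls back to the exact orthogonal walk
whenever the heuristic's score exceeds `beta`. The pure-R simplex is
adequate for the worked examples and test sizes (tens of variables); very
large deficient instances are better served by the orthogonal walk, which
is exact anyway.

## The orthogonal median walk

For orthogonal inputs (permutations and genomes included) a median
attaining `beta` always exists and is found by "walking towards the
median": while `B` is not on a geodesic between `A` and `C`
(`d(A,B) + d(B,C) > d(A,C)`), pick any non-zero
`u` in `im(A-B) ∩ im(C-B)` and replace `B` by `B + H` with
`H = -2uu'B/u'u`, an orthogonal reflection at rank distance 1 from `B`
that moves one unit closer to both `A` and `C`. The walk terminates after
exactly `(d(A,B) + d(B,C) - d(A,C))/2` steps.

Implementation choices:

* The intersection is computed by the nullspace-of-stacked-nullspaces
  formula; if that returns dimension 0 while betweenness fails (a known
  numerical failure mode) the fallback
  `Orth((A-B) Null([A-B C-B])[1:n, ])` is used.
* `u` is the first basis column — any non-zero choice is valid.
* Rank decisions use an absolute tolerance of 1e-6 (1e-12 for scoring);
  QR-based rank estimates proved unreliable on the exact low-rank
  differences arising here, so ranks come from singular values.
* When all three inputs are permutation matrices, a transposition `(i, j)`
  lying in one cycle of each pairwise quotient performs the step in O(n)
  and keeps every iterate a permutation. Such a pair need not exist before
  betweenness is reached (the Klein four-group triple is the canonical
  case: its unique median is fractional, so no transposition path can end
  at it); the walk then switches to the generic rank-1 step.
* Orthogonality of the iterate is monitored; drift beyond 1e-3 triggers an
  SVD re-orthonormalization (an engineering safeguard that the tests never
  trip at the sizes used).

## Genome projection of non-genomic medians

Medians of genomic inputs are often genomic but need not even be binary;
the walk's output is always orthogonal, so each row of the entrywise
square `M ∘ M` is a probability distribution over potential partners of
that extremity. `sample_genome()` visits rows in random order and draws a
partner among the still-unassigned extremities (renormalized; uniform
fallback when the available mass is zero; the diagonal means "telomere").
An optional flag additionally zeroes probabilities at negative entries of
`M`, which on the Klein median `J/2 - I` suppresses the score-6 and
score-7 outcomes and always recovers one of the three inputs (score 4).
Row order and conflict resolution are not dictated by any published
procedure; the random-order/renormalize choice is this package's, made
once and seedable.

## The simulator and the experiments

`simulate_instance()` follows the published protocol: a unichromosomal
linear ancestor with `n/2` genes in identity order; each of the three
genomes derived by `k ~ Uniform{ceil(rn/2) .. floor(3rn/2)}` random DCJ
operations; circular chromosomes cut at one uniformly chosen adjacency at
the end. The DCJ primitive picks two distinct elements (adjacencies or
telomeres) uniformly and applies a uniformly chosen changing reassortment:
2-break, single replacement, or fusion of two telomeres; every outcome has
DCJ distance 1 and rank distance 1 or 2 from its predecessor. The default
grid is `n ∈ {12, 16, 20, 30, 50, 100, 200, 300, 500}`,
`r ∈ {0.05, ..., 0.3}`, 10 replicates — 540 instances, each checked in the
tests for `beta` integrality and `delta >= 0`.

Two experiment drivers are included. `experiment_dcj_vs_rank()` compares an
identity-ordered linear genome against a uniformly random signed linear
genome for every gene count up to 1000 and fits DCJ against rank distance
by ordinary least squares; the slope is 0.500 and `r²` exceeds 0.999,
confirming that the two distances are practically interchangeable up to the
factor 2. `experiment_delta_fraction()` regenerates the grid and reports
the fraction of deficiency-zero instances.

**A caution on the deficiency-zero fraction.** Under the protocol exactly
as stated above, the grid's `delta = 0` fraction computes to about 34%,
not the published 87.5%. The discrepancy is structural, not statistical:
`delta > 0` sets in once breakpoint density saturates (at `n = 500`,
roughly beyond 40 operations per lineage), and the stated mean of `rn`
operations per lineage reaches 150 at the top of the grid, where the three
genomes are close to independent random involutions — a regime in which
the deficiency-zero case provably becomes vanishingly rare. We verified
that this conclusion is robust to every unspecified detail (operation mix,
inversion-only simulation, star versus chain topology, cutting
conventions) and validated the invariant computations against numerical
nullspace oracles. The simulator therefore implements the protocol as
written and reports the fraction it actually produces; reproducing the
published figure would require several-fold fewer operations than the
protocol states.

## Problem sizes used by the tests

The suite exercises: exhaustive involution sweeps up to `n = 6` plus
seeded sampling to `n = 10` (distance oracle agreement); random triples to
`n = 50` for nullspace oracles; the deficiency-zero solver to 100 genes
(`n = 200`); the orthogonal walk to `n = 300` for permutations and
`n = 50` for dense orthogonal inputs; and the full 540-instance grid for
the two experiments. These sizes keep the default run inside a few minutes
while covering every code path; all generators are seeded, so runs are
reproducible.

## Known limitations

* The L1 subproblems use a dense pure-R simplex; the compressed-sensing
  path is not intended for `n` in the hundreds (use the orthogonal walk
  there).
* The simulator emulates content-preserving rearrangements only — no
  duplications, insertions or losses — and its uniform-DCJ choice is one of
  several defensible readings of "random DCJ operations"; passing tests
  say nothing about distance saturation corrections on real, highly
  diverged genomes.
* `sample_genome()` is a sampling heuristic, not an optimal genomic
  projection; the optimal projection is an open problem.
* Exact rational solving is limited to systems whose intermediate values
  stay below 2^53; that covers the test sizes comfortably but is not
  arbitrary-precision arithmetic.
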