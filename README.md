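# rankmedian

Medians of three genomes (and of three permutations or orthogonal matrices)
under the **rank distance**, for ancestral genome reconstruction and small
phylogeny problems.

A genome with fixed gene content is encoded by its adjacencies: gene *g*
contributes a tail extremity 2*g*−1 and a head 2*g*, and the genome is a
perfect partition of the *n* extremities into adjacency pairs and telomere
singletons — equivalently a symmetric permutation matrix *M*. The rank
distance *d*(*A*, *B*) = rank(*A* − *B*) equals the minimum total weight of
a rearrangement scenario where adjacency creations and destructions cost 1
and single/double adjacency replacements (inversions, translocations,
2-breaks) cost 2. Unlike the DCJ distance, whose median-of-three problem is
NP-hard, rank medians are computable in polynomial time, and this package
implements that machinery:

* **Distances** — rank, SCJ, DCJ and algebraic distances from the
  breakpoint graph (`rank_distance()`, `scj_distance()`, `dcj_distance()`,
  `algebraic_distance()`), plus numerical `rank_distance_matrix()` for
  general inputs.
* **Invariants** — `alpha_invariant()` (triple-agreement dimension),
  `beta_invariant()` (the universal score lower bound
  β = ½[d(A,B)+d(B,C)+d(C,A)]) and the deficiency
  δ = α + β − n, all in O(n); the five-subspace dimensions
  (`subspace_dims()`) and the projection candidates `M_A, M_B, M_C`
  (`candidate_median()`), each scoring exactly β + δ.
* **Exact δ = 0 solver** — `solve_special_case()` builds the reduced
  difference-variable system (2(n−α) equations, 2β unknowns, one shared
  factorization for all n rows) and returns the *unique* median, scoring
  exactly β; an exact-rational mode reproduces fractional entries such as
  ±1/2, ±1/3 bit for bit.
* **Compressed-sensing heuristic** — `compressed_sensing_median()` finds
  per-row minimum-L1 solutions of the under-constrained system by linear
  programming when δ > 0.
* **Exact orthogonal median** — `orthogonal_median()` walks an input
  toward the other two by orthogonal rank-1 reflections
  (H = −2uu′B/u′u, u ∈ im(A−B) ∩ im(C−B)), with an O(n) transposition
  fast path for permutation inputs; the result always attains β.
* **Genome projection** — `classify_matrix()` (genomic / permutation /
  binary / integer-with-negatives / fractional) and `sample_genome()`,
  which reads the squared entries of an orthogonal median as adjacency
  probabilities and samples a proper genome.
* **Simulation** — `simulate_instance()` (DCJ rearrangement protocol from
  a linear ancestor), `random_involution()`, and the experiment drivers
  `experiment_delta_fraction()` and `experiment_dcj_vs_rank()`.
* **I/O and CLI** — GRIMM-style gene-order files (`read_gene_orders()`),
  one-line permutations, dense matrix TSV, and a command-line front end
  (`inst/cli/rankmedian`) with `distance`, `invariants`, `median`,
  `sample-genome`, `simulate` and `experiment` subcommands.

## A worked example

The Klein four-group triple — the genomes with adjacencies
{1,2},{3,4} / {1,3},{2,4} / {1,4},{2,3} — is the textbook case of a
deficiency-zero instance whose unique median is not a genome:

```r
library(rankmedian)
ex <- median_example("klein")
median_invariants(ex$perms[[1]], ex$perms[[2]], ex$perms[[3]])[c("alpha", "beta", "delta")]
#> $alpha
#> [1] 1
#> $beta
#> [1] 3
#> $delta
#> [1] 0

res <- rank_median(ex$perms[[1]], ex$perms[[2]], ex$perms[[3]], method = "auto")
res
#> rank-distance median (exact-special)
#>   n = 4, score = 3, beta = 3, gap = 0, delta = 0
#>   classification: fractional
res$matrix
#>      [,1] [,2] [,3] [,4]
#> [1,] -0.5  0.5  0.5  0.5
#> [2,]  0.5 -0.5  0.5  0.5
#> [3,]  0.5  0.5 -0.5  0.5
#> [4,]  0.5  0.5  0.5 -0.5
```

δ = 0, so the solver returns the unique median J/2 − I: it attains the
lower bound β = 3, beating every genome (the inputs themselves score 4),
at the price of being fractional. Because the median is orthogonal, its
squared entries form adjacency probabilities, and a genome can be sampled
from it:

```r
set.seed(42)
sample_genome(res$matrix)
#> genome on n = 4 extremities
#>   adjacencies: {1,4} {2,3}
#>   telomeres:   (none)
```

— here one of the three inputs, a best-scoring genome. The same analysis
runs from the shell on gene-order files:

```sh
inst/cli/rankmedian median --method auto inst/extdata/klein.txt
# {"method": "exact-special", "score": 3, "beta": 3, "delta": 0, "gap": 0, "classification": "fractional"}
```

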