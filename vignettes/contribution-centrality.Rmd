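---
title: "Contribution centrality: dissimilarity-weighted eigencentrality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contribution centrality: dissimilarity-weighted eigencentrality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(contricent)
```

## The model

Eigenvector centrality scores a node by the summed scores of its
neighbours: `c = (1/lambda) A c`, so `c` is the dominant (Perron)
eigenvector of the adjacency matrix `A`.  Its weakness is the implicit
assumption that every neighbour contributes equally.  A neighbour whose
neighbourhood almost coincides with mine tells the network little it did
not already know through me; a neighbour that bridges to regions I
cannot otherwise reach is structurally essential.

Contribution centrality repairs this by weighting each neighbour's score
with a structural dissimilarity between the two endpoints' neighbourhoods:

```
c_i = (1/lambda) * sum_j  A_ij * d_ij * c_j      =>      W c = lambda c,
W = A o D  (entrywise product)
```

where `d_ij` is, by default, the Jaccard dissimilarity

```
d_ij = 1 - |eta(i) n eta(j)| / |eta(i) u eta(j)|
```

between the neighbourhoods `eta(i)`, `eta(j)`.  Since `A` and `D` are
nonnegative, so is `W`, and the Perron-Frobenius theorem guarantees a
nonnegative dominant eigenvector: the score vector.  The method has no
tunable parameter.  When `W` is irreducible the Perron vector is unique
and strictly positive; reducibility (possible when some edge has
`d_ij = 0`) is detected and reported by `check_irreducibility()` and as
a warning from `contribution_centrality()`.

Two useful consequences of the definition:

* **Triangle-free collapse.**  If the graph has no triangles, adjacent
  nodes share no neighbours, every edge has `d_ij = 1` under the open
  convention, `W = A`, and the method coincides with plain eigenvector
  centrality.  The test-suite verifies this exhaustively over every
  labelled connected graph on up to 6 nodes.
* **Scale invariance.**  Multiplying all dissimilarities by `k > 0`
  scales `lambda` by `k` and leaves the scores untouched, so rankings do
  not depend on the overall scale of the measure.

## The neighbourhood convention

The Jaccard definition leaves one genuine design choice open: whether a
node belongs to its own neighbourhood.  Both readings are defensible and
both are implemented (`convention = "closed"` / `"open"`):

* **open** -- `eta(i)` is the set of neighbours of `i`.  For adjacent
  `i ~ j` the sets can never be identical (each contains the other but
  not itself), so no edge of `W` is ever dropped.
* **closed** -- `eta(i)` additionally contains `i`.  Adjacent nodes with
  identical closed neighbourhoods (mutually adjacent "twins" with the
  same outside contacts) get `d_ij = 0` and their edge drops out of `W`,
  which can make `W` sparser than `A`.

The package defaults to **closed**.  Two observations drove this choice.
First, only the closed convention can zero out an edge between nodes
with exactly the same neighbourhood, which is precisely the behaviour
the method advertises (a neighbour that duplicates your neighbourhood
contributes nothing).  Second, on the three bundled benchmark networks
the closed convention reproduces the canonical rankings exactly -- the
karate club's leadership triple 34, 33, 1 in that order, and the full
published top-10 of the Les Miserables coappearance network -- while the
open convention swaps two adjacent pairs (33/1 and
Fantine/MmeThenardier).  The acceptance tests compute both conventions
side by side.

A degenerate corner follows from the closed convention: on a complete
graph all closed neighbourhoods coincide, `W` is the zero matrix, and no
dominant eigenvector exists; the package raises a "degenerate weight
matrix" error rather than inventing scores.  Isolated node pairs under
the open convention (empty unions) are defined to have `d = 0` with a
warning; such pairs are never adjacent, so they cannot enter `W`.

For weighted networks the Tanimoto dissimilarity
`1 - (ri . rj)/(|ri|^2 + |rj|^2 - ri . rj)` on adjacency rows replaces
Jaccard (`measure = "tanimoto"`); on 0/1 rows it reduces to open-Jaccard
exactly.  Edge weights must be positive -- nonnegativity of `W` is the
one hard precondition of the method -- and this is enforced at graph
construction.  Custom measures plug in through `register_measure()`;
their outputs are range-checked into `[0, 1]` per pair, and an
out-of-range value is an error naming the pair, never a silent clamp.

## Numerical choices

`dominant_eigenpair()` uses power iteration with a fixed uniform
positive start vector (`1/sqrt(N)` in every coordinate): the Perron
vector is reachable from any positive start, and a deterministic start
makes results bit-reproducible with no random seed in the main path.
Plain power iteration fails to converge on bipartite-type spectra where
`-lambda_max` is also an eigenvalue, so the iteration runs on the
shifted matrix `M + sigma I` with `sigma` set to a quarter of the
largest row sum -- large enough to break the `+/-lambda` tie for any
nonnegative `M`, small enough not to slow convergence materially.  The
eigenvalue is reported as the Rayleigh quotient of the *unshifted*
matrix, and convergence is declared when the relative residual
`||Mv - lambda v|| / lambda` drops below `tol` (default `1e-10`, cap
`max_iter = 10000`; exceeding the cap is an error carrying the
diagnostics).  The converged vector's sign is fixed so its largest
entry is positive; entries below zero by more than `tol` are an error,
smaller negatives are rounding noise and are clamped to zero before a
final renormalisation.  Scores are normalised to unit Euclidean length
-- rankings are invariant to the normalisation, which is chosen purely
for comparability.

Disconnected graphs are scored per connected component with a warning
(mirroring the standard per-component convention of closeness
centrality); scores are then comparable only within a component, and
singleton components score zero.  Rankings break score ties by node
label, numeric-aware when all labels are integers, so output order is
reproducible.

Sparse evaluation: `d_ij` is only ever needed where `A_ij > 0`, so
`dissimilarity_matrix()` evaluates adjacent pairs only by default and
`W` is assembled as a sparse matrix; a dense all-pairs mode exists for
diagnostics, and `write_matrix_market()` exports either matrix.

## Baseline measures

The six comparison measures follow their standard definitions on
unweighted topology: degree (raw counts); eigenvector centrality (the
same solver applied to `A`); betweenness (unnormalised, endpoints
excluded, unordered pairs -- Brandes' algorithm via igraph,
cross-checked in the tests against the package's own explicit
shortest-path census); closeness (`(N_c - 1)/sum d`, per component);
information centrality in the Stephenson-Zelen matrix form
(`C = (L + J)^{-1}`, `I_ij = 1/(C_ii + C_jj - 2 C_ij)`, score = harmonic
mean over partners, the self term excluded as infinitely informative);
and communicability/subgraph centrality (`(e^A)_ii` via symmetric
eigendecomposition, cross-checked against a 30-term walk series).  The
information measure's prose definition in terms of combined paths and
shared links is realised by the matrix formulation, its standard
tractable equivalent.

## The synthetic generator and what the tests do not show

`sample_ba()` grows preferential-attachment (Barabasi-Albert) graphs:
from `m` isolated seed nodes, each arriving node attaches to `m`
distinct existing nodes with probability proportional to degree (the
first arrival attaches to all seed nodes), giving exactly `m(n - m)`
edges, a connected graph, and a heavy-tailed degree distribution.  These
graphs drive the runtime study (`runtime_benchmark()`, CLI `bench`) with
the generator's canonical parameter `m = 2`.  The scaling check in the
test-suite uses sizes 100 / 1,000 / 10,000 with 3 repetitions, which
completes in seconds while still spanning two orders of magnitude;
timings are reported but never asserted, being hardware-dependent.

Synthetic scale-free graphs exercise sparsity and degree heterogeneity,
but they are unweighted, unclustered relative to real social networks,
and have no community structure; passing the property suite on them
shows numerical correctness of the pipeline, not that contribution
centrality is the right measure for any particular real system.  The
substantive evidence on real data is limited to the three bundled
benchmark networks, whose "correct" rankings are themselves historical
judgements (club leadership, the Medici's brokerage position, narrative
importance of characters).

## Known limitations

* Directed networks are out of scope: `W` would be asymmetric and the
  Perron-Frobenius uniqueness argument needs an irreducibility analysis
  the method does not supply.
* Only rankings of the benchmark networks are treated as reproducible
  reference results; absolute score values depend on the normalisation.
* Betweenness is exact (no sampling) and therefore quadratic-plus in
  network size; it is meant for the benchmark-scale networks, not for
  the `10^5`-node graphs the spectral method itself handles easily.

## A worked example

```{r example}
karate <- load_fixture("karate")
res <- contribution_centrality(karate)
glance(res)
head(tidy(res), 5)
```

```{r compare}
cmp <- compare_centralities(karate, methods = c("contribution",
                                                "eigenvector", "degree"),
                            top = 5)
cmp$top
```

```{r plot, fig.width = 6, fig.height = 4}
autoplot(res, top = 10)
```
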