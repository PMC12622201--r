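---
title: "Persistent Stanley-Reisner invariants for protein mutation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistent Stanley-Reisner invariants for protein mutation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psrt)
```

## The model

A simplicial complex $\Delta$ on a vertex set corresponds, through its
Stanley-Reisner ring, to an intersection of prime monomial ideals
$P_\sigma$, one per *facet* $\sigma$ (a maximal simplex).  When the complex
is filtered — simplices enter as a scale parameter $t$ grows — each simplex
$\sigma$ has a well-defined interval during which it is a facet:

* **birth**: the filtration value at which $\sigma$ itself appears;
* **death**: the smallest filtration value of any cofacet
  $\tau \supset \sigma$ with $\dim\tau = \dim\sigma + 1$, because the
  moment a cofacet exists, $\sigma$ stops being maximal.

Collecting the intervals $[b_\sigma, d_\sigma)$ by dimension gives the
*facet persistence barcode*.  Unlike persistent homology, which reports
global cycles, facet persistence is sensitive to local maximality: a pair
of atoms at hydrogen-bond distance shows up directly as two dimension-0
bars dying at the bond length while a dimension-1 bar is born there.

Alongside the barcode we track the *f-vector curve*
$f(\Delta_t) = (f_{-1}^t, f_0^t, \dots, f_{d-1}^t)$, where $f_i^t$ counts
the $i$-dimensional faces present at scale $t$ and $f_{-1}^t = 1$ for the
empty face.  The `h_vector()` transform
$h_j = \sum_{i=0}^{j} (-1)^{j-i}\binom{d-i}{j-i} f_{i-1}$ is provided for
completeness; the identity $\sum_j h_j = f_{d-1}$ is checked numerically in
the test suite.  f-vector curves scale to clouds where enumerating facets
is impractical (hundreds of atoms produce $10^6$–$10^7$ triangles and
tetrahedra near 12 Å), at the cost of losing interval information.

## Filtrations and conventions

Two filtered complexes are supported.

* **Vietoris-Rips** (`rips_filtration()`): a simplex enters when all its
  pairwise distances are `<= t`.  The filtration parameter is the **edge
  length (diameter)**, not the radius; every narrated barcode event on the
  toy motifs (hexagon edges at 2, cuboid edges at 1) is an edge length, so
  both fixtures and features use the same convention.
* **Alpha** (`alpha_filtration()`): the subcomplex of the Delaunay
  triangulation filtered by circumscribing-ball **radius** in Å, so both
  complexes live on one Å-valued grid.  Vertices appear at 0.

Bars that survive to the ceiling `f_max` are reported with
`death = f_max` and `open = TRUE`; plots and grid counts treat them as
alive through the ceiling.  Bars with persistence at most
`1e-9 * f_max` are dropped — this is the exact-arithmetic statement
"exclude bars of persistence zero" made robust under floating point.  The
same `1e-9` relative tolerance is used wherever filtration values are
compared for simultaneity.

Vertex indices are 1-based throughout, including serialized output; this
package follows R indexing rather than keeping a separate 0-based internal
convention, so a vertex id can always be used directly to subset the input
cloud.

## Site-specific, element-specific protein features

For a point mutation, atoms of the mutated residue form the **site set**
and heavy atoms of all other residues within a cutoff `r` (default
**16 Å**) of any site atom form the **neighborhood set**.  The *modified
Euclidean distance* makes within-set distances infinite:

$$D_{mod}(a_i, a_j) = \begin{cases} \infty & a_i, a_j \text{ both site or
both neighborhood} \\ D_E(a_i, a_j) & \text{otherwise,} \end{cases}$$

so Rips complexes under $D_{mod}$ are bipartite: only site-neighborhood
interactions create edges, no simplex of dimension 2 or higher can ever
form, and every dimension-1 facet bar survives to the ceiling.  These
corollaries are asserted as properties in the test suite.

Atoms are further restricted to the elements C, N and O (S and Se are
excluded), giving nine ordered (site element, neighborhood element) pairs:
C–C interactions track hydrophobic contacts, N–O and O–N track hydrogen
bonds and salt bridges.  Per pair, features are sampled on the filtration
grid:

* grid: 1.0 to 11.8 Å in steps of 0.4 Å — 28 points.  The nominal range
  1–12 Å is not an integer multiple of the step; fixing the grid at 28
  points with the ceiling `f_max = 12` kept separate makes vectors
  reproducible bit for bit.
* statistics: the number of dimension-0 and dimension-1 facet bars **alive**
  at each grid value (the reading of "calculated at each step size" most
  consistent with a per-scale ideal count), and the face counts `f0`, `f1`.
* complexes: the Rips complex under $D_{mod}$, and the alpha complex under
  the standard metric on the **union** of the pair's site and neighborhood
  atoms.  The alpha atom set is not pinned down by the source convention;
  the union preserves pair specificity and is flagged here as the natural
  sensitivity-analysis knob.  Pairs are ordered (site, neighborhood) for
  both complexes.

A structure block is therefore `2 complexes x 9 pairs x 4 statistics x 28
grid points = 2016` values; the mutation embedding is
`[WT | MT | WT - MT]` (the difference block is wild-type minus mutant by
convention) plus any precomputed auxiliary/transformer feature row appended
verbatim.  Empty subclouds contribute zero blocks so the length is constant
across mutations.  Mutant structures are inputs — the package does not
generate them — and the fixture generator fabricates wild-type/mutant pairs
by residue substitution with idealized geometry.

## Numerical choices

* **Delaunay construction.**  No 3-D Delaunay facility is available to this
  package, so the kernel certifies every candidate cell directly by the
  empty-circumsphere criterion in compiled code.  This is $O(n^5)$ —
  deliberate, auditable, and adequate for the dozens-of-atoms subclouds the
  featurizer produces (about half a second at $n = 60$), but not for
  whole-protein clouds; for those, Rips f-vector curves are the scalable
  alternative.  The construction is cross-checked in the tests against an
  independent plain-R oracle.
* **Degeneracy.**  Exactly duplicated points are collapsed with a warning.
  Collinear and coplanar inputs are detected by rank and triangulated in
  their 1-D or 2-D affine hull.  Cospherical/cocircular inputs (the cuboid
  and the unit square are both degenerate in this sense) are resolved by a
  deterministic symbolic perturbation applied in canonical (lexicographic)
  point order, so results do not depend on input row order; alpha values
  are computed on the same perturbed coordinates the triangulation
  certified.  Near-singular circumcenter systems fall back to a
  minimum-norm solution whose limit is the correct lower-dimensional
  circumcenter.
* **Facet deaths.**  For each simplex the death is the minimum filtration
  value over its cofacets, found by a sorted vertex-tuple lookup rather
  than by materializing facet lists per filtration step.  Computing
  dimension-$d$ deaths requires dimension-$(d+1)$ simplices; the complex
  records whether it was truncated at its dimension cap, and
  `facet_barcode()` refuses to report a dimension whose cofacets may be
  missing — except in the bipartite case, where their absence is
  structural.
* **Ties.**  Simplices whose values agree within the relative tolerance are
  treated as simultaneous; bars are sorted by (dimension, birth, death,
  vertices) for deterministic serialization.

## The learners

**CATree** is an ensemble of gradient-boosted trees (xgboost backend):
20000 estimators, maximum depth 7, learning rate 0.05, square-root feature
sampling per split, 0.4 row subsampling, and 10 independently seeded
repetitions whose predictions are averaged.  The default configuration
reduces only the estimator count (to 200) so the ensemble trains in
seconds; `catree_config(paper_scale = TRUE)` restores the full count.  The
minimum-samples-to-split setting is recorded in the configuration but has
no exact analog in the backend's tree builder.

**CANet** is a plain fully connected ReLU network — six hidden layers,
15000 neurons each at full scale (64 at the default test scale), Adam at
learning rate 0.001, 200 epochs, batch size 32 for regression/binary and
50 for the three-class solubility task.  No dropout or normalization
layers are used: the source architecture does not state any, so the
simplest reading is implemented.  Training is deterministic for a fixed
seed.  Solubility labels must be `decrease`, `increase`, `unchanged`.

Metrics: MCC, AUC, F1 and balanced accuracy for binary tasks; Pearson
correlation and RMSE for regression; for three classes, *normalized
accuracy* is implemented as macro-averaged recall (robust to the strong
class imbalance of solubility data) and *GC²* as the confusion-matrix
$\chi^2$ divided by $N(K-1)$.  Both three-class definitions are
provisional, since only their names are fixed by the source.

## What the synthetic generators emulate — and what they do not

* `make_cuboid()` / `make_hexagon()` reproduce the two point-cloud motifs
  whose barcodes are fully understood analytically; the hexagon is the
  unique highly symmetric six-point configuration matching every narrated
  event (dimension-0 deaths at the side length, triangles at
  $2\sqrt3 \approx 3.46$, i.e. just before 3.5) and is adopted as the
  canonical reconstruction.
* `make_mutation_pair()` writes minimal wild-type/mutant PDB pairs with
  idealized extended-chain geometry and exact per-residue heavy-atom
  compositions.  Coordinates are quantized to PDB precision (0.001 Å) at
  generation, so files, manifests and recomputed geometry agree exactly.
  These are geometric stand-ins: no rotamers, no energy minimization, no
  crystallographic artifacts (altlocs, missing residues) beyond those the
  parser tests construct explicitly.  Passing tests on these fixtures
  certify the geometry/algebra pipeline, not biological realism of the
  structures.
* The planted-signal dataset used to sanity-check CATree hides one
  informative coordinate among 60 noise columns, with 10% label noise on
  the training rows and clean test labels.  This checks that the learner
  *finds* planted structure under square-root feature sampling; it
  deliberately does not test approximation of oblique decision boundaries,
  which axis-aligned trees at these sample sizes cannot do and which the
  embedding does not require.

Problem sizes used by the test suite are chosen for exhaustive
verifiability: random clouds of up to 10 points (where every subset can be
enumerated), fixtures of 4-8 residues, and 500-sample learner checks.

## Limitations

* Facet barcodes on large clouds are combinatorially infeasible by nature;
  use `f_vector_curve()` (and the CLI's `--format fvector`) beyond a few
  hundred points.
* The brute-force Delaunay kernel is impractical above roughly 150 points.
* Weighted alpha complexes, Cech complexes, periodic boundaries, persistent
  graded Betti numbers and homology are out of scope.
* SASA, secondary structure and transformer embeddings are consumed as
  precomputed tables, never computed.
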