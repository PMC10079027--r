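---
title: "Building and analysing structural connectomes with brainhub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and analysing structural connectomes with brainhub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainhub)
```

## The problem

A structural connectome is a weighted network whose nodes are parcellated
brain regions and whose edge weights count the white-matter streamlines that
tractography reconstructs between them. Which regions dominate such a
network depends strongly on which regions are in it: widely used cortical
atlases (the 84-structure Desikan-Killiany default of common tractography
software) omit the brainstem and several other deep structures, and with
them the routes that many cortico-cortical streamlines physically take.
brainhub implements the full analysis chain needed to study that contrast:
endpoint-to-matrix construction, run and subject averaging, restriction to a
smaller node set, volume normalization, three node-centrality measures with
cross-subject ranking tables, and three global topology measures. Because
subject-level diffusion MRI cannot be redistributed, the package also
includes a synthetic generator that emulates the statistical structure of
multi-subject tractography output, so every stage runs and is testable at
desk scale.

## From endpoints to matrices

The unit of input is a streamline's pair of endpoint coordinates (world mm).
Each endpoint is mapped to a region by applying the inverse of the label
volume's voxel-to-world affine and rounding half away from zero to the
nearest voxel (0-based indices, the NIfTI convention); out-of-grid points
map to background. A streamline whose endpoints fall in regions $i$ and $j$
increments both $a_{ij}$ and $a_{ji}$ — a bi-directional label map — so
matrices are symmetric by construction. Records are discarded, with a tally
by reason, when an endpoint is background, when a label lies outside the
requested node subset, or when both endpoints share a region. The
same-region case is a deliberate choice the upstream convention leaves open:
the centrality definitions below assume no self-loops, so the diagonal is
kept at zero and the discards are counted rather than silently dropped.

Runs are pooled per subject by an elementwise mean, and subjects by an
elementwise mean plus the inter-subject sample standard deviation (divisor
$n-1$); SDs describe variability between individuals, not estimation error.

Three restriction modes produce the smaller-atlas variant of a connectome:
`submatrix` simply drops rows and columns; `endpoint_filter` rebuilds the
matrix discarding streamlines that touch removed structures;
`traversal_filter` additionally discards streamlines whose traversed-label
set intersects the removed structures. The last is the default for
synthetic data because it emulates what actually happens when tracking is
re-run with an altered white-matter mask: streamlines that pass *through* a
removed structure are never generated, which is how removing deep structures
depresses cortico-cortical connectivity far from the removed nodes.

Volume normalization divides each weight by the sum of its two endpoint
region volumes, $a'_{ij} = a_{ij}/(v_i + v_j)$, discounting the streamline
mass a structure accrues by sheer size.

## Centrality measures

For a connectivity matrix $A = (a_{ij})$ over $N$ nodes:

* **Degree (strength)** $d_i = \sum_j a_{ij}$.
* **Eigenvector centrality**: the components of the eigenvector of $A$'s
  largest eigenvalue, computed by power iteration. For a connected
  non-negative matrix the Perron–Frobenius theorem makes this vector unique
  and positive. The iteration runs on $A + sI$ with $s$ the maximum
  strength: the shift leaves the eigenvector unchanged but prevents the
  oscillation that plain power iteration exhibits on bipartite-like graphs,
  whose extreme eigenvalues tie in magnitude. The vector is scaled so its
  maximum component is 1; the overall factor carries no information when
  comparing nodes within one network. On a disconnected matrix the vector
  is computed on the largest component with zeros elsewhere and a warning.
* **Betweenness** $b_i = \frac{2}{(N-1)(N-2)} \sum_{j<k;\,j,k\neq i}
  \sigma_{jk}(i)/\sigma_{jk}$, where $\sigma_{jk}$ counts shortest paths and
  $\sigma_{jk}(i)$ those passing through $i$. Since the graph is complete or
  near-complete and weighted, "shortest" needs a metric: the distance of an
  edge is the reciprocal of its weight, so strong connections are short.
  Geodesics and path counts come from a dense Dijkstra with tied paths
  counted at a relative tolerance of $10^{-9}$; the accumulation over pairs
  uses the dependency recursion of Brandes, and the unordered-pair
  convention makes an isolated star's centre score exactly 1. Endpoints are
  excluded from their own paths; unreachable pairs contribute nothing.

Ranking tables are built subject-first: the measure is computed on each
subject's run-averaged matrix, then each structure's values are averaged
across subjects and accompanied by their inter-subject SD, and finally the
means are divided by their own maximum so the top structure scores exactly
1. This order (rather than measuring the group-mean matrix) is what makes
the SD column meaningful; the group-matrix variant remains available by
calling the measures on the averaged matrix directly. Both the raw-scale
and max-normalized SDs are emitted, since either scale can be wanted for
error bars. Ties in the mean are broken lexicographically by name so output
is deterministic.

## Global topology

* **Global efficiency** (integration)
  $E_{glob} = \frac{1}{N(N-1)}\sum_{i\neq j} 1/s_{ij}$ over the same
  reciprocal-weight geodesics; unreachable pairs contribute 0.
* **Modularity** (segregation)
  $Q = \frac{1}{2m}\sum_{ij}\left[a_{ij} - \frac{d_i d_j}{2m}\right]
  \delta(c_i, c_j)$ with $m = \frac12\sum_{ij} a_{ij}$. The reported
  "ultimate modularity" is the maximum found by a Louvain heuristic
  (greedy local moves, community aggregation, resolution 1) with seeded
  node-order shuffles over 10 restarts by default; the single-community
  partition ($Q = 0$) is always a candidate, so the result is never
  negative, and the returned value is recomputed from the original matrix
  rather than trusted from the heuristic's bookkeeping.
* **Global reaching centrality** (hierarchy)
  $GRC = \sum_i [C_R^{max} - C_R(i)]/(N-1)$, where the local reaching
  centrality $C_R(i)$ averages, over all nodes reachable from $i$, the mean
  edge weight along the selected geodesic. The defining formula was stated
  for directed graphs; each undirected edge is treated as two directed
  links. Which geodesic to select on a weighted graph is genuinely
  underdetermined — this is the main metric ambiguity in the chain — and
  the package resolves it consistently with the other measures:
  reciprocal-weight distance, ties broken by fewest links and then by
  lexicographically earliest node sequence, making the selection
  deterministic. Raw weights are used as the link weights; with weights at
  most 1 the measure is bounded by $[0,1]$.

## The synthetic generator

No generative model exists upstream (real data came from diffusion MRI), so
the generator is the package's own design: the minimal structure that
reproduces the qualitative findings the analysis is meant to detect.

* **Parcellation**: $N$ regions in three communities — two "hemisphere"
  blocks and a "subcortical" block that contains all hubs. Volumes are
  lognormal (median 5000 mm³, dispersion `sdlog` 0.5 by default); hubs get
  the largest draws scaled by a multiplier (default 3), emulating a
  brainstem-like structure that is both large and strongly connected.
* **Label volume**: a brain-like ellipsoid in the grid is partitioned by
  multiplicatively weighted Voronoi assignment around per-region seed
  points, radii proportional to the cube root of region volume, so voxel
  counts track volumes approximately.
* **Pair distribution**: a planted-hub block model. Within-community pairs
  get weight `w_in`, between-community pairs `w_out` (defaults 2 and 1),
  pairs touching a hub are boosted by `hub_boost` (default 3), and the
  matrix is normalized to unit mass over unordered pairs. Every
  inter-community pair is assigned a traversal set containing one hub, the
  abstraction of streamlines crossing deep structures: removing the hub
  under `traversal_filter` severs those routes.
* **Ensemble**: each subject's pair distribution is the ground truth times
  independent multiplicative lognormal noise (sd 0.2 on the log scale by
  default), renormalized — multiplicative so weights stay positive, and
  renormalized so the object remains a distribution. Each run is an
  independent multinomial endpoint sample; endpoints are placed uniformly
  inside a random voxel of their region (no cortical-surface bias — the
  simplest defensible placement). Every stochastic step derives its stream
  from one master seed, so ensembles are bit-reproducible.

The generator emulates: hub dominance, community structure, routing of
inter-community connections through hubs, sampling noise across runs, and
between-subject variability. It does not emulate curved streamline
geometry, distance-dependent connection probabilities, seeding-density
artifacts, or any diffusion signal physics; the noise sd is a free
parameter, not calibrated to real cohorts. Passing tests therefore show
the analysis chain is correct and recovers planted structure under
realistic sampling noise — not that any particular anatomical claim holds
in real data.

## Packaged atlas fixtures

`extended_atlas()`, `removed_structures()` and `restricted_atlas()` provide
the 104/20/84-structure node sets of the extended-versus-restricted
contrast. Names follow the FreeSurfer aseg/aparc convention (68 cortical
parcels, 14 subcortical structures and 2 cerebellar cortices in the
restricted set; the brainstem, ventral diencephalon, white-matter and
CSF-space structures among the 20 removed). The volume column is synthetic
— plausible magnitudes for exercising volume normalization, not
measurements — and the fixture filenames carry a `_synthetic` suffix to
say so.

## Numerical choices

* Geodesic tie tolerance: relative $10^{-9}$, applied to the shorter of the
  two competing path lengths.
* Power iteration: tolerance $10^{-12}$ on the max-norm change, 10,000
  iteration cap, non-convergence is an error rather than a silent result.
* Matrix validation: symmetry enforced to a relative $10^{-9}$ on
  construction and file read; weights re-symmetrized by averaging with the
  transpose to keep downstream algebra exact.
* Louvain: move threshold $10^{-12}$ gain; restarts default to 10; the
  returned $Q$ must agree with an independent recomputation to $10^{-12}$.
* File round-trips: 17 significant digits in TSV, lossless below
  $10^{-12}$.

## Study conditions used by the packaged simulations

The package's own verification simulations run at deliberately desk-scale
sizes chosen once: planted-hub recovery uses 30 regions, 1 hub with boost 3,
within/between weight ratio 2, 20 subjects × 3 runs × 5,000 streamlines,
noise sd 0.2, over 100 seeds; the variant-contrast simulation uses the same
generator with 3 subjects × 2 runs × 4,000 streamlines over 50 seeds, which
is sufficient because its outcome is a per-seed direction indicator rather
than an estimate. For these runs the volume dispersion is set to 0 with hub
multiplier 3, pinning the hub volume at exactly three times the median so
the volume-normalization stress test is exact rather than seed-dependent.
The full-scale design the generator emulates (104 regions, 100 subjects,
~10⁴ streamlines per run) runs through exactly the same code path.

## Known limitations

* The block model has three communities and hub routing concentrated on one
  hub; real connectomes have richer mesoscale structure.
* Louvain is a heuristic: it can under-shoot the true maximum modularity
  (tests verify it never over-shoots an exhaustive search on small graphs).
* Betweenness is $O(N^3)$-ish and the kernels are dense; the package is
  sized for networks of order $10^2$ nodes, which covers whole-brain
  parcellations of this granularity comfortably, but not voxel-level
  graphs.
* Real anatomical claims (which structure dominates a human connectome)
  require real tractography input; the package accepts external endpoint
  TSVs from any tool for that purpose.
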