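# brainhub

Structural connectome construction, hub centrality, and global network
topology in R.

## What it is for

A structural connectome is a weighted graph: nodes are parcellated brain
regions, edge weights count the tractography streamlines whose endpoints
fall in each pair of regions. Which regions look like hubs in such a
network depends on which regions the atlas contains — common 84-structure
Desikan-Killiany-style atlases omit the brainstem and other deep
structures, along with the routes many cortico-cortical streamlines
physically take. brainhub is for researchers who want to quantify that
dependence: it builds connectomes from streamline endpoint records, averages
them over runs and subjects, contrasts an extended (deep-structure-
inclusive) node set with a restricted one, normalizes edge weights by region
volume, and measures node importance and whole-network organization.

Node centrality, for matrix $A=(a_{ij})$ over $N$ regions:

- degree (strength): $d_i = \sum_j a_{ij}$
- eigenvector centrality: the Perron eigenvector of $A$, $\mathbf v =
  \tfrac1\lambda A\mathbf v$, scaled to max 1
- betweenness: $b_i = \frac{2}{(N-1)(N-2)}\sum_{j<k;\,j,k\ne i}
  \sigma_{jk}(i)/\sigma_{jk}$, geodesics under edge distance $1/a_{ij}$

Global topology:

- integration: global efficiency $E_{glob} = \frac{1}{N(N-1)}
  \sum_{i\neq j} 1/s_{ij}$
- segregation: ultimate modularity, $Q = \frac{1}{2m}\sum_{ij}
  [a_{ij} - \frac{d_i d_j}{2m}]\,\delta(c_i,c_j)$ maximized by a seeded
  Louvain heuristic
- hierarchy: global reaching centrality $GRC = \sum_i [C_R^{max} -
  C_R(i)]/(N-1)$

All graph kernels (Dijkstra with tied-path counting, Brandes accumulation,
power iteration, Louvain) are implemented in the package and verified in
the test suite against brute-force oracles (Floyd–Warshall, exhaustive path
and partition enumeration, dense eigendecomposition).

Because subject-level diffusion MRI is not redistributable, the package
includes a first-class synthetic generator: a planted-hub block model over
a three-community parcellation, a Voronoi-partitioned label volume, and
multi-subject/multi-run multinomial endpoint sampling with lognormal
between-subject noise. External endpoint TSVs from any tractography tool
plug into the same build functions.

## Worked example

Simulate a 30-region cohort with one planted hub, build each subject's
run-averaged connectome, and rank structures by degree:

```r
library(brainhub)

parc <- make_parcellation(n_regions = 30, n_hubs = 1, seed = 42)
lv   <- make_label_volume(parc, grid_shape = c(24, 24, 24), seed = 42)
gt   <- make_ground_truth_matrix(parc, w_in = 2, w_out = 1, hub_boost = 3)
ens  <- generate_ensemble(gt, lv, n_subjects = 10, n_runs = 3,
                          n_streamlines = 5000, subject_noise_sd = 0.2,
                          seed = 42)

sids <- vapply(ens, function(e) e$subject_id, numeric(1))
subj <- lapply(split(ens, factor(sids, levels = sort(unique(sids)))),
               function(runs) average_runs(lapply(runs, build_matrix,
                                                  lv = lv, parc = parc)))
rank_structures(per_subject_centralities(subj, "degree"), top = 5)
#>   measure            name mean   sd normalized_mean sd_normalized rank
#> 1  degree          Hub-01  791 24.9           1.000        0.0314    1
#> 2  degree  Left-Cortex-05  333 13.3           0.421        0.0167    2
#> 3  degree Right-Cortex-12  333 24.3           0.420        0.0308    3
#> 4  degree Right-Cortex-11  330 10.6           0.418        0.0134    4
#> 5  degree  Left-Cortex-04  329 16.4           0.416        0.0207    5
```

The hub attracts more than twice the streamline mass of any other region
(`mean` is streamlines per region, averaged over runs and subjects; `sd` is
the spread between subjects; `normalized_mean` divides by the top value, so
the leading structure is exactly 1). Global organization of the group-mean
connectome:

```r
gm <- average_subjects(subj)$mean_matrix
global_efficiency(gm)                 # 15.12  (integration)
louvain_partition(gm, seed = 42)$q    # 0.134  (segregation; 3 communities)
global_reaching_centrality(gm)        # 15.1   (hierarchy, raw weight scale)
```

`run_pipeline(pipeline_config(...))` performs all of the above end to end —
the four connectome variants (extended/restricted × raw/volume-normalized),
ranking tables for all three measures, topology summaries, and provenance —
and writes deterministic CSV/TSV/NIfTI outputs. A thin command-line wrapper
lives at `inst/scripts/brainhub-pipeline.R`. The packaged
`extended_atlas()` / `removed_structures()` / `restricted_atlas()` fixtures
provide the 104/20/84-structure node sets of the extended-versus-restricted
contrast.

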