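# connsmooth

Structural-connectome graph smoothing of source-space EEG functional
connectivity.

## The problem

Source-projected EEG lets whole-cortex functional connectivity (FC) be
studied at millisecond resolution, but volume conduction leaks every
source into its neighbours, producing spurious zero-lag correlations that
decay with Euclidean distance and cannot be separated pair-by-pair from
genuine coupling. `connsmooth` is for network-neuroscience analyses of
source-space EEG (power-envelope FC in particular) that want to *boost*
the genuine, anatomically mediated component instead of discarding
zero-lag information: under the assumption that genuine FC rides on
white-matter structural connectivity (SC), each region's signal is
averaged with its structurally connected neighbours,

```
x̂_i(t) = x_i(t) + G * Σ_j c_ij x_j(t)
```

a one-hop low-pass filter on the graph with weights `c_ij` (derived from
the connectome and/or inter-ROI distances) and scalar filter weight
`G ≥ 0`. Connected regions' signals become more similar; unconnected
regions are untouched; leakage, which ignores the connectome, gains
nothing.

The package implements the operator together with the machinery needed to
validate it end to end:

* **IO and configuration** — labelled delimited matrices, parcellation
  tables, per-interval ROI time courses, JSON run configs, and a CLI
  (`exec/connsmooth`, subcommands `simulate`, `graphs`, `si`, `filter`,
  `fc`, `glm`, `fitcurve`, `communities`).
* **Connectome graphs** — distance-binned group-consensus SC that
  preserves intra- and interhemispheric single-subject densities;
  degree-preserving rewired nulls; the four filter-graph variants
  (`sc`, `ed_full`, `ed_match`, `ed_dens`); search information
  (`-log2` probability that a random walker follows the shortest path),
  the dense SC-derived predictor used throughout.
* **FC estimation** — power-envelope correlation (zero-phase band-pass,
  Hilbert envelope, 0.5 Hz low-pass, duration-weighted Fisher-z
  combination), Welch coherence and imaginary coherence, Fisher-z and
  rank-normal transforms, artifact-window screening.
* **Structure–function statistics** — pair-level tables (FC vs distance,
  search information, relative regional variance, ROI size), stepwise
  GLM with interactions, and distance-matched comparison of connected vs
  unconnected pairs (exact Wilcoxon signed-rank).
* **Fit and control analyses** — fit-versus-G curves against a reference
  FC, paired variant comparisons, variance-matched white-noise controls.
* **Community structure** — repeated signed Louvain co-assignment
  matrices, per-ROI rank-correlation agreement, and the
  (resolution, filter-weight) sweep with Pareto reporting.
* **Synthetic cohort** — a fully seeded generator for the whole study
  (lobed two-hemisphere geometry, distance-decaying subject connectomes,
  SC-coupled band-limited sources, instantaneous distance-dependent
  leakage, in-band measurement noise) with the leakage-free ground-truth
  FC recorded, so every analysis can be exercised without acquisition
  data.

## Worked example

```r
library(connsmooth)

# a small synthetic study: 34 ROIs, 6 subjects, alpha-band coupling
study <- make_cohort(n_rois = 34, n_subjects = 6, seed = 42)
cons <- consensus_sc(study$subject_scs, study$parcellation)
print(cons)
#> <structural_connectome> 34 ROIs, density 23.7% (36.0% intra, 12.1% inter)

# smooth on the SC-masked distance graph and fit to the leakage-free truth
graph <- build_filter_graph("ed_match", cons, study$parcellation)
fcs <- study_fc_grid(study$epochs, graph, c(0, 0.05, 0.2, 1), study$band)
curve <- fit_curve(fcs, study$reference_fc)
round(tapply(curve$curve$z, curve$curve$G, mean), 3)
#>     0  0.05   0.2     1
#> 0.464 0.519 0.588 0.537

# how hidden are shortest paths in the consensus connectome?
si <- search_information(cons)
ed <- roi_distances(study$parcellation)
ut <- upper.tri(ed)
cor(ed[ut], si$si[ut])
#> [1] 0.6
```

The consensus connectome reproduces the density structure of
tractography-derived group connectomes (sparser across hemispheres). The
fit curve is the package's core result: the mean Fisher-z correlation
between each subject's envelope FC and the leakage-free reference rises
from 0.464 unfiltered to 0.588 at `G = 0.2`, then falls again as
over-smoothing lets the graph dominate — smoothing along structural
connections recovers genuine coupling that leakage and noise had obscured.
Search information rises with distance (r = 0.60 here): long-range pairs
have better-hidden shortest paths.

On the full default cohort (68 ROIs, 18 subjects, seed 20), the same
analysis gives a mean baseline fit of z = 0.322 rising to 0.427 at the best
filter weight for the SC-masked distance graph, versus 0.395 for the dense
distance graph, with the SC-masked advantage consistent within subjects.

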