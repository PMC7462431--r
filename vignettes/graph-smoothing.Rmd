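---
title: "Connectome-constrained smoothing of source-space EEG: model, assumptions, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-constrained smoothing of source-space EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Functional connectivity (FC) between source-projected EEG regions of
interest mixes two distance-dependent signals: genuine coupling, which is
partly mediated by white-matter structural connectivity (SC), and volume
conduction ("leakage"), the instantaneous spread of electric fields that
creates spurious zero-lag correlations decaying with Euclidean distance
(ED). The two cannot be separated pair by pair. `connsmooth` takes the
constructive route: if genuine FC rides on SC, then averaging each region's
signal with its structurally connected neighbours,

$$\hat x_i(t) = x_i(t) + G \sum_j c_{ij}\, x_j(t),$$

selectively reinforces the SC-mediated component relative to leakage, which
depends on distance but not on SC per se. Here $c_{ij}$ are the weights of a
*filter graph* derived from the connectome and $G \ge 0$ is the scalar
filter weight. The operator is linear, zero-lag and purely spatial: no
temporal mixing, no renormalization (correlation-based FC is invariant to
per-ROI scale). Filtering is applied to the broadband signal before
band-pass and envelope extraction; because the operator is spatial and the
band-pass temporal, the two commute exactly, which `study_fc_grid()`
exploits to band-pass each interval once per study rather than once per
$(G,\ \mathrm{variant})$.

## Filter graphs

Four variants, built by `build_filter_graph()` from a group-consensus SC:

* **sc** — consensus fiber counts themselves;
* **ed_full** — dense $\exp(-k\,\mathrm{ED})$ between all pairs;
* **ed_match** — $\exp(-k\,\mathrm{ED})$ masked by the SC support
  (same present/absent edges as **sc**);
* **ed_dens** — $\exp(-k\,\mathrm{ED})$ on the shortest-distance pairs up
  to the SC's connection density;

plus a degree-preserving rewired control (**randomized**). The decay scale
$k$ in "auto" mode equates the median off-diagonal `ed_full` weight with
the median nonzero weight of the max-normalized consensus SC, so that a
given $G$ produces comparable effective weights across variants. All
graphs are normalized to maximum weight 1 by default. With that
normalization the interesting range of $G$ is roughly $[0.01, 5]$: a node's
neighbour weights sum to about 5–20, so by $G \approx 1$ the neighbour term
dominates and the FC of the filtered signals stops changing (the operator
"saturates"). The default grid is therefore geometric,
$\{0, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10, 100, 1000\}$, spanning
identity to saturation; an arithmetic grid over $[0,1000]$ would sample
only the saturated plateau.

## Consensus connectome and search information

Averaging tractography across subjects with a single weight threshold
starves interhemispheric connections, whose streamlines are longer and
less reliably traced. `consensus_sc()` therefore thresholds intra- and
interhemispheric edges separately, within equal-count distance bins
(default $\lceil\sqrt{E}\rceil$ bins per class), retaining the most
consistently present edges until each class matches the average
single-subject density, with a recurrence floor (default 30% of subjects).
Retained weights are mean fiber counts over the subjects carrying the edge.

Because FC is dense while SC is sparse, pairwise structure–function
analyses use *search information*: for each pair $(s,t)$,
$-\log_2$ of the probability that a greedy random walker follows the
shortest path (edge lengths $1/w$; the probability multiplies, over the
nodes of the path, the outgoing path-edge weight divided by the node
strength). It is defined for all pairs of a connected graph, grows when
the shortest path is "hidden" among strong detours, and is roughly
inversely related to fiber count. We symmetrize by the arithmetic mean and
use inverse-weight edge lengths (the standard connectome convention; a
$-\log$ length mode is available). Search information is invariant to
global rescaling of the SC weights; the test suite checks the
implementation against a brute-force path-enumeration oracle on small
random graphs.

## FC measures

The primary measure is the power-envelope correlation: zero-phase
Hamming-windowed FIR band-pass (order $\approx 3 \cdot
\mathrm{rate}/f_\mathrm{low}$, capped at a third of the interval length),
analytic-signal magnitude, zero-phase low-pass at 0.5 Hz, Pearson
correlation over time. Only intervals of at least 19 s are used — the 0.5 Hz
envelope leaves very few effective samples per interval, and shorter
stretches make the estimate unusable. Per-interval matrices are combined by
duration-weighted Fisher-z averaging (the combination rule is a package
choice; with identical intervals it reduces exactly to the single-interval
FC). Welch coherence and imaginary coherence (5 segments, 50% overlap,
Hann taper, band-averaged) are provided for comparison, on ~3 s windows
screened by a 6-standard-deviation artifact rule.

All filters are applied as symmetric (linear-phase) FIR kernels with exact
group-delay compensation and reflection padding, via FFT convolution on
all channels at once — zero-phase by construction, single-pass.

## The synthetic cohort

The generator produces the study the validation machinery needs, with
known ground truth; real acquisitions are not required anywhere. The
default cohort mirrors a realistic resting-state source-space study:
68 ROIs on two hemispheric shells, 18 subjects, 2–5 artifact-free
intervals each of 20–60 s at 250 Hz.

* **Geometry** (`make_parcellation`): the left-hemisphere centroids are
  sampled on a shell around four lobe axes (mimicking the
  frontal/temporal/parietal/occipital clustering of anatomical
  parcellations); the right hemisphere is the mirror image with a 2 mm
  jitter, so ROI i left / ROI i right are homotopic partners, as in real
  cortices. Minimum centroid separation 8 mm; ROI sizes log-uniform in
  [100, 5000] voxels.
* **Connectomes** (`make_subject_scs`): edge presence decays exponentially
  with ED (length scale 45 mm) and is scaled per class so single-subject
  densities are ~39% within and ~12% across hemispheres (the
  `inter_penalty = 0.3` is the inter/intra density ratio). Homotopic pairs
  get a presence floor (0.75) inside the interhemispheric budget and an
  elevated fiber count (multiplier 8), emulating preferential callosal
  connectivity — without it, mirror regions would couple no more than any
  equally distant pair, which real connectomes contradict. A Gaussian
  copula shares a group propensity across subjects so edges recur the way
  real bundles do; fiber counts decrease with distance with log-normal
  subject dispersion.
* **Sources** (`make_sources`): latent signals are band-passed white noise
  amplitude-modulated by an independent slow (<0.5 Hz) positive envelope,
  so envelope correlation is a meaningful coupling target. Genuine
  coupling is instantaneous mixing along the row-normalized SC with weight
  `coupling = 1.2`; leakage is a second instantaneous mixing by the
  row-normalized kernel $\exp(-\mathrm{ED}/15\,\mathrm{mm})$; finally
  per-ROI *band-limited* measurement noise at in-band amplitude ratio
  `snr = 1` (with a ±30% spread across ROIs, which is what makes relative
  regional variance an informative predictor). The stored ground truth is
  the envelope FC of the pre-leakage, pre-noise signals, computed by the
  same code path as every other FC in the package.

Band-limiting the noise matters: broadband white noise is ~96% removed by
an 8–13 Hz band-pass, so only in-band noise influences envelope FC. The
three default levels were chosen together so that the cohort reproduces,
qualitatively, the empirical regime the method was designed for: genuine
SC-mediated FC is present but obscured (unfiltered fit to the leakage-free
reference FC of $z \approx 0.35$), leakage imprints a distance dependence,
and noise leaves room for denoising. They were fixed before the acceptance
suite was frozen and have not been revisited.

What the generator deliberately does *not* emulate: 1/f spectra, conduction
delays, task structure, a realistic lead field (leakage is a fixed spatial
kernel, not a head model), or polysynaptic coupling (genuine mixing is
one-hop). Passing tests therefore show that the pipeline behaves correctly
under the stated generative assumptions — not that it will produce the same
effect sizes on any particular real dataset.

## Structure–function regression and matched comparison

`build_pair_table()` vectorizes the upper triangle (one row per unordered
ROI pair): FC, ED, search information, pair-level relative regional
variance (RRV) and ROI size — nodal quantities are reduced to pairs by the
mean (the symmetric choice; `min` is available). `stepwise_glm()` runs
forward–backward selection over the four standardized main effects and six
first-order interactions on a Gaussian identity-link model; a candidate
enters when the dispersion-scaled deviance difference is significant
(χ², `alpha_add = 0.05`) and leaves at `alpha_remove = 0.10`; interactions
require both mains in the model. Single-predictor models give each
variable's stand-alone r². With four correlated candidates screened at
0.05, the null probability that *something* enters is above 0.05 by
construction (multiplicity is not corrected, matching standard stepwise
tools); on this cohort it measures ~0.13.

`matched_sc_comparison()` tests whether FC over SC-connected pairs exceeds
FC over unconnected pairs at matched distances: the pooled ED range is
restricted to the overlap of the two classes, split into 10 equal-count
bins, the larger class subsampled per bin to the smaller one's count
(100 resamplings averaged), and the per-subject class means compared with
an exact Wilcoxon signed-rank test, Bonferroni-corrected over bands. The
matching controls the *between*-bin distance profile; a strong FC–distance
gradient combined with a residual within-bin class difference can still
bias the test, which is why the calibration tests draw the null with FC
independent of distance.

## Communities

`louvain_coassignment()` repeats Louvain clustering (default 200 runs,
random order per run) at resolution γ and records per-pair co-assignment
frequencies; rows are ROI "community profiles". FC matrices carry negative
correlations, and no installed R implementation offers signed modularity
with a resolution parameter, so the dense-matrix generalized Louvain is
implemented here: positive and negative weights contribute asymmetrically
(the negative term is down-weighted by its share of total weight;
`neg_mode = "zero"` zeroes negatives instead). On purely positive graphs
it optimizes ordinary Newman–Girvan modularity and is cross-checked
against igraph in the tests. Agreement between two community structures is
the mean over ROIs of the Spearman correlation between their profiles
(diagonal excluded; constant profiles are dropped with a warning —
"rank correlation" is read as Spearman). `community_sweep()` maps
agreement and community count over (γ, G), seeds every cell with a
deterministic substream recorded in its output, and flags the
agreement-versus-parsimony Pareto front rather than hard-coding a
preferred community count. Group-average FC matrices are rank-normalized
(`rank_normal()`: normal quantiles of the off-diagonal ranks) before
clustering so that matrices from different filter weights are comparable.

## Numerical choices and degenerate inputs

* Fisher z clips correlations at $\pm(1-10^{-15})$ before `atanh`; perfect
  self-comparisons are flagged rather than returned as `Inf`.
* Constant envelope channels yield FC entries of 0 with a warning;
  constant FC matrices are an error in fit curves (no correlation exists).
* All-zero difference vectors in signed-rank tests report p = 1 with the
  statistic set to `NA` instead of erroring.
* Degenerate Louvain inputs (all-zero matrices) and disconnected SC pairs
  (infinite search information) raise or warn explicitly.
* Rewiring swaps that would disconnect the graph are rejected; ties when
  selecting shortest-ED pairs are broken by lexicographic pair order.
* Seeds: every stochastic function takes a `seed` and isolates it with
  `withr::with_seed`; nothing perturbs the caller's RNG state.

## Problem sizes used in the shipped analyses

The acceptance script and the end-to-end tests run the default 18-subject,
68-ROI cohort; fit curves use the G grid {0, 0.02, 0.05, 0.1, 0.2, 0.5,
1, 5} for two graph variants, and the community sweep uses γ ∈
{0.9, 1.0, 1.1, 1.2, 1.3} × G ∈ {0, 0.02, 0.05, 0.1, 0.5} at 100–200 Louvain
repetitions — grids chosen to cover the identity-to-saturation range of
the operator and the 2-to-many-communities range of γ at this N. Monte
Carlo calibrations (stepwise null rate, matched-test type-I error and
power, two-node closed form) use 60–500 replicates as noted in the tests.

## Known limitations

The operator only ever *adds* neighbour signal; it cannot deconvolve
leakage (its inverse would need negative weights), so improvements are
relative to a reference that is itself SC-structured. The consensus
procedure assumes hemisphere labels and centroid geometry are trustworthy.
The signed Louvain is a local optimizer; co-assignment frequencies absorb
run-to-run variability but inherit its resolution limits. Coherence-type
measures are provided for comparison, not tuned: their Welch segmentation
follows the stated 5-segment/50% convention without window-length
optimization.

A substantive limitation surfaced by the synthetic study: the *pairwise
fit* to the leakage-free reference improves robustly and substantially
under SC-masked smoothing (every cohort realization we generated), but
the *community agreement* of the group-mean FC does not reliably improve.
In this generative world the reference communities differ from the
observed ones mainly through bilateral (homotopic) merging, and a one-hop
smoothing step cannot amplify single callosal bridges faster than it
amplifies the ~16 intrahemispheric neighbours of each ROI: moderate
filter weights either preserve the lobe partition (fiber-count graph,
whose boosted callosal weights at least prevent collapse) or merge lobes
into hemispheres (distance-mapped graphs). Where the unfiltered community
structure happens to be degraded by noise, filtering can crisp it and
agreement rises; where it is already crisp, filtering is neutral at best.
Community-level claims about real data should therefore be checked
against their own baseline rather than assumed to follow from the
pairwise-fit improvement.
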