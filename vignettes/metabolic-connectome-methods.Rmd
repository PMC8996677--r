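---
title: "Methods: estimating and comparing metabolic brain networks from FDG-PET SUVR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and comparing metabolic brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metconn)
```

## The problem

Resting FDG-PET gives one number per brain region per subject: the
standardized uptake value ratio (SUVR), regional glucose uptake normalized
to cerebellar gray matter. Because a static scan has no within-subject time
series, "metabolic connectivity" is defined *across subjects*: two regions
are connected when their uptake covaries over the subjects of a group after
conditioning on all other regions. `metconn` estimates these group-level
networks, summarizes their topology with standard graph-theory measures,
classifies how hub regions reorganize between a control-like and a target
group (the lost / preserved / reconfigured taxonomy), tests group
differences nonparametrically, and identifies subnetworks such as the
default-mode (DMN) and salience (SN) networks by spatial independent
component analysis.

## Sparse inverse covariance estimation

Each group's network is a Gaussian graphical model. With `S` the empirical
correlation matrix of the subjects-by-ROI SUVR matrix (ROIs are
standardized so the penalty acts on a common scale), the precision matrix
estimate maximizes the penalized log-likelihood

$$\log\det\Theta \;-\; \operatorname{tr}(S\Theta)\;-\;\lambda
\sum_{i\neq j}\lvert\Theta_{ij}\rvert ,$$

solved by block coordinate descent (one lasso regression per column of the
working covariance, compiled code). Only off-diagonal entries are
penalized, so the working covariance keeps the empirical diagonal. A zero
\(\Theta_{ij}\) means regions *i* and *j* are conditionally independent —
no edge; edge weights are the partial correlations
\(-\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}\). Entries below `1e-8` in
magnitude are treated as exact zeros.

Group sizes in this design are small (six subjects in the smallest group),
so the penalty cannot be chosen by likelihood criteria alone, and no single
penalty is comparable across groups. The package therefore works on a
**density sweep**: for each target density (default 0.10 to 0.40 in steps
of 0.02) it finds, by warm-started bisection on \(\lambda\) (edge count is
non-increasing in \(\lambda\)), the penalty whose estimated graph has that
edge density, and compares groups at *matched density* rather than matched
penalty. Global measures are reported per density and integrated over the
sweep by a normalized trapezoid (`metric_auc`), so a constant metric
integrates to itself. When a requested density is unreachable (the density
plateaus above the target at the smallest admissible penalty), the closest
achievable fit is returned with a warning rather than an error.

Numerical contract of the solver: every returned precision is symmetric,
passes a Cholesky factorization, and satisfies the KKT conditions of the
penalized problem within tolerance (`kkt` is reported). At `lambda = 0`
with an invertible covariance the closed-form inverse is returned; at
`lambda >= max |S_ij|` the graph is empty.

## Graph measures

All measures operate on the binary, symmetric, zero-diagonal adjacency of
the estimated support (weighted variants of downstream analyses use the
partial correlations). Global: mean clustering coefficient, global
efficiency (mean inverse shortest-path length; \(1/\infty = 0\)), mean
local efficiency (global efficiency of each node's neighbor-induced
subgraph), degree assortativity (Pearson correlation over edge endpoints,
`NA` when degrees are constant), hierarchy (the exponent \(\beta\) in
\(C(k)\propto k^{-\beta}\), fit by least squares on log-log over nodes with
degree \(\ge 2\) and positive clustering; `NA` when fewer than two
eligible distinct degrees exist), synchronizability
(\(\lambda_2/\lambda_{\max}\) of the combinatorial Laplacian; 0 for
disconnected graphs), and characteristic path length over reachable pairs
with the number of unreachable pairs reported alongside — disconnection is
common at the sparse end of the sweep, and silently coercing undefined
values to 0 would bias group contrasts. Nodal: degree, clustering, mean
shortest path, nodal and local efficiency, and the participation
coefficient \(1-\sum_m (k_{im}/k_i)^2\) over a greedy-modularity (Louvain)
partition.

## Hubs and the reorganisation taxonomy

A node is a hub when its criterion exceeds the network mean by one sample
standard deviation (strictly; a constant criterion yields no hubs). Degree
centrality is the default criterion, applied to the AUC-integrated degree
across the sweep — a single-density rule inherits that density's
estimation noise, while the integrated degree is stable. The participation
coefficient is available behind a flag because the two centralities answer
different questions (connector vs high-degree hubs) and the degree rule is
the self-consistent default here. Given hub flags in both groups, each ROI
receives exactly one category: *lost* (control only), *preserved* (both),
*reconfigured* (target only), or *non-hub*. Swapping the group roles swaps
lost with reconfigured and fixes preserved — a property the tests enforce.

## Inference

Group differences in network measures are tested by label permutation:
subjects are reassigned to groups of the original sizes, and the entire
chain — correlation, penalty search, graphical lasso, graph measure — is
re-estimated inside every permutation (compiled, warm-started). The
p-value is the plain fraction of permuted absolute differences reaching
the observed one (default two-sided, 5000 permutations; the
\((b+1)/(B+1)\) correction is available for users who need strictly
positive p-values). An exhaustive-enumeration variant serves as the exact
reference when \(\binom{n_a+n_b}{n_a}\le 200{,}000\). Edge-level contrasts
use percentile bootstrap confidence intervals of the partial-correlation
difference (resampling subjects within groups), labeled
enhanced/weakened pre-FDR; multiplicity is controlled by Benjamini–
Hochberg within each density level. A caveat on power: the L1 penalty
shrinks every retained weight by roughly \(\lambda\), and under density
matching \(\lambda\) is sizeable, so edge-weight differences are
attenuated — on planted contrasts of ~0.35 partial-correlation units at
100 subjects per group the bootstrap flags the edge in roughly 60–80% of
replicates, not near-certainly. Edge-level findings at these sample sizes
should be read as direction-plus-screening, not as calibrated effect
estimates. Per-ROI uptake contrasts use an OLS
GLM of the standardized response on group plus age and sex, so the group
coefficient is an effect size in SD units; the effect-size filter is
\(|\beta| > 0.8\) (magnitude, since both directions are of interest).

## Spatial ICA

For subnetwork identification the subjects-by-voxels matrix is
row-centered, reduced and whitened by PCA, and unmixed by natural-gradient
Infomax with the logistic nonlinearity — subjects are mixtures, voxels are
samples, components are independent spatial maps. The component count is
chosen by the Wax–Kailath MDL criterion on the PCA eigenvalue spectrum
(voxels as samples); exactly rank-deficient data short-circuit to the
numerical rank. The learning rate adapts: it grows 5% while successive
natural-gradient updates agree and shrinks 30% when they oppose
(overshoot), capped at 20 times the initial rate, with divergent steps
rolled back at half rate; convergence is declared when the relative weight
update drops below `1e-7` (at most 512 iterations, honest `converged`
flag). Components are ordered by explained variance and signs fixed so
each map's peak-magnitude voxel is positive, making results bit-identical
under a fixed seed. Maps are z-scored; display masks use the strict
positive-tail threshold `z > 1.96` (a two-tailed option exists for
template matching). Templates are assigned greedily to the components with
the highest spatial correlation of the template mask with the |z| map,
without replacement, ties broken toward the lowest component index.

## The synthetic-data module

No patient scans are distributable, so every stage is validated on
generated data with known truth:

* **Planted precision models.** `make_sparse_precision` draws a sparse
  support with `n_hubs` hub nodes of degree
  \(\min(0.55\,p,\; m/n_{\text{hubs}})\) (always at least three times the
  median non-hub degree). Edge magnitudes are uniform on 0.3–0.6, divided
  by a common row-norm scale so the unit-diagonal precision is well
  conditioned; the resulting partial correlations land at roughly
  0.15–0.35, the scale reported for PET metabolic covariance, and —
  crucially for validation — above the sampling noise floor
  (\(\approx 1/\sqrt{n}\)) of the emulated cohorts' group sizes. Hub-incident edges
  carry coherent positive partial correlations (metabolic coupling around
  real hubs is predominantly positive); background edges alternate in
  sign. If the smallest eigenvalue still falls below 0.1 the diagonal is
  inflated, which preserves the support exactly.
* **Group pairs.** `make_group_pair` strips a planted "lost" hub down to a
  floor degree of 2 and raises a peripheral "reconfigured" node to hub
  degree, logging every edit; a common scale keeps preserved edges
  identical across the two truths.
* **SUVR samples.** Multivariate normal draws from the inverse precision,
  shifted to a positive mean level of 1.2 (covariance-invariant but
  SUVR-like), with age (normal, mean 50, SD 10) and sex (Bernoulli 0.5)
  covariates attached. Default group sizes mirror a presymptomatic genetic-FTD cohort design: 6 vs
  12 and 32 vs 33 subjects, with `p = 40` ROIs as the fast default and
  172 available.
* **Volume datasets.** Subject volumes are linear mixtures of compact
  Gaussian blobs (truncated at 5% of peak, hence spatially
  super-Gaussian) plus iid noise, with the mixing matrix, source maps,
  binary templates, and a toy label atlas (blob cores plus a corner
  reference region) returned for scoring.

What passing these tests shows — and does not. The generator produces iid
multivariate-normal subjects with exactly sparse precisions and noiseless
group labels. Real FDG-PET adds spatial autocorrelation from smoothing,
partial-volume effects, registration error, site and scanner effects, and
non-Gaussian tails; recovery rates measured here are therefore upper
bounds on what identical sample sizes achieve on real scans, and the
validated claim is that the *implementation* is correct, not that n = 6
suffices for reliable single-study hub maps.

## Problem sizes and reproducibility

The shipped analyses and tests run at desk scale by design: `p = 40` ROIs
for the study-shaped fixtures, support recovery scored at `p = 20`,
`n = 400`; permutation calibration with 500 null replicates of 200
permutations at the emulated 6-vs-12 design; hub recovery over 20 seeds at
`n = 50` per group; ICA on 24×24×16 grids with 30 subjects. A full
pipeline run (`run_pipeline`) writes every artifact plus a manifest with
per-stage seeds, MD5 checksums and a content hash; re-running the same
configuration reproduces the hash bit-identically, and a single global
seed fans out deterministically to the stage seeds.

## Known limitations

* Networks are estimated per group; subject-level metabolic networks are
  out of scope, as are time-resolved or longitudinal models.
* The density sweep bounds (0.10–0.40) follow common practice for
  SICE-based PET connectomes; densities below 0.05 leave most graphs
  disconnected and above ~0.5 the penalty no longer sparsifies.
* Hierarchy and synchronizability have no universally agreed definition in
  the clinical literature; the standard toolbox definitions documented
  above are used, and undefined cases propagate as `NA` markers.
* Spatial normalization, segmentation, and attenuation correction are
  upstream of this package: volumes and atlas are assumed to share a grid,
  and no resampling is performed.
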