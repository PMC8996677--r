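# metconn — metabolic connectome analysis for FDG-PET cohorts

Static FDG-PET yields one standardized uptake value ratio (SUVR) per brain
region per subject, so "metabolic connectivity" is a *group-level* notion:
two regions are connected when their uptake covaries across the subjects of
a group, conditional on every other region. `metconn` is an R package plus
a scripted analysis workflow for neuroimaging groups who want to

* estimate group metabolic networks by **sparse inverse covariance
  estimation** (graphical lasso), comparing groups at matched network
  density across a sweep (0.10–0.40);
* summarize topology with the standard graph measures — clustering,
  global/local efficiency, assortativity, hierarchy, synchronizability,
  shortest paths, participation coefficient — per density and integrated
  over the sweep;
* identify **hubs** (degree centrality > mean + 1 SD) and classify their
  reorganisation between groups as **lost / preserved / reconfigured**;
* test differences by subject-label **permutation** (full re-estimation
  inside every permutation), bootstrap edge CIs, GLM contrasts with age and
  sex covariates, and Benjamini–Hochberg FDR;
* find subnetworks (default-mode / salience style) by **spatial Infomax
  ICA** with MDL order selection and template matching.

The network model: for each group with ROI-standardized empirical
correlation `S`, the precision estimate solves

```
maximize  log det Θ − tr(SΘ) − λ Σ_{i≠j} |Θ_ij|
```

by block coordinate descent (compiled). Zeros of `Θ` are absent edges;
weights are partial correlations `−Θ_ij / √(Θ_ii Θ_jj)`; `λ` is chosen by
bisection to hit each target density, so groups are compared at matched
sparsity. Because no patient scans are distributable, a synthetic-data
module plants known precision structure, hub perturbations and spatial
sources, and every stage is validated against that truth (see
`vignettes/metabolic-connectome-methods.Rmd` for the model, parameter and
generator details).

## Worked example

The `analysis/` scripts run a complete synthetic study shaped like a
presymptomatic-carrier design: 6 carriers vs 12 controls, 40 ROIs, one
planted lost hub and one planted reconfigured hub, plus a powered 50 vs 50
cohort from the same truths.

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_connectome.R
Rscript analysis/03_graph_metrics.R
Rscript analysis/04_hub_reconfiguration.R
Rscript analysis/05_group_inference.R
Rscript analysis/06_ica_subnetworks.R
```

Outputs land under `results/synthetic_study/`. A run with the shipped seed
prints, among other things:

```
AUC-integrated global measures:
                     metric auc.carrier auc.control
              assortativity   0.1795218   0.1053304
                  hierarchy   0.2701154  -0.1109200
     clustering_coefficient   0.3744751   0.2835116
          global_efficiency   0.5819443   0.5924003
           local_efficiency   0.5934899   0.4874572
            synchronization   0.2144326   0.2114934

-- powered cohort (50 vs 50) --
  lost          planted: roi034   recovered: roi028,roi032,roi034
  reconfigured  planted: roi039   recovered: roi018,roi039

                measure         diff p_perm p_fdr
      global_efficiency -0.001047009  0.968 0.968
 clustering_coefficient -0.123330420  0.466 0.932

MDL order selection: k = 3 (3 sources planted)
within-network comparison: 1/28 edges flagged (planted edge roi007-roi008: increased)
```

Reading this: the global organisation of the two groups is statistically
indistinguishable (permutation p ≈ 0.97 and 0.47 — the planted edits are
local, not global), the powered cohort recovers both planted hub changes
(with a couple of false positives, normal at n = 50), the study-sized
cohort's hub map is noisy (the script prints the comparison — hub maps at
n = 6 vs 12 are exploratory), MDL finds the 3 planted spatial sources, and
the deepened within-network edge is flagged as increased.

Equivalent programmatic entry points: `run_pipeline(run_config(...))`
executes the whole chain from one validated configuration and writes a
manifest with seeds and checksums; individual steps are exported functions
(`build_adjacency_series()`, `hub_taxonomy()`, `permutation_test()`,
`infomax_ica()`, ...).

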