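---
title: "Small-world analysis of an AVH-related connectome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-world analysis of an AVH-related connectome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avhnet)
```

## The analysis

avhnet implements a graph-theoretic analysis of resting-state
functional connectivity restricted to a 35-region network implicated in
auditory verbal hallucinations (AVH). The pipeline consumes
preprocessed ROI time series for three record types — healthy controls
(HC, one session), patients at baseline, and the same patients after
treatment — and proceeds in fixed stages:

1. **Connectivity.** Pearson correlations between all ROI pairs give a
   35×35 matrix per record.
2. **Binarization.** Each matrix is thresholded to an unweighted graph
   at every sparsity level of a sweep (default 0.08–0.48 in steps of
   0.01, 41 levels), retaining exactly `round(s·N(N−1)/2)` top-ranked
   edges so all subjects have identical densities.
3. **Graph metrics.** Segregation (clustering coefficient Cp, local
   efficiency Eloc) and integration (characteristic path length Lp,
   global efficiency Eglob) per graph.
4. **Null normalization.** γ = Cp/⟨Cp_null⟩ and λ = Lp/⟨Lp_null⟩
   against degree-preserving Maslov–Sneppen rewirings; small-worldness
   σ = γ/λ.
5. **AUC summarization.** Each metric's curve over the sweep is
   reduced to its trapezoidal area under the curve, one scalar per
   metric per record.
6. **Inference.** Covariate-adjusted group contrasts of the AUCs with
   Benjamini–Hochberg FDR; network-based statistic (NBS) permutation
   inference on edges; responder classification by AHRS reduction;
   Pearson correlations between edge change and symptom change.

A synthetic cohort generator reproduces the statistical structure this
analysis assumes, so every stage is testable end to end without access
to the original recordings (which are not publicly deposited).

## Edge ranking and thresholding

Sparsity thresholding is purely rank-based, which has two consequences
worth stating explicitly. First, any monotone transformation of the
correlations (Fisher z, uniform shifts) leaves every binarized graph
unchanged — hence no z-transform is applied before thresholding; z
enters only in edgewise inference, where it stabilizes variances.
Second, the ranking criterion matters only through which edges change
rank: the default ranks by signed correlation descending (binarized
functional connectomes conventionally exclude negative edges), and an
`absolute` mode ranks by |r|. Ties break by lexicographic node order,
making edge sets reproducible and nested across the sweep. The
edge-count boundary uses half-away-from-zero rounding.

The sweep's default range reproduces the range over which group
results are reported (0.08–0.48); the wider 8–50% methods-style range
is one configuration flag away.

## Path length on fragmented graphs

At 8% density a 35-node graph often fragments. The default `lp`
convention (`exclude`) averages geodesics over connected pairs only and
records the component count; a `largest-component` mode is also
implemented. Global efficiency needs no convention (disconnected pairs
contribute 0), which is why Eglob is the better-behaved integration
metric at low densities — and why the two can move in opposite
directions on the same data. Degree-0/1 nodes contribute 0 to Cp and
Eloc rather than being dropped, keeping the averaging denominator at N
for every subject.

## Null models

Nulls are degree-preserving double-edge swaps (10 successful swaps per
edge by default, the standard mixing heuristic), not forced to be
connected; null Lp uses the same disconnection rule as the empirical
graph so λ is not biased by asymmetric handling. 100 nulls per graph
is the default; the test suite scales this down since the AUC
integrates 41 levels and averages most of the ensemble noise away.
Graphs admitting no legal swap (complete graphs) return unchanged with
a warning — which doubles as the self-normalization identity
γ = λ = σ = 1.

A structural fact about λ: as density grows the degree-preserving null
approaches the graph itself, so per-subject λ at the top of the sweep
is 1 + O(0.005) and its sign is uninformative subject by subject. The
small-world criterion λ > 1 is therefore evaluated on group-mean
curves; per-subject criteria are meaningful for γ and σ.

## Covariate adjustment

Unpaired contrasts residualize the AUCs on age, sex (male = 1) and
mean frame-wise displacement pooled over the two groups, then apply a
Student t test to the residuals — the simplest auditable reading of
"included as covariates", equivalent to an ANCOVA group term up to
degrees-of-freedom bookkeeping. The paired contrast cannot residualize
the differences (an intercept would absorb the tested mean); it
instead tests the intercept of `lm(diff ~ centered covariates)`, with
ΔFD as the motion covariate. Covariate columns that are constant in a
given sample, or designs too small to support adjustment, fall back to
unadjusted tests. The FDR family is all metric × contrast tests of one
analysis run; two-sided tests throughout.

## NBS: extent, intensity, and the primary threshold

The NBS forms components from edges whose |t| exceeds a primary
threshold (default: the t-value at p = 0.01 for the design's df) and
compares each component's statistic against the permutation
distribution of the maximum (group-label exchange for unpaired
designs, per-pair sign flips for paired ones; add-one p-values, never
exactly 0). Two component statistics are implemented: **extent** (edge
count, the original formulation, the default) and **intensity**
(supra-threshold |t| mass).

The choice matters. An isolated single-edge effect has extent 1, and
under the null the maximum component extent is ≥ 1 whenever *any* of
the 595 edges crosses the threshold — which at p = 0.01 happens almost
surely. The extent statistic is therefore structurally blind to focal
effects, however strong. The recovery analyses of the planted
single-edge hyperconnectivity reductions consequently use the
intensity statistic with a strict primary threshold (p = 1e-4): strict
thresholds both favor focal, high-intensity effects and de-chain the
permutation null, which in paired designs is additionally inflated by
treatment-effect heterogeneity (responder/non-responder mixtures make
sign-flip nulls heavy-tailed). Broad, distributed effects — such as
the responder-vs-non-responder comparison of change matrices — are
detected well by the default extent configuration.

## The synthetic cohort generator

The generator is the package's ground truth and defines the study
conditions; its defaults are fixed, documented here, and not tuned per
analysis.

**Population correlation model.** Pair (i, j) has correlation
`base(i,j) + r_dist · exp(−d_ij / dist_scale)`, where `base` is
`r_within` (0.20) inside an anatomical module and `r_between` (0.10)
between modules, `d_ij` is Euclidean distance between the atlas MNI
coordinates, `r_dist` = 0.60 and `dist_scale` = 30 mm. The distance
term reflects the well-replicated decay of functional coupling with
anatomical distance and is what keeps thresholded graphs in the
small-world regime across the whole sweep: a pure block model
fragments into cliques at low density (λ < 1), whereas the
distance-decay backbone yields connected, lattice-like graphs with
σ, γ, λ > 1 at every level. The five modules (temporal, prefrontal,
subcortical, parietal, visual) are a packaged mapping over the
35-node atlas, editable as a TSV.

**Planted patient effects.** Three mechanisms, chosen for their
topological consequences under fixed-density thresholding:

* *Segregation deficit* (0.06): subtracted from within-module
  correlations; lowers Cp, Eloc, γ and hence σ.
* *Integration deficit* (0.45): subtracted from every correlation
  incident to three integration-hub nodes (posterior cingulate, medial
  prefrontal, inferior parietal — canonical default-mode hubs).
  Because thresholding is rank-based, mild uniform weakening merely
  reshuffles edges and — counterintuitively — *raises* global
  efficiency by randomizing the sampled ranking; only nodes weakened
  enough to lose the rank competition disconnect, which is the one
  mechanism that lowers Eglob at fixed density. The magnitude is
  therefore large relative to the segregation deficit.
* *Hyperconnectivity* (+0.20) on two designated edges, TPJ.L–LPFC.L
  and MTG.R–DPUT.R, elevated above their control-level value at
  baseline. The hub set is deliberately disjoint from these endpoints
  so focal hyperconnectivity and hub disruption remain separable; a
  weakened hub that is also a hyper-edge endpoint would be further
  disconnected by the post-treatment hyper-edge reduction, masking the
  efficiency recovery in non-responders.

**Treatment response.** Exactly `round(0.675 · n)` patients are
responders. Responders draw fractional AHRS reductions uniformly in
[0.50, 0.75] and non-responders in [0.05, 0.45] — spanning the
reported mean reduction (≈ 48%) while keeping the boundary
unambiguous — and responders reverse 80% of both deficits
post-treatment. Each patient's hyper-edge z-reduction is
`0.015 · ΔAHRS + N(0, 0.05)`, giving a positive edge-change/symptom
coupling. Baseline AHRS is N(25.2, 5.1), ages ≈ 24.5 ± 5.8 years, FD
≈ 0.28 ± 0.05 mm, matching the study marginals.

**Observation model.** Time series are `t_len` = 180 i.i.d. Gaussian
draws from the population correlation (Cholesky factor) plus white
noise (sd 0.4); Pearson correlation assumes second-order structure
only, so no hemodynamic or autocorrelation model is attempted.
Matrices that leave the PSD cone after the subtractive deficits are
repaired by eigenvalue clipping and rescaling to unit diagonal (the
repair is flagged on the returned matrix and shifts entries by < 0.01
at the default parameters). What passing tests show is that the
*pipeline* recovers planted second-order structure at the study's
sample sizes; they cannot certify behavior under hemodynamic
confounds, autocorrelated noise, or motion artifacts real data carry.

**Effect magnitudes** are free fixture parameters: the source analyses
report significance, not effect sizes, so magnitudes cannot be copied.
The defaults above were calibrated once, during generator design,
to make every planted effect detectable at the study's sample sizes
(47 HC, 40 patient pairs) while preserving the small-world regime in
both groups, and are not revisited per run.

## Numerical choices and degenerate inputs

* Correlations of constant (zero-variance) series are set to 0 with a
  warning; series shorter than 30 timepoints warn but load.
* Sparsities yielding zero edges error (`degenerate sparsity`), as do
  edgeless graphs asked for Lp, zero-variance t tests, and n < 3
  correlations.
* Fisher z clips inputs to ±(1 − 1e−7) so unit correlations stay
  finite.
* Seeds: every stochastic stage of `runPipeline()` consumes a seed
  derived deterministically from the master seed plus the stage name
  (a small integer hash, kept below 2³¹), so whole-run reproducibility
  is a tested guarantee while stages stay independent.
* The ROI extractor averages voxels whose affine-mapped centers fall
  within a 6 mm sphere (configurable) of each node coordinate — the
  field convention for coordinate-defined nodes; empty spheres warn
  and yield zero columns.

## The packaged atlas and its anomalies

The 35-row atlas fixture preserves the printed table verbatim,
including its anomalies: two coordinate-duplicate row pairs (20/33,
both labeled PCC at (3, −39, 20), and 8/34 at (24, 7, −19)) and
left-tagged abbreviations on two right-hemisphere rows (13, 34). The
loader flags all of them in a validation report and a `dedupe` option
collapses exact-coordinate duplicates; the default keeps fidelity to
the printed table, since whether the duplicates are intentional is not
decidable from the source.

## Problem sizes used in the tests

The test suite exercises the full 41-level sweep but scales ensemble
sizes to what the checks need: 20 null graphs per level for the
small-world criteria (their group means integrate over 41 levels, so
ensemble noise is second-order), 4 nulls and 150 permutations inside
the 50-replicate recovery study, and 200 permutations for the
200-replicate NBS calibration. The acceptance script uses the full
100-null ensembles.

## Known limitations

* The pipeline consumes preprocessed ROI series; no fMRI preprocessing
  (motion correction, filtering, nuisance regression) is included.
* Weighted-network and negative-edge metrics are out of scope, as are
  lattice-referenced small-world variants (ω, SWP), hub/betweenness
  analyses, and longitudinal mixed models.
* The NBS primary threshold, permutation scheme and count in the
  original analysis are unreported; all are explicit configuration
  with logged defaults, and component-level conclusions are
  conditional on the primary threshold.
* The generator's Gaussian, temporally white observation model is a
  deliberate simplification; autocorrelation would widen sampling
  variability of correlations relative to what the tests assume.
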