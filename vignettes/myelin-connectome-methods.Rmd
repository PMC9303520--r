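---
title: "Methods: myelin-weighted connectome analysis with PLS and epicenter rings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: myelin-weighted connectome analysis with PLS and epicenter rings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis in one paragraph

`r1connectome` analyzes brain networks whose edge weights are the
longitudinal relaxation rate R1 (1/T1, in s⁻¹), a quantitative MRI metric
sensitive to myelin content. A subject's connectome assigns each pair of
parcellation regions the median R1 sampled along the bundle of tractography
streamlines joining them. Group connectomes keep edges present in at least
half the subjects, weighted by the cross-subject median. Group differences
and brain–behavior relationships are tested with partial least squares
(PLS) on the subjects × edges matrix: singular value decomposition of a
cross-block matrix, permutation tests on the singular values, and bootstrap
ratios (BSR) for edge-level reliability. An epicenter ring analysis then
asks whether edges directly connected to candidate disease-origin regions
(substantia nigra, nucleus basalis of Meynert, hippocampus, amygdala,
medulla, pons, midbrain, locus coeruleus) show lower R1 than edges one step
further out, using ANCOVA adjusted for age and sex with
Benjamini–Hochberg FDR correction.

## Connectome construction

A streamline is assigned to the unordered region pair whose two label
blocks contain its first and last point; streamlines touching background
or leaving the volume are discarded (with a logged count). Coordinates are
0-based with the voxel-center convention. R1 is sampled by resampling each
streamline at a uniform 0.5-voxel arc-length step and interpolating the
volume trilinearly. The edge weight is the *pooled* median over all
samples of all streamlines in the bundle; a median-of-per-streamline-medians
variant is available via `compute_edge_weight(method = "per_streamline")`
for sensitivity checks. The pooled reading was adopted because the weight
is described as one median along the bundle; neither the interpolation
scheme nor the step is prescribed anywhere, so both are explicit,
documented defaults.

The consensus rule is implemented as `count/total >= fraction`: an edge
present in exactly 50% of subjects is retained ("at least 50%"). The
consensus weight is the median over the subjects in which the edge is
present; pooling absent edges as zeros would bias R1 downward and was
rejected.

## PLS

*Mean-centering mode.* The cross-block matrix has one row per group: the
group's edge means minus the unweighted mean of the group means. Balanced
(unweighted) centering was chosen so that the 35-versus-81 imbalance of
the emulated cohort does not tilt the contrast; the alternative (weighted
grand mean) is a one-line change but is not exposed because mixing the two
conventions silently is a classic source of irreproducibility.

*Behavioral mode.* The cross-block stacks within-group Pearson
correlations of each clinical score with each edge (correlation rather
than covariance, the standard behavioral-PLS practice; covariance is
available behind `mode = "covariance"`).

The SVD sign convention fixes each latent variable so its
largest-magnitude edge salience is positive. Permutation p-values follow
the plain-proportion definition `#(λ_perm ≥ λ_obs)/n_perm` — they can be
exactly 0 — with an add-one variant behind a flag. Bootstrap resampling is
within group; replicate saliences are aligned to the original by the sign
of their dot product (full Procrustes alignment was considered and
rejected: for the LV-at-a-time BSR it reduces to the sign rule). The
default |BSR| threshold is 2.56 as conventionally printed for a 99%
confidence band, although the exact two-sided normal quantile is 2.576;
both are accepted by `threshold_reliable_edges()`. Degenerate bootstrap
resamples (a group collapsing to identical rows, or a zero-variance score
column) are redrawn up to a retry budget.

## Ring analysis

Rings are defined on a single reference adjacency — the pooled-cohort
(both groups) presence consensus — so ring membership is identical across
groups. First ring: nodes directly connected to an epicenter node. Second
ring: nodes reachable only through one first-ring node; a node adjacent to
both an epicenter and a first-ring node stays in the first ring. First-ring
edges join epicenter to first ring; second-ring edges join first ring to
second ring; edges among first-ring nodes belong to neither. Per subject
and ring the median R1 is taken over the ring edges that subject possesses
(absent edges are dropped, not imputed — the median is robust and presence
varies by subject). The group comparison is an ANCOVA of the ring medians
on group (healthy controls vs pooled PD; a subgroup mode is available via
`pool_pd = FALSE`) with age and sex (F = 0, M = 1) as covariates, with BH
FDR across all epicenter × ring tests run in the session. Epicenter-internal
R1 is compared with pooled-variance two-sample t tests (Welch optional).

## The synthetic cohort generator

No patient data ship with the package; the generator emulates the
statistical structure the analysis assumes, with defaults frozen to the
emulated study's conditions:

* **Cohort**: 35 healthy controls, 59 PD without RBD, 22 PD with RBD.
  Ages are truncated normals ([35, 90] years) at the published group
  moments (HC 61.2 ± 9.16, PD subgroups 60.83 ± 10.21 and 63.86 ± 7.47);
  sex is Bernoulli at the published proportions; clinical scores
  (MDS-UPDRS III off-medication, Hoehn & Yahr, MMSE, MoCA, Mattis DRS,
  disease duration) are independent normals at the published group
  moments, clipped to each instrument's range. Inter-score correlation is
  not modeled, except that the pipeline overwrites the PD motor score
  with the behavior-coupled draw when behavioral PLS is exercised.
* **Template network**: a connected Erdős–Rényi graph, 40 nodes at
  density 0.2564 (200 edges), baseline edge weights uniform on
  0.55–1.15 s⁻¹ (an R1-plausible band for white matter at 3 T). Eight
  bilateral epicenter groups occupy nodes 0–15.
* **Disease effect**: a subject's edge weight is
  `baseline × s × (1 − δ·affected·is_PD) + ε`, with `s` a shared
  lognormal subject scaling (sdlog 0.02, mimicking between-scan R1
  calibration differences) and `ε` independent normal edge noise
  (SD 0.02 s⁻¹). δ defaults to 0.05 — a free parameter: no effect size
  for the R1 reduction is published, so δ was fixed once at a value
  producing realistic (not saturated) single-edge effects. 40 affected
  edges are drawn preferentially incident to epicenter nodes;
  `n_affected_edges = NA` plants on *every* epicenter-incident edge, the
  pure first-ring disease model used by the ring tests.
* **Dropout**: edge presence is independent Bernoulli per subject-edge;
  by default 5% of edges form a weak tail at presence 0.7, exercising the
  consensus rule without dominating the analysis.
* **Behavior**: the score is
  `intercept + slope × (mean R1 deficit on a planted 8-edge subnetwork) + noise`
  (slope 250 score-units per s⁻¹, noise SD 4, intercept 30), scaled so
  simulated motor scores have a realistic range and a strong but not
  deterministic coupling.
* **Phantom**: nodes become disjoint voxel cuboids, each template edge a
  straight one-voxel-dilated corridor of known constant R1 with a
  matching two-point streamline, so recovered edge weights have an exact
  ground truth.

Every generator is a pure function of its arguments including the seed.
Per-subject streams are derived from the model seed and the subject id
through a rolling hash plus multiplicative-congruential mixing, which was
verified to keep subjects exchangeable under the null (a structured
id-to-seed map can otherwise bias permutation tests).

What the generator does *not* emulate: spatial structure of real
parcellations, tractography biases (bundle length, curvature, seeding
density), correlated clinical scores, site effects, and any relation
between demographics and edge weights. Passing tests therefore certify the
statistical machinery — identities, calibration, recovery under the
assumed generative model — not performance on real MRI data.

## Numerical choices and problem sizes

Tolerances: SVD energy identity to 1e-8, salience orthonormality to 1e-10,
ANCOVA F against the nested-model oracle to 1e-8, phantom weights to 1e-6,
BH-FDR to 1e-12. Even-count medians use the midpoint convention. Weights
are clipped positive at 1e-6 s⁻¹. Ties in the consensus rule are retained.

The test and acceptance runs use the full cohort sizes (n = 116) with 500
permutations and 500 bootstraps for single runs, and reduced replicate
counts for Monte-Carlo properties: 200 null replicates at 100 permutations
for type-I control, 20 replicates for planted-edge recovery and for the
ring contrast. These sizes give binomial error bands tight enough to
detect miscalibration while keeping a full run in about a minute.

## Known limitations

* The behavioral PLS reports the signed correlation between LV scores and
  the clinical score; sign interpretation is left to the user (the sign of
  an LV is a convention, and published summaries sometimes mix the two).
* Whether the original analysis ran PLS on the consensus edge set or on
  all edges is not stated; the consensus set is the default here.
* Whether rings were defined on a group-level or per-subject adjacency is
  not stated; the pooled-cohort consensus is the default, and
  `derive_reference_adjacency()` accepts any subject subset if a
  group-specific adjacency is wanted.
* Fisher's exact test and nonparametric ANCOVA are out of scope; the
  chi-square is asymptotic by design.
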