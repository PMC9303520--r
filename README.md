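# r1connectome

Myelin-weighted structural connectome analysis for case–control cohorts:
R1-weighted connectome construction, consensus group connectomes, partial
least squares (PLS) inference, epicenter ring analysis, and cohort
demographics — with a synthetic cohort generator so the full pipeline is
testable without patient data.

## The problem

Quantitative MRI can map the longitudinal relaxation rate R1 (1/T1, s⁻¹),
a myelin-sensitive metric. Weighting each white-matter connection of a
tractography-derived brain network by its median R1 turns the connectome
into a myelin-weighted graph, and neurodegenerative demyelination — as in
Parkinson's disease (PD) — becomes a question about edge weights: *which
connections lose R1, do they concentrate around candidate disease
epicenters, and do they track motor severity?*

This package implements that analysis chain for researchers in imaging
neuroscience:

1. **Connectome construction** — assign streamlines to region pairs by
   their endpoints, sample an R1 volume trilinearly along each streamline
   (uniform arc-length resampling), and weight each edge by the pooled
   median over its bundle. Group connectomes keep edges present in ≥ 50%
   of subjects, weighted by the cross-subject median.
2. **PLS** — for the group contrast, the cross-block matrix **R** holds
   each group's mean-centered edge means; for behavior, the within-group
   correlations of clinical scores with edges. Its SVD
   **R** = **U S Vᵀ** yields latent variables: design saliences **U**,
   edge saliences **V**, singular values *λₖ*. Significance is assessed by
   permutation (*pₖ* = #(λₖᵖᵉʳᵐ ≥ λₖᵒᵇˢ)/n_perm) and edge reliability by
   bootstrap ratios BSR = salience / bootstrap SE, thresholded at
   |BSR| > 2.56 (≈ 99% confidence).
3. **Ring analysis** — around each candidate epicenter (SN, NBM,
   hippocampus, amygdala, medulla, pons, midbrain, LC), the first ring
   collects edges to directly connected nodes and the second ring edges
   from those nodes one step further. Per-subject ring medians are
   compared between groups by ANCOVA (adjusting for age and sex) with
   Benjamini–Hochberg FDR across all epicenter × ring tests.
4. **Cohort statistics** — Kruskal–Wallis, uncorrected 2×2 chi-square,
   pooled/Welch t, Pearson r, BH-FDR, and a Table-1-style demographics
   summary.

## Worked example

Simulate the default synthetic cohort (35 healthy controls, 59 PD without
RBD, 22 PD with RBD on a 40-node, 200-edge template with a 5% R1
reduction planted on 40 edges), then run the contrast PLS and a ring
analysis:

```r
library(r1connectome)

tpl <- generate_template_network(seed = 11)
man <- generate_manifest(35, 59, 22, seed = 12)
mod <- effect_model(delta = 0.05, seed = 13)
cns <- generate_cohort_connectomes(tpl, man, mod)

ei <- consensus_edge_index(build_group_connectome(cns))
dm <- assemble_data_matrix(cns, ei,
                           groups = ifelse(man$group == "HC", "HC", "PD"))
fit  <- pls_svd(mean_center_by_group(dm$X, dm$groups), X = dm$X)
perm <- permutation_pvalues(dm$X, groups = dm$groups, n_perm = 500, seed = 14)
boot <- bootstrap_ratios(dm$X, groups = dm$groups, lv = 1, n_boot = 500, seed = 15)
rel  <- threshold_reliable_edges(boot$bsr, dm$edge_index,
                                 labels = tpl$nodes$label)
```

This prints (via `cat`/`print` as in the example script):

```
consensus edges: 200
LV1 singular value: 0.1856   perm p: 0
reliable edges (|BSR| > 2.56): 40
        node_i             node_j      bsr direction
 hippocampus_L  ctx_temporal_L_03 13.61248  positive
    amygdala_L ctx_occipital_L_01 13.60874  positive
         NBM_L ctx_occipital_R_02 13.48875  positive
```

LV1 separates the groups (no permuted singular value reaches the observed
one in 500 permutations), and the 40 edges passing |BSR| > 2.56 are
exactly the 40 planted edges — positive saliences mean higher R1 in
controls, i.e. the planted PD reduction. The ring analysis around the
substantia nigra shows the first-ring/second-ring dissociation the planted
(epicenter-incident) effect implies:

```r
adj <- derive_reference_adjacency(cns)
rd  <- define_rings(adj, tpl$epicenters$SN, "SN")
compare_ring_groups(ring_subject_medians(cns, list(rd)), man)
#  epicenter   ring   n          F            p            q
#         SN  first 116 50.6033326 1.134315e-10 2.268629e-10
#         SN second 116  0.4135713 5.214769e-01 5.214769e-01
```

Cohort tables use the same kernel; for instance the sex-by-group
comparison of a 81-PD / 35-control cohort with 52/29 vs 12/23 F/M:

```r
chi_square_2x2(matrix(c(52, 29, 12, 23), 2, byrow = TRUE))$p
# [1] 0.002944985
```

`run_pipeline(pipeline_config(seed = 1), "out/")` chains all stages
(simulate → consensus → PLS contrast → behavioral PLS → rings →
demographics) and writes TSV/JSON artifacts; re-runs are bit-identical.
A thin CLI wrapper lives at `inst/cli/r1connectome-cli.R`.

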