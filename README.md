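# connectogcn

Classification of multisite resting-state functional connectomes with a
graph convolutional network (GCN), and everything around it: Fisher-z
Pearson connectivity, parametric empirical-Bayes ComBat harmonization of
edge-level site effects (with a before/after audit), per-subject
K-nearest-neighbour graph encoding, exact class-activation-mapping (CAM)
node saliency, a nested cross-validated linear SVM baseline, and post hoc
nodal topology statistics (degree, efficiency, betweenness) with
permutation tests and POMP-standardized symptom correlations.

The package is written for neuroimaging researchers who pool case-control
rs-fMRI cohorts across scanners and want a tested, reproducible pipeline
from ROI time series (or precomputed connectivity matrices) to a
cross-validated classifier with interpretable region-level saliency.
Because cohorts of this kind are rarely deposited, a seeded synthetic
multisite cohort generator with the statistical structure the analysis
assumes (505 patients / 907 controls over 6 sites by default, one site
contributing controls only) makes every stage testable end to end.

## The core model

Each subject's connectome is a weighted graph `G = (V, E, W)`: one node per
atlas region (90 by default), node features = the region's row of the
Fisher-z connectivity matrix, adjacency = union-symmetrized KNN on
Euclidean distance between node features (k = 10, Gaussian edge weights).
With the renormalized operator `Ŵ = D̃^{-1/2}(W + I)D̃^{-1/2}`, the
classifier is

    H⁽⁰⁾ = X;   H⁽ˡ⁺¹⁾ = ReLU(Ŵ H⁽ˡ⁾ Θ⁽ˡ⁾);   logit_c = w^c · mean_v H⁽ᴸ⁾_v + b_c

i.e. graph convolutions → global average pooling → one linear head. That
topology makes CAM exact: the node score `M_c(v) = Σ_k w^c_k H⁽ᴸ⁾_vk`
satisfies `mean_v M_c(v) = logit_c − b_c` identically, so region saliency
is a lossless decomposition of the class logit rather than a gradient
approximation. Site effects are removed beforehand by ComBat
(`y = α + xᵀβ + γ_site + δ_site·ε` per edge, empirical-Bayes shrinkage of
γ, δ across edges, diagnosis/age/sex protected as covariates). Models are
evaluated by stratified 10-fold and leave-one-site-out cross-validation
with balanced accuracy, sensitivity, specificity and AUC.

## Worked example

A small synthetic run, end to end (about a minute on one CPU):

```r
library(connectogcn)

cfg <- list(
  seed = 42L,
  cohort = list(n_regions = 30L,
                site_sizes = list(c(20L, 20L), c(0L, 15L), c(20L, 20L)),
                n_timepoints = 120L, effect_size = 0.5),
  graph = list(k = 8L),
  model = list(kind = "gcn", gcn = list(widths = c(32L, 32L), max_epochs = 60L)),
  cv = list(scheme = "kfold", k = 5L),
  topology = list(sparsity = 0.2, n_perm = 2000L))

res <- run_pipeline(cfg)
print(res$cv_report)
#> cv_report [gcn, kfold, harmonization after]: balanced accuracy 100.0% (95% CI 100.0-100.0)
#>   sensitivity 100.0%, specificity 100.0%, AUC 1.000; 5 fold(s)
print(res$site_audit$before)
#> site_effect_scan [control]: 428 of 435 edges significant (98.4%) at FDR q=0.05
print(res$site_audit$after)
#> site_effect_scan [control]: 8 of 435 edges significant (1.8%) at FDR q=0.05
head(res$saliency$ranking, 5)
#>   region name mean_activation rank
#> 1     14 R014       -4.497073    1
#> 2     23 R023       -4.448200    2
#> 3     20 R020       -4.444208    3
#> 4     11 R011       -4.170471    4
#> 5      2 R002       -4.133857    5
```

Reading the output: the per-edge ANOVA audit drops from 98.4% of edges with
significant cross-site differences to 1.8% after harmonization; the
classifier separates the groups perfectly at this effect size (0.5); and
the top salient regions are exactly the generator's planted signal nodes
(here 2, 5, 8, ..., 29 — the cohort used 10 evenly spaced signal regions),
with *negative* mean activations because the planted effect is
hypoconnectivity: the affected regions vote against the patient class when
connectivity is intact. Downstream, `res$group_differences` shows
FDR-significant decreases in degree/efficiency at those regions and
`res$symptom_correlations` recovers the negative correlation between their
nodal efficiency and negative-symptom POMP scores, e.g.

```
          variable  symptom  n          r            p fdr_significant
48 efficiency.R008 negative 40 -0.5703057 0.0001220558            TRUE
```

At full scale (`default_pipeline_config()`: 90 regions, 6 sites, 1412
subjects), the same pipeline runs the study-sized analysis; a thin CLI
wrapper lives at `inst/cli/connectogcn.R`
(`Rscript inst/cli/connectogcn.R run --seed 1 --out runs/demo`).

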