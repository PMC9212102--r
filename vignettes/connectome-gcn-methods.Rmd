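---
title: "Classifying multisite functional connectomes with graph convolutional networks"
author: "connectogcn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying multisite functional connectomes with graph convolutional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectogcn)
```

## The analysis problem

Resting-state fMRI studies of psychiatric disorders increasingly treat the
brain as a network: regional BOLD time series are parcellated into atlas
regions, pairwise Pearson correlations form a functional connectivity
matrix, and group differences are sought at the level of network topology
rather than single connections. Two practical obstacles dominate when such
cohorts are pooled across acquisition sites:

1. **Site (batch) effects.** Scanner hardware and sequence parameters shift
   and rescale connectivity estimates per site, often more strongly than the
   diagnostic effect of interest.
2. **Network-level signal.** Classifiers built on independent edges (e.g. a
   linear SVM on the vectorized upper triangle) ignore the neighborhood
   structure that makes a connectome a graph.

`connectogcn` implements the full analysis chain: connectivity estimation
with Fisher r-to-z stabilization, edge-level ComBat harmonization with a
before/after audit, per-subject KNN graph encoding, a graph convolutional
network (GCN) classifier with exact class-activation-mapping (CAM) node
saliency, a nested cross-validated linear SVM baseline, and post hoc nodal
topology statistics with symptom correlations. Because clinical MRI
cohorts of this kind are not publicly deposited, the package also ships a
seeded synthetic multisite cohort generator with the statistical structure
the analysis assumes, so every stage is exercised end to end by the test
suite.

## The models

### Connectivity and harmonization

For subject $i$ the feature matrix is the region-by-region matrix of
Fisher-transformed correlations, $z = \operatorname{atanh}(r)$ with $r$
clipped at $\pm(1 - 10^{-7})$ and the diagonal fixed at 0 (self-connectivity
carries no information and a zero diagonal keeps KNN distances finite). The
canonical edge ordering everywhere is the row-major strict upper triangle,
so 90 regions yield $90 \cdot 89 / 2 = 4005$ edge features.

Harmonization follows the parametric empirical-Bayes ComBat model per edge
$e$, subject $i$ of site $s$:

$$y_{ise} = \alpha_e + x_i^\top \beta_e + \gamma_{se} + \delta_{se}\,\varepsilon_{ise}$$

Per-site location $\gamma$ and scale $\delta$ are estimated on standardized
residuals, shrunk across edges via moment-matched normal / inverse-gamma
priors (iterative conditional updates to relative tolerance $10^{-6}$, at
most 100 iterations), and removed while the covariate effects (diagnosis,
age, sex) and the pooled variance are restored. Protecting diagnosis as a
covariate is essential: removing site means without it would also remove
part of the case-control contrast, since sites differ in case mix. The
implementation is written in this package and is checked in the test suite
against `sva::ComBat` (agreement to ~1e-6 on a shared fixture). Two
conventions worth knowing:

* The pooled variance uses the $/n$ denominator of the reference
  implementation. A consequence, asserted exactly in the tests, is that a
  second location/scale pass is not a strict no-op but a deterministic
  shrink of $\sqrt{(n-k)/n}$ toward the grand mean.
* EB shrinkage trades per-edge unbiasedness for stability, so exact-removal
  identities (e.g. a pure additive shift vanishing to machine precision)
  hold for the unshrunk estimator (`eb = FALSE`); with shrinkage the
  residual site differences are instead verified to be statistically
  invisible (the audit below).

The audit (`site_effect_scan`) runs a per-edge one-way ANOVA across sites
within a diagnostic subgroup and applies Benjamini–Hochberg FDR at
$q = 0.05$. On the default synthetic cohort the percentage of flagged edges
moves from well above 50% before harmonization to 0% after, the qualitative
signature reported for this analysis on clinical data.

### Graph encoding

Each subject's graph has one node per region; the node feature is the
region's connectivity profile (its row of the z-matrix). The adjacency is
built by K-nearest neighbours on Euclidean distance between node features
(`k = 10` by default, following the sensitivity analysis of the source
analysis; ties broken by lower region index), symmetrized by union
($W_{ij} = \max(w_{ij}, w_{ji})$). Edge weights are Gaussian,
$w = \exp(-d^2 / 2\sigma^2)$ with $\sigma$ the mean selected distance;
binary weights are retained for ablation since the upstream description
does not fix the kernel. Graph convolution uses the renormalized operator

$$\hat W = \tilde D^{-1/2} (W + I)\, \tilde D^{-1/2},$$

whose spectral radius is at most 1.

### GCN classifier and exact CAM

The classifier is deliberately restricted to the topology that makes CAM
exact: graph convolutions, global average pooling (GAP), and a single
linear head,

$$H^{(0)} = X,\quad H^{(l+1)} = \mathrm{ReLU}(\hat W H^{(l)} \Theta^{(l)}),\quad
\mathrm{logit}_c = w^c \cdot \tfrac1a \textstyle\sum_v H^{(L)}_{v\cdot} + b_c.$$

The CAM node score $M_c(v) = \sum_k w^c_k H^{(L)}_{vk}$ then satisfies the
GAP-CAM identity $\frac1a \sum_v M_c(v) = \mathrm{logit}_c - b_c$, asserted
to 1e-8 for every trained model in the test suite. Defaults: three conv
layers of widths 64/64/128, Adam (learning rate $10^{-3}$, weight decay
$5\times10^{-4}$), minibatches of 32, at most 200 epochs with early
stopping (patience 20) on a stratified 10% validation split of the training
data only, inverse-frequency class weights (the default cohort is 505
patients vs 907 controls). The upstream description defers these
hyperparameters to a supplement; the values here are this package's
declared defaults, all exposed in `gcn_config()`. Training is pure R on
double precision, with per-minibatch graphs stacked into one sparse
block-diagonal adjacency so each step is a handful of BLAS calls, and is
bitwise reproducible given the seed.

**Saliency ranking.** Per-subject CAM scores are averaged across subjects
and ranked by the *magnitude* of the mean activation (`aggregate_saliency`,
`rank_by = "magnitude"`). In a two-class softmax the node-wise evidence for
one class is exactly the evidence against the other, so magnitude ranking
makes the patient-class and control-class maps identical — the behaviour
described for this analysis — and is the right convention when the planted
group effect is hypoconnectivity, which contributes large *negative*
patient-class activations at the affected nodes. The signed ranking is
available via `rank_by = "signed"`.

### SVM baseline and region weights

The baseline is a linear hinge-loss SVM (via `e1071`/libsvm) on the 4005
upper-triangle edges, with the regularization constant selected from
$\{10^{-3}, \dots, 10^{3}\}$ by an inner stratified 10-fold grid search
maximizing balanced accuracy, then refit on the full training set. A
region's weight is the mean over its 89 incident edge weights — absolute
values by default (saliency should reflect contribution magnitude; the
signed mean is available), averaged across CV folds when fold weights are
supplied.

### Nodal topology and symptom correlations

Subject networks are thresholded to a fixed sparsity (default 0.20, the
top 20% of positive edges by weight; negative Fisher-z edges are never
retained because path-length semantics need nonnegative weights — the
upstream toolbox convention). For the top-10 salient regions three
centralities are computed: strength (weighted degree), nodal efficiency
$E(i) = \frac{1}{N-1}\sum_{j \ne i} 1/d_{ij}$ and betweenness, both
path-based metrics using edge length $1/w$ (shortest paths via igraph;
verified against brute-force Floyd–Warshall and path-enumeration oracles on
hundreds of random graphs). Group differences use a two-tailed permutation
test on the difference of group means (10,000 seeded permutations,
$p = (1 + \#\{|T^\ast| \ge |T|\})/(n_{\mathrm{perm}}+1)$), BH-FDR corrected
across the regions-by-metrics family, the GCN-derived and SVM-derived
salient sets tested separately. Symptom scores are standardized to POMP
(percent of maximum possible, $100\,(x - \min)/(\max - \min)$, scale bounds
carried in the subject table rather than hard-coded) and related to nodal
centralities by complete-case Pearson correlation with BH-FDR across the
metric-by-symptom family.

### Cross-validation and metrics

Two schemes mirror the study design: pooled stratified k-fold (default 10)
and leave-one-site-out (LOSO), in which each site with both classes is held
out once and single-class sites (the control-only site) remain in training
and are reported as skipped. Metrics are balanced accuracy
(mean of sensitivity and specificity — the identity is asserted on every
report row), sensitivity, specificity, and midrank Mann–Whitney AUC. 95%
CIs use a normal approximation across fold estimates; for LOSO, where only
a few site-level estimates exist, a 1000-resample bootstrap over pooled
test subjects is used instead, and the method is stamped into the report.
The CI construction is not specified upstream; this is the package's
declared choice. Harmonization is fitted on the pooled cohort before CV
splitting, replicating the upstream order of operations; this leaks
distributional information across folds, so a strict fold-wise mode
(`harmonize$within_folds`, fit on training subjects, applied to held-out
subjects via `combat_apply`) is provided.

## The synthetic cohort generator

`synth_config()` defaults encode the study conditions: six sites with
(patients, controls) = (301, 217), (0, 340), (49, 63), (32, 83), (67, 72),
(56, 132) — 505 patients and 907 controls, one control-only site — 90
regions, 200 time points.

* **Control covariance.** $R = 0.1\,J + \text{blockdiag}$: background
  correlation 0.1 everywhere, within-network blocks of 15 regions at 0.4,
  and a signal subnetwork of 10 regions (defaults at AAL-like bilateral
  amygdala/striatal/pallidal/thalamic positions 41, 42, 71–78) mutually
  correlated at 0.6. Signal nodes are detached from their anatomical block,
  which makes the matrix provably positive semidefinite for any signal
  correlation down to 0 — a naive "raise this block" construction is
  indefinite.
* **Group effect.** Each patient draws an individual hypoconnectivity
  magnitude $m_i \sim N(\text{effect}, (\text{effect}/3)^2)$, truncated to
  keep the signal correlation in $[0.005, 0.6]$; their signal-pair
  correlation is $0.6 - m_i$. Hypoconnectivity (rather than mixed-sign
  effects) is chosen because it produces the decreased nodal efficiency at
  the affected regions that the post hoc analysis is meant to recover.
* **Site effects** are injected at the Fisher-z edge level (where ComBat
  operates): per site and edge, additive $\gamma \sim N(0, 0.3^2)$ and
  multiplicative $\delta \sim N(1, 0.2^2)$ truncated positive. They are
  drawn independently of diagnosis, so harmonization cannot cheat by
  removing the group effect.
* **Symptoms.** Patients' negative-symptom score maps a standardized
  combination of their effect magnitude (weight = coupling, default 0.6)
  and noise onto a declared 7–49 scale, clipped to bounds; the positive
  score is uncoupled noise. Controls have no scores.

What the generator does **not** emulate: raw 4D volumes, head motion and
physiological noise, autocorrelated BOLD dynamics (time points are i.i.d.
draws from the subject covariance), heavy-tailed edge distributions, or
site-by-diagnosis interactions. Passing tests therefore demonstrate that
the pipeline recovers planted effects under its own model assumptions — a
necessary correctness property — not that it would achieve any particular
accuracy on real patients.

## Numerical and design choices

* Seeds: every stochastic step (generation, site draws, fold assignment,
  network initialization and shuffling, permutation tests, bootstrap) is
  driven by an explicit seed through `withr::with_seed`, and identical
  configuration + seed reproduces the CV report byte-identically.
* Ties: KNN neighbour ties and saliency-rank ties break toward the lower
  region index; the C grid breaks balanced-accuracy ties toward the
  smaller (more regularized) constant.
* Degenerate inputs fail loudly with the offending field named:
  zero-variance regions, non-square or non-numeric matrix files, negative
  adjacency weights, single-class training labels, single-site
  harmonization (a warning and pass-through), networks with no positive
  edges.
* Problem sizes in the test suite are scaled to desk hardware: recovery
  checks use 4-site cohorts of 150 patients / 150 controls at 90 regions
  over 5 seeds, the harmonization audit 4 sites of 60 controls, and oracle
  sweeps hundreds of graphs of up to 8 nodes; these sizes are the package's
  validation design, chosen to give stable Monte-Carlo margins.

## Known limitations

* The GCN trains on CPU in R; it is sized for atlas-scale graphs (90–160
  nodes) and cohorts of a few thousand subjects, not for voxel-level or
  population-graph workloads.
* Parametric ComBat only; the nonparametric prior variant, ComBat-GAM and
  longitudinal ComBat are out of scope.
* Per-subject graphs over regions only: no population graphs over subjects,
  learned adjacencies, or dynamic connectivity.
* CAM is exact for the conv→GAP→linear topology and is refused for
  anything else rather than silently falling back to gradient
  approximations.
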