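---
title: "Dually fused graph-convolutional survival modelling for paired omics"
author: "FuseSurv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dually fused graph-convolutional survival modelling for paired omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FuseSurv)
```

## The problem

Given paired gene-expression and microRNA-expression matrices for the same
patients together with right-censored survival outcomes
$\{x_i^{(1)}, x_i^{(2)}, O_i, \Delta_i\}_{i=1}^n$
($O_i = \min(T_i, C_i)$ the observed time, $\Delta_i$ the event indicator),
we want per-patient risk scores whose ranking agrees with survival. Two
complementary sources of information must be integrated: the *features* of
the two omics views (including their interactions) and the *neighbourhood
structure* among patients that both views express.

## The model

**Per-omics encoding.** Each view is projected to width $l$ and passed
through three highway blocks
$$x_{out} = H(x_{in}) \odot T(x_{in}) + x_{in} \odot (1 - T(x_{in})),$$
where $H$ is an affine map with ReLU activation and the gate $T$ is an
affine map with sigmoid activation. Gate biases start at $-1$, so training
begins close to the identity carry and the blocks learn transformations only
where they pay. This yields $Z^{(1)}, Z^{(2)} \in \mathbb{R}^{n \times l}$.

**Cross-omics features by factorized bilinear pooling.** The $j$-th
cross-omics feature of a patient is the bilinear form
$$z^{(c)}_j = z^{(1)\top} U_j V_j^\top z^{(2)},$$
with $U_j, V_j \in \mathbb{R}^{l \times d}$, evaluated as an inner product
of the two rank-$d$ projections (the $l \times l$ matrix $U_j V_j^\top$ is
never materialized). Stacking $j = 1..m$ gives $Z^{(c)} \in \mathbb{R}^{n
\times m}$. The fused representation concatenates the low-level sum with the
cross features:
$$Z = (Z^{(1)} + Z^{(2)}) \oplus Z^{(c)}.$$

**Graph fusion.** Per view, a $k$-nn affinity graph is built with the
exponential kernel
$$A(i,j) = \exp\!\left(-\rho^2(x_i, x_j) / (\mu\,\delta^2)\right)$$
for $j$ among the $k$ nearest neighbours of $i$, where $\delta^2$ is the
median off-diagonal pairwise squared distance of that view and $\mu$ is a
per-view bandwidth (0.3 for the gene graph, 0.2 for the microRNA graph).
The two graphs are averaged elementwise, and the fused graph is normalized
as $\hat{A} = \tilde{D}^{-1/2}(A + I)\tilde{D}^{-1/2}$.

**Graph convolution and Cox head.** The embedding is
$$Z_h = \sigma\!\left(\tanh(\hat{A} Z W_1)\, W_2\right),$$
and risks are $r_i = \beta^\top z_{h,i}$. All parameters minimize the
negative Cox log partial likelihood
$$\mathcal{L} = -\sum_{i:\Delta_i = 1}\Big[r_i - \log\!\!\sum_{j: O_j \ge O_i}\!\! e^{r_j}\Big]$$
by full-batch Adam. The cumulative baseline hazard is recovered afterwards
with the Breslow estimator.

## Numerical and design choices

Several details are genuinely open in this architecture family; the package
fixes them as follows and exposes most as configuration.

* **Risk set.** The partial-likelihood risk set is
  $R(i) = \{j : O_j \ge O_i\}$ (the patient belongs to its own risk set;
  Breslow handling of ties). A strict inequality would make the
  single-patient likelihood ill-defined. The log-sum-exp is stabilized by
  max subtraction, and the loss is invariant to constant risk shifts (a
  property the tests check to 1e-8).
* **One-hop mixing.** The convolution matrix multiplies only the first GCN
  layer; the second layer is dense. A conventional two-hop variant is
  available via `trainConfig(twoHop = TRUE)`.
* **Graph symmetrization.** The directional $k$-nn rule yields an
  asymmetric matrix; it is symmetrized as $(A + A^\top)/2$ by default
  (mutual-edge and elementwise-max rules are available) so that the
  symmetric normalization is well defined. Self-affinity enters only via
  the $+I$ self-loop. Distance ties at the $k$-th neighbour break by
  ascending sample index, making graph construction deterministic.
* **Encoder shape.** The reduction from the raw feature width to $l$ is a
  single linear projection; $H$ uses ReLU, gates use sigmoid with bias
  initialized at $-1$; all weights are Glorot-uniform from a seeded RNG.
  No dropout or weight decay is applied.
* **Metric tie handling.** Both the concordance index and the cumulative
  dynamic AUC count tied risk scores as 1/2 (Harrell convention); a strict
  inequality would penalize ties asymmetrically. AUC case sets at time $t$
  are restricted to patients with an *observed* event before $t$; a patient
  censored before $t$ contributes no known event.
* **Stratification boundary.** Median-risk stratification assigns samples
  at the median to the low-risk group, deterministically.
* **Standardization.** Feature standardization uses the population ($1/n$)
  variance, so a standardized feature satisfies `mean(x^2) == 1` exactly.
* **Discretization.** The preprocessing pipeline can quantile-discretize
  standardized features into `nBins` categories, but this stage is **off**
  by default: the encoders consume continuous features, and discretization
  discards within-bin variation without a compensating benefit in this
  architecture.
* **Log base.** The log transform is natural-log by default; base 2 is one
  configuration knob away, and downstream standardization makes the choice
  immaterial up to a per-feature constant.

## Training configuration

| Parameter | Default | Meaning |
|---|---|---|
| `learningRate` | 2e-4 | Adam step size (full-batch) |
| `maxEpochs` | 3000 | epoch budget; early stop after 20 epochs with relative improvement below `tol` = 1e-6 |
| `l`, `m` | 50, 10 | encoder width; number of cross-omics features |
| `d` | 16 | FBM factor rank (the interaction matrix rank) |
| `h1`, `h2` | 30, 15 | GCN hidden widths |
| `k` | 10 | graph neighbourhood size; selectable from \{2..15\} by `selectKCV()` |
| `muGene`, `muMirna` | 0.3, 0.2 | kernel bandwidths of the two graphs |
| `graphMode` | transductive | graph and forward pass cover train+test, loss sums over training samples only |

The epoch budget deserves a note: at the fixed learning rate of 2e-4 the
full-batch loss is still descending steeply after a few hundred epochs, so
the budget is set generously and the early-stopping rule decides in
practice (typical runs stop after 500--1500 epochs). Cohorts of a few
hundred patients make full-batch training exact and bit-deterministic given
the seed.

In the default transductive mode, held-out patients participate in graph
construction and message passing but never in the loss; a stricter
`graphMode = "train_graph"` trains on the training subgraph only and embeds
held-out patients once, after fitting.

## The synthetic cohort generator

`simulateCohort()` provides the package's universal test bed. Patients are
assigned to `nClusters` clusters whose latent centres are drawn with
standard deviation `clusterSep = 6`, large against the unit within-cluster
spread, so the planted partition is geometrically unambiguous (exactly so
at `noiseSD = 0` — a property the graph tests rely on). Both omics views
are random linear loadings of the shared latent factors plus independent
Gaussian noise, then cohort-centred per feature. Centring mimics
model-ready (post-preprocessing) data and matters more than it looks: a
bilinear form evaluated around a large mean offset is locally linear, and
only after centring does the planted cross-omics term
$x^{(1)\top} M x^{(2)}$ (low-rank $M$) remain genuinely invisible to an
additive linear model — the regime in which factorized bilinear pooling
should help. Centring is a per-feature translation, so it leaves the
pairwise-distance geometry (and the cluster margins) untouched; full
standardization was deliberately rejected because unit-scaling
weakly-separating features erases the noiseless cluster margins.

The additive and cross-omics risk components are each standardized to unit
variance before scaling by `betaAdditive` / `betaCross`, so the two effect
sizes are directly comparable. Event times are proportional-hazards
exponential (Weibull via `weibullShape`) in the planted risk; censoring is
independent with a rate calibrated by root-finding on the closed-form
censoring probability $\mathrm{E}_i[c/(\lambda_i + c)]$, so the realized
censoring proportion tracks `targetCensoring` (cohorts of this kind in
practice range from roughly 40% to 85% censored).

What the generator does **not** emulate: count-distribution noise,
library-size or batch effects, real marginal distributions of expression
data, or feature-feature correlation beyond the shared latent structure.
Passing tests therefore demonstrate correct recovery of planted structure
under the model's own assumptions, not performance on real cohorts.

## Problem sizes used by the test suite

Unit tests run on cohorts of 15--100 patients with 12--40 features and
reduced architecture widths. The end-to-end checks use the package's
reference study conditions: cohorts of 300 patients (120 gene, 40 microRNA
features), effect sizes `betaAdditive = 2, betaCross = 1` at 40% censoring
for recovery, and `betaAdditive = 1, betaCross = 1.5` at 50% censoring for
the ablation comparison, each over five cohort seeds with 80/20 holdouts.

## Known limitations

* The Cox head and partial likelihood assume proportional hazards; risks
  are time-constant.
* No regularization (dropout, weight decay) is applied, matching the
  architecture's description; with hundreds rather than thousands of
  patients the model can overfit the training partial likelihood, and the
  gap between training and held-out concordance is the main accuracy
  limiter on simulated cohorts.
* The plain (non-IPCW) concordance and AUC definitions are implemented;
  under heavy censoring these estimate censoring-distribution-weighted
  quantities, not the Uno-corrected ones.
* Transductive evaluation assumes test patients are available at graph
  construction time; the strict mode trades accuracy for a purer
  train/test separation.

## A minimal session

```{r example, eval = FALSE}
co <- simulateCohort(simConfig(nSamples = 200, seed = 1))
ds <- co$dataset

# 80/20 split, train the full model, evaluate the held-out patients
ev <- survEvent(ds)
fit <- trainModel(ds, "FULL", trainIdx = 1:160, testIdx = 161:200,
                  trainConfig(seed = 1))
rk <- riskScores(fit, "test")
concordanceIndex(rk, survTime(ds)[161:200], ev[161:200])

# repeated-holdout protocol and median-risk stratification
rep <- repeatedHoldout(ds, "FULL", splitScheme(0.8, 5), trainConfig(seed = 1))
summary(rep)
grp <- stratifyByMedian(riskScores(fit))
logrankTest(grp, survTime(ds), survEvent(ds))
```
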