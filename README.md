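# FuseSurv

Survival prediction from paired gene-expression and microRNA cohorts with
right-censored outcomes, for biostatisticians and computational biologists
who want a tested, scriptable implementation of dually fused
graph-convolutional survival modelling: *feature* fusion of the two omics
views through factorized bilinear pooling, and *graph* fusion of the two
patient-similarity graphs, feeding a graph convolutional network trained
end-to-end under the Cox partial likelihood.

## The model

For patients $\{x_i^{(1)}, x_i^{(2)}, O_i, \Delta_i\}$ (two omics views,
observed time $O_i = \min(T_i, C_i)$, event indicator $\Delta_i$):

1. **Encoding.** Each view passes through a three-layer highway encoder
   ($x_{out} = H(x) \odot T(x) + x \odot (1 - T(x))$) to width $l$.
2. **Feature fusion.** Cross-omics features are rank-constrained bilinear
   forms $z^{(c)}_j = z^{(1)\top} U_j V_j^\top z^{(2)}$, $j = 1..m$; the
   fused representation is $Z = (Z^{(1)} + Z^{(2)}) \oplus Z^{(c)}$.
3. **Graph fusion.** Per view, a k-nn graph with exponential kernel
   $A(i,j) = \exp(-\rho^2(x_i,x_j)/(\mu\delta^2))$, $\delta^2$ the median
   pairwise squared distance; the two graphs are averaged and normalized to
   $\hat{A} = \tilde{D}^{-1/2}(A+I)\tilde{D}^{-1/2}$.
4. **GCN + Cox head.** $Z_h = \sigma(\tanh(\hat{A} Z W_1) W_2)$, risks
   $r = Z_h \beta$, trained full-batch by Adam on the negative log partial
   likelihood $-\sum_{\Delta_i=1}[r_i - \log\sum_{O_j \ge O_i} e^{r_j}]$;
   the baseline cumulative hazard comes from the Breslow estimator.

Evaluation follows the standard survival toolkit: Harrell concordance,
cumulative dynamic AUC, Kaplan–Meier curves with median-risk stratification
and log-rank testing, repeated 80/20 holdout, cross-validated selection of
the neighbourhood size k, and the ablation variants of the network
(`GCN_SINGLE`, `LOW_FF`, `FBM_FF`, `HIGH_FF`, `NO_GRAPH`, `NO_FBM`).

A seeded synthetic-cohort generator (`simulateCohort()`) plants additive
and cross-omics risk structure in two correlated views with shared cluster
structure and calibrated censoring, so the whole pipeline is exercisable
without any external data.

## Worked example

```r
library(FuseSurv)

co <- simulateCohort(simConfig(nSamples = 200, seed = 1))
ds <- co$dataset
ds
#> MultiOmicsSurvival: 200 samples
#>   gene:     120 features
#>   microRNA: 40 features
#>   outcome:  97 events (51.5% censored)

ev <- survEvent(ds)
fit <- trainModel(ds, "FULL", trainIdx = 1:160, testIdx = 161:200,
                  trainConfig(seed = 1))
fit
#> SurvFit [FULL]: 160 train / 40 test samples, 221 epochs, final loss 293.618

rk <- riskScores(fit, "test")
concordanceIndex(rk, survTime(ds)[161:200], ev[161:200])
#> [1] 0.8688525
cumulativeAUC(rk, survTime(ds)[161:200], ev[161:200])
#> [1] 0.9212963

grp <- stratifyByMedian(riskScores(fit))
logrankTest(grp, survTime(ds), survEvent(ds))
#> $chisq
#> [1] 96.26  ($p ~ 1e-22)
```

The held-out concordance of 0.87 says that for 87% of comparable test-pair
orderings the patient with the shorter survival received the higher
predicted risk; the log-rank p-value says the median-risk split separates
the cohort's survival curves far beyond chance.

A thin command-line front end wrapping these functions (subcommands
`simulate`, `preprocess`, `train`, `evaluate`) lives at
`inst/scripts/fusesurv.R`.

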