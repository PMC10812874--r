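# DRPcurves

Learning-curve evaluation of multi-omics drug response prediction under
cancer-blind testing.

## What it is for

Predicting how effective a drug is against a cancer cell line — its
ln(IC50) — from the cell line's molecular profile is a core problem in
stratified medicine. Transcriptomics is the usual input, but proteomics
and phosphoproteomics are closer to the drug's actual targets; the
difficulty is that phosphoproteomics panels cover far fewer cell lines,
so a fair comparison at a single dataset size is uninformative.
**Learning curves** — generalization error as a function of training-set
size, averaged over repeated splits — let you compare modalities at
matched sizes *and* project how each would improve with more data.

The package is for computational biologists who want to run that
comparison: it builds the paired dataset, enforces cancer-blind
evaluation (test cell lines never seen in training, simulating an unseen
patient), trains a drug-average benchmark, gradient-boosted trees
(XGBoost) and a feed-forward network with random hyperparameter search
and early stopping, and analyses the resulting curves.

The core objects are the training set
$T_n = \{x_{c,i}, x_{d,i}, y_i\}_{i=1}^n$ — omics profile $x_c$, one-hot
drug $x_d$, response $y$ = ln(IC50) — scored by MSE, and the power law
of the central curve region,

$$\epsilon(n) = \alpha\, n^{\beta},$$

a straight line of slope $\beta$ in log-log coordinates, fitted by least
squares and used for extrapolation and for locating persistent crossings
between curves (e.g. where gradient boosting overtakes the network as
data grow). A seeded synthetic generator emulating GDSC/ProCan-style
inputs (log2-scale profiles, 38% proteomics missingness imputed to zero,
per-cell-line-scaled phosphoproteomics, drug-level mean structure plus a
cell-line effect carried by informative features) makes the entire
pipeline testable offline.

## Worked example

```r
library(DRPcurves)

cfg <- experimentConfig(
  synthetic  = syntheticConfig(nCellLines = 100, nDrugs = 20, seed = 1),
  modalities = c("rnaseq", "proteomics"),
  learners   = c("benchmark", "gbt"),
  nRepeats   = 5, kSizes = 4, minSize = 32,
  gbtParams  = list(nrounds = 150, max_depth = 4),
  seed = 1, outDir = "results/demo")
res <- runExperiment(cfg)
res$comparisonSummary
#>        condition   modality   learner  mean_mse     stderr avg_rank
#> 1 none|benchmark       none benchmark 1.0842898 0.17483538      3.0
#> 2 proteomics|gbt proteomics       gbt 0.6208540 0.07209413      1.8
#> 3     rnaseq|gbt     rnaseq       gbt 0.5874182 0.05953954      1.2
```

Mean test MSE at the largest training size, averaged over 5 cancer-blind
splits: both omics-driven models beat the drug-average benchmark (1.08),
RNA-seq edges out proteomics, and the average ranking (1 = best per
split, midranks on ties) shows RNA-seq wins 4 of the 5 splits.

```r
fit <- fitPowerLaw(res$curves[["rnaseq|gbt"]], window = c(1, 4))
fit
#> PowerLawFit: eps(n) = 39.78 * n^-0.6389  (window 1..4, residual 0.265)
percentMseReduction(res$comparisonSummary$mean_mse[1],   # benchmark
                    res$comparisonSummary$mean_mse[3])   # rnaseq|gbt
#> [1] 45.82461
```

The fitted exponent $\beta \approx -0.64$ quantifies how fast the RNA-seq
curve improves with data over this size range; the omics model reduces
MSE by ~46% relative to the benchmark. `plotLearningCurves(res$curves)`
draws the log-log curves with standard-error ribbons.

## Layout

* `R/` — S4 classes (`OmicsMatrix`, `PairedDataset`, `CancerBlindSplit`,
  `LearningCurve`, …) and the exported functions, one file per pipeline
  stage.
* `tests/testthat/` — unit, property and end-to-end acceptance tests; all
  fixtures are generated in code.
* `vignettes/learning-curves-for-drug-response.Rmd` — the methods
  vignette: model, assumptions, parameter choices, limitations.
* `inst/scripts/drplc.R` — thin CLI (`simulate`, `run`) over the package
  functions.
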