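# gblupqm

Genomic prediction for plant-breeding programs: GBLUP, with and without
empirical quantile-mapping calibration of the predictions, and with and
without meta-analytic outlier filtering of the training set — benchmarked
head-to-head by repeated cross-validation.

## Who this is for

Quantitative geneticists and breeders who want to know whether two popular
refinements of GBLUP actually buy prediction accuracy on their data:

* **Quantile mapping (QM)** aligns the distribution of GBLUP predictions
  with that of the observed training values through the transfer function
  *h*(x) = CDF⁻¹_y(CDF_x(x)), estimated from empirical quantiles of the
  training-set (predicted, observed) pairs.
* **Outlier filtering** scores every training observation with K
  cross-validated residual diagnostics, combines the per-observation
  p-values with one of four classical meta-analysis statistics, and removes
  flagged lines before refitting:

  | Method | Statistic | Null |
  |---|---|---|
  | Invchi (Fisher) | L = Σ −2 log p_k | χ² with 2K df |
  | Logit (Mudholkar–George) | S = Σ log(p_k/(1−p_k)), scaled | t with 5K+4 df |
  | Meanp (Edgington) | W = (0.5 − p̄)·√(12K) | N(0, 1) |
  | SumZ (Stouffer) | Z = Σ w_k z(p_k) / √(Σ w_k²) | N(0, 1) |

Crossing the two stages gives ten model variants (GBLUP, QM, four filtered,
four filtered+QM). The core model is y_i = μ + g_i + ε_i with
g ~ N(0, σ²_g **G**), where **G** is the VanRaden genomic relationship
matrix; fitting is by REML (eigendecomposition, deterministic) or a Gibbs
sampler with scaled-inverse-chi-square priors. Accuracy is scored by
Pearson correlation (COR) and normalized RMSE (NRMSE) on repeated random
80/20 train/test splits, with relative efficiencies reported in percent.

A built-in simulator generates SNP dosage matrices and single-trait
phenotypes with controllable heritability, residual skew and outlier
contamination, including scaled profiles matching the shapes of 14
published benchmark datasets, so the entire pipeline runs without any
external data.

## Worked example

Simulate a 300-line × 1,000-marker dataset at heritability 0.5 with 5% of
lines contaminated by 5-SD phenotype shifts, then run the ten-variant grid
over ten 80/20 splits:

```r
library(gblupqm)

cfg <- sim_config(n_lines = 300, n_markers = 1000, heritability = 0.5,
                  outlier_fraction = 0.05, outlier_magnitude = 5, seed = 42)
ds <- simulate_dataset(cfg)
grm <- compute_grm(ds$markers)
folds <- make_partitions(names(ds$phenotypes), n_reps = 10, master_seed = 7)
tab <- run_grid(ds$phenotypes, grm, folds, dataset = "sim300")
tab
#> Evaluation over 100 fold-rows (10 variants)
#>  dataset   variant    cor  nrmse n_folds
#>   sim300     GBLUP 0.1911 0.1259      10
#>   sim300    Invchi 0.2660 0.1222      10
#>   sim300     Logit 0.2666 0.1226      10
#>   sim300     Meanp 0.2805 0.1226      10
#>   sim300      SumZ 0.2688 0.1227      10
#>   sim300        QM 0.1864 0.1266      10
#>   sim300 QM_Invchi 0.2650 0.1222      10
#>   sim300  QM_Logit 0.2653 0.1221      10
#>   sim300  QM_Meanp 0.2768 0.1216      10
#>   sim300   QM_SumZ 0.2657 0.1221      10
```

Each row averages the per-split test-set COR and NRMSE of one variant. With
genuine contamination present, every filtered variant beats plain GBLUP
(COR ≈ 0.27 vs 0.19) because the planted outliers corrupt the training
fit; on clean simulations the ordering reverses, since filtering then
removes informative extreme observations. `render_report(tab)` narrates the
comparison with percent differences:

```r
writeLines(render_report(tab)[1:3])
#> Best by correlation: Meanp (COR = 0.2805).
#>   GBLUP: COR = 0.1911 (Meanp 46.7568% greater than GBLUP)
#>   Invchi: COR = 0.2660 (Meanp 5.4457% greater than Invchi)
```

A command-line front-end with `simulate`, `run`, `report` and `calibrate`
subcommands ships at `inst/scripts/gblupqm`.

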