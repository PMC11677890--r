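# petalmetry

Petal morphometrics and allometric scaling of corolla area.

Flower size matters for pollination and reproductive investment, and the
corolla — the whorl of petals — is its most visible component. Measuring
every petal planimetrically (scan, threshold, count pixels) is accurate
but destructive and slow, so floral biologists use allometric shortcut
models that predict area from two ruler measurements. This package gives
that workflow a tested, reproducible implementation, from silhouette
image to model choice:

* **Montgomery equation (ME)**, per petal: `A = k · L · W`, with `L` the
  petal length, `W` the maximum perpendicular width, and `k` a
  dimensionless coefficient (π/4 for an ellipse, 1 for a rectangle).
* **Montgomery–Koyama–Smith equation (MKSE)**, per flower:
  `A_T = k_KS · L_KS · W_KS`, where `A_T` is the flower's total petal
  area, `L_KS` the sum of its petals' widths and `W_KS` its maximum
  petal length.
* **Power-law equation (PLE)**: `A_T = β (L_KS · W_KS)^α`, relaxing the
  MKSE's isometry (`α = 1` recovers the MKSE, so the models are nested).

All fits are OLS on the natural-log scale; models are compared by
log-scale RMSE, Gaussian-ML AIC, and the percent-error rule
`PE = (RMSE_MKSE − RMSE_PLE)/RMSE_MKSE × 100%`, adopting the extra PLE
parameter only when PE > 5%. Confidence intervals come from a seeded
case-resampling bootstrap (3000 replicates by default). Supporting
tooling covers silhouette tracing (8-connected components, sub-pixel
marching-squares contours, pixel→cm scaling), principal-axis petal
measurement, Koyama–Smith aggregation, Tukey-HSD trait panels, and a
synthetic two-species generator with exact ground truth.

## Worked example

```r
library(petalmetry)
library(dplyr)

sim <- generate_dataset(seed = 42)   # two species-like populations
sim$truth
#> # A tibble: 2 × 6
#>   species     k alpha sigma n_flowers n_petals
#>   <chr>   <dbl> <dbl> <dbl>     <int>    <int>
#> 1 obovate 0.631   1   0.037        60      693
#> 2 notched 0.710   0.9 0.047        63      315

petals_ob <- filter(sim$petals, species == "obovate")
fit_montgomery(petals_ob, bootstrap = 3000, seed = 1)
#> <ME fit, n = 693>
#>   intercept (ln k) = -0.4626   slope = 1   k_hat = 0.6297
#>   rmse (ln scale) = 0.03639   aic = -2622   r = 0.9898
#>   95% CI k: [0.6279, 0.6314]  (B = 3000 bootstrap reps)

flowers_ob <- filter(sim$flowers, species == "obovate")
mkse <- fit_total_area_model(flowers_ob, "MKSE")
ple  <- fit_total_area_model(flowers_ob, "PLE", bootstrap = 3000, seed = 1)
select_model(mkse, ple)
#> <model comparison>
#>   PE = 0.7158% vs threshold 5% -> MKSE preferred; AIC MKSE = -275.754,
#>   AIC PLE = -274.616; PLE slope 95% CI [0.9614, 1.012] contains 1
```

The generator's truth table says the obovate species was built with a
shape-determined `k = 0.631` and isometric corolla scaling (`α = 1`).
The ME fit recovers `k̂ = 0.6297` from the 693 noisy petals with a tight
bootstrap interval, and the model comparison correctly keeps the simpler
MKSE: the RMSE gain from freeing the exponent is 0.7% (≪ 5%) and the
slope CI contains 1. Running the same lines on the notched species
selects the PLE instead, with a slope CI excluding 1 — the two presets
bracket the two regimes the comparison is designed to separate.

Real data enter the same way: `trace_boundaries()` +
`measure_petals()` for binary silhouette scans, or `read_petal_table()`
for a CSV of per-petal `species,flower_id,petal_id,A,L,W` measurements,
then `aggregate_flowers()` and the fitting functions above.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic data
and write tables to `results/`:

| script | what it does |
| --- | --- |
| `analysis/01_simulate.R` | generate the two-species dataset (petals, flowers, truth) |
| `analysis/02_trace_measure.R` | validate rasterize → trace → measure at 600 dpi |
| `analysis/03_fit_models.R` | ME/MKSE/PLE fits, bootstrap CIs, PE model selection |
| `analysis/04_group_comparison.R` | Tukey HSD trait panel between species |

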