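# oasiscarbon

Ecosystem carbon stock accounting and driver detection for arid oasis
landscapes.

Arid-basin oases — irrigated, vegetated cores grading into desert — store
carbon in vegetation and shallow soils, and that store shifts as garden and
arable land expand, construction encroaches, and policy scenarios protect or
convert forest-grassland. Quantifying the stock, decomposing its change over
land-use transitions, and identifying which environmental and human factors
drive its spatial heterogeneity is the job of this package. It is aimed at
landscape ecologists and carbon-accounting practitioners who work from field
point samples (aboveground biomass, AGB, in g·m⁻²; soil organic carbon,
SOC, in g·kg⁻¹), multi-epoch categorical land-use maps, and co-registered
environmental rasters.

## What it computes

The pipeline chains five stages, each usable on its own:

1. **Chemometric sample handling.** Samples are split into calibration and
   validation sets by the SPXY rule (joint X–y max–min distances, descended
   from Kennard–Stone). Predictors are screened by Pearson correlation and
   optionally refined by CARS (Monte-Carlo PLS-coefficient competition with
   an exponentially decaying retention ratio) or IRIV (binary-matrix
   shuffling with strong/weak/uninformative/interfering classification and
   backward elimination).
2. **Regression inversion.** Random forest regression (RFR) and support
   vector machine regression (SVMR) are fitted on each variable combination
   and compared by validation R², with

   R² = 1 − Σ(zᵢ−ẑᵢ)²/Σ(zᵢ−z̄)², RMSE = √(Σ(zᵢ−ẑᵢ)²/n), RPD = SD/RMSE,

   where SD uses the n−1 divisor. RPD < 1.4 flags poor, 1.4–2 rough and ≥ 2
   strong estimation. The winner is inverted over the predictor raster
   stack.
3. **Four-pool carbon density.** Per cell: aboveground carbon = 0.45 × AGB;
   underground carbon via per-class root-to-shoot ratios (arable 0.10,
   garden 0.30, forest-grassland 3.70, unused 4.50); soil carbon
   SCD = S × B × G × 0.01 (kg·m⁻²) from SOC, bulk density and the 0–20 cm
   depth; dead organic carbon = one tenth of aboveground. Water carries
   zero; construction takes 41.4 % (urban green coverage) of the
   forest-grassland means. Class-mean density tables are projected to other
   epochs by climate-ratio correction (soil by a linear precipitation
   regression, biomass by an exponential precipitation and a linear
   temperature regression), with land-use scenarios EPS/NDS/CDS/EDS matched
   to SSP126/245/370/585 climate.
4. **Stock accounting.** InVEST-style totals S = Σᵢ Dᵢ·Aᵢ over land-use
   classes, per-cell change classification at a ±5 % relative threshold,
   and an exactly conservative decomposition of the inter-epoch stock
   difference over the land-use transition matrix.
5. **Driver detection (OPGD).** Continuous drivers are discretized by the
   best of five methods (equal, quantile, Fisher–Jenks, geometric, standard
   deviation) over k = 3…8, maximizing the geographical-detector statistic

   q = 1 − Σᵢ Aᵢσᵢ² / (Aσ²),

   with permutation significance; interaction detection categorizes each
   driver pair from nonlinear weakening to nonlinear enhancement.

A seeded synthetic-scene generator (`generate_scene`) produces multi-epoch
land-use maps, latent AGB/SOC fields, a 44-layer predictor stack, a climate
series and nine driver rasters with planted, known structure, so the entire
pipeline is testable end to end without any external data. User-supplied
rasters (Esri ASCII grid) and CSV point tables in the same schema are
accepted by every stage.

## Worked example

```r
library(oasiscarbon)

cfg <- pipeline_config(
  scene = scene_config(grid_rows = 100L, grid_cols = 100L, seed = 1L),
  cars_runs = 30L, iriv_models = 200L, opgd_permutations = 99L, seed = 1L)
res <- run_pipeline(cfg)

res$agb$comparison
#> <model_comparison> best: set_II-RFR
#>                  set method n_vars train_r2 val_r2 val_rmse val_rpd val_band
#> set_II-RFR    set_II    RFR     12    0.995  0.976     40.4    6.50   strong
#> set_IV-RFR    set_IV    RFR      6    0.995  0.974     41.6    6.30   strong
#> set_II-SVMR   set_II   SVMR     12    0.993  0.971     43.8    5.98   strong
#> ...

res$stocks[["2019"]]
#> <stock_report> epoch 2019: total 1675.03 t over 1 km2
#>  lu area_km2  density stock_t area_share stock_share
#>  AR    0.330 1837.651 606.425       33.0    36.20385
#>  GA    0.118 2542.364 299.999       11.8    17.91008
#>  FO    0.188 2343.039 440.491       18.8    26.29753
#>  CO    0.056  970.018  54.321        5.6     3.24299
#>  WA    0.030    0.000   0.000       3.0     0.00000
#>  UN    0.278  984.866 273.793       27.8    16.34555

res$drivers
#> <factor_detection>
#>  name       q    p   band         method k
#>    VC 0.67770 0.01   main natural_breaks 8
#>    ST 0.10458 0.01 medium    categorical 5
#>    EL 0.10445 0.01 medium       quantile 7
#>    ...
```

Reading the output: the Pearson-screened RFR model wins AGB inversion
(validation R² 0.976, RPD 6.5 — "strong" estimation); garden land carries
the highest class density (2 542 g·m⁻²) and fixes disproportionate carbon
(17.9 % of stock on 11.8 % of area); vegetation cover is the dominant driver
of stock heterogeneity (q = 0.678, "main influence" band), which is the
structure the generator plants.

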