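# kcqi

Construction and hyperspectral prediction of a **kiwifruit comprehensive
quality index (KCQI)**.

Postharvest kiwifruit quality changes along several axes at once: soluble
solids content (SSC, °Brix) rises as starch hydrolyses, flesh firmness
(kg·cm⁻²) collapses, and the CIELAB colour coordinates drift (L* and b*
fall, a* rises towards zero, chroma C = √(a*² + b*²) falls). This package
implements a complete, tested pipeline for grading fruit on a single
composite index instead of any one parameter:

1. **Index construction** — Pearson screening, KMO and Bartlett adequacy
   tests, principal-component factor extraction with varimax rotation, and
   loading-based parameter selection reduce the six measured parameters to
   five (a* is excluded by a cross-loading rule), combined as

   ```
   KCQI = ln[ 1000 · F · L* · b* · C / SSC ]
   ```

   with firmness F. The index decreases monotonically as fruit ripen.

2. **Index prediction from spectra** — hyperspectral cubes (ENVI I/O,
   256 bands over 400–1000 nm) are white/dark corrected
   (R꜀ = (Iᵣ − I_d)/(I_w − I_d)), a region of interest is placed
   automatically on the fruit, mean ROI spectra are extracted, samples are
   partitioned 8:2 by SPXY, characteristic bands are selected by SPA, CARS
   or random frog, and the index is regressed by PLSR, random forest or a
   1-d convolutional network (Conv–BN–ReLU ×2 → Dropout 0.2 → FC, half-MSE
   loss). Models are scored by R², RMSE and RPD on calibration and
   prediction sets, and applied pixel-wise to render pseudocolour quality
   maps.

Because no public dataset accompanies this study design, the package ships
a first-class synthetic generator (`simConfig()`, `simulateQualityTable()`,
`simulateSpectrum()`, `simulateCube()`) that reproduces the design's
shelf-life trajectories, its Pearson correlation structure and its spectral
features (chlorophyll dips at 420/670 nm, NIR shoulder at 830 nm, water
band at 970 nm). The methods vignette (`vignettes/kcqi-methods.Rmd`)
documents the generative model and every numerical choice.

## Worked example

```r
library(kcqi)

cfg <- simConfig()                              # 2 cultivars x 4 days x 30 fruits
tab <- addKCQI(simulateQualityTable(cfg, seed = 1))
aggregate(cbind(ssc, firmness, kcqi) ~ day, tab, function(x) round(mean(x), 2))
#>   day   ssc firmness  kcqi
#> 1   0 11.99    13.63 17.85
#> 2   3 13.37    11.07 17.22
#> 3   6 14.89     9.09 16.69
#> 4   9 16.48     7.19 16.02

fm <- factorAnalysis(tab)
sprintf("KMO = %.3f, Bartlett chi2 = %.0f (p = %.3g), 3-factor cum. var = %.1f%%",
        fm@kmo, fm@bartlett["chi2"], fm@bartlett["p"], fm@cumulativeVariance[3])
#> "KMO = 0.610, Bartlett chi2 = 2398 (p = 0), 3-factor cum. var = 90.6%"
```

SSC climbs from ~12 to ~16.5 °Brix while firmness falls below 8 kg·cm⁻²,
and the composite index declines monotonically with shelf-life day — the
joint behaviour the index is built to capture. KMO > 0.5 and Bartlett
p ≈ 0 license the factor analysis behind the parameter selection.

The full study design — cube simulation, correction, ROI spectra, SPXY,
CARS band selection, network training, pixel maps — runs end to end with:

```r
bundle <- runPipeline(pipelineConfig(selectors = "cars", models = "cnn",
                                     fullSpectrumBaseline = FALSE, seed = 101))
bundle$report
#>   selector model nBands       rc2     rmsec       rp2   rmsep      rpd
#> 1     cars   cnn      5 0.9589528 0.1768394 0.9505041 0.16663 4.494851
```

(about 45 s on one CPU; `inst/scripts/run-pipeline.R` wraps this for the
shell and writes CSV/JSON/PNG artifacts).

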