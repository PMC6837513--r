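# speccal

Calibration design for hyperspectral prediction of grain nutrients.

Spectral phenotyping of cereal grains — predicting nutrient
concentrations such as nitrogen, phosphorus or zinc from near-infrared
hyperspectral images instead of wet chemistry — stands or falls with the
calibration model: the regression that links a sample's average grain
reflectance spectrum to a laboratory reference value. Reference samples
are expensive (combustion analysis, ICP-OES), so the practical questions
are: which regression model, how many reference samples, and from which
field environments should they be drawn? speccal is an R package for
plant-breeding and chemometrics researchers who want to study exactly
these questions on a multi-environment trial, end to end.

## What the package does

* **Reflectance correction** of raw spectral cubes against dark current
  and a co-imaged white-reference panel:
  `R_λ = (I_λ − I_λ^DC) / (I_λ^W − I_λ^DC)`.
* **Segmentation** of grain pixels from background by Neural Gas
  clustering of pixel spectra followed by an RBF pixel classifier, and
  per-sample spectrum averaging.
* **Regression back-ends**: NIPALS partial least squares (20
  components), an RBF network (20 Gaussian kernels, conjugate-gradient
  refinement) and a two-hidden-layer perceptron (30/10 tanh units,
  Levenberg–Marquardt).
* **Evaluation machinery**: treatment-stratified random calibration
  draws at 5–80% of an environment plus leave-one-out; composition
  designs that extend a calibration set across years (2n) or across all
  four environments (4n); 100-round validation schemes; a 7 × 4 model
  transferability matrix; cost–benefit ratios between consecutive set
  sizes and logarithmic learning-curve fits (`R² = a + b ln n`).
* **Statistics**: variance components and repeatability
  `rep = Vg / (Vg + Vr/R)`, coefficients of variation, Fisher-z model
  comparison with one-way ANOVA, Tukey–Kramer letters, and
  Fligner–Killeen variance-homogeneity tests.
* **Synthetic study generator**: a 48-genotype × 2-location × 2-year ×
  2-treatment × 4-replicate barley trial (1,536 plots) with calibrated
  variance structure (repeatability ≈ 0.93, trait CVs ≈ 6–27%),
  nutrient-driven 288-band spectra (970–2500 nm) and raw mini-cubes with
  dark current and a white panel — so the whole pipeline runs and is
  tested without access to proprietary image data.

## Worked example

```r
library(speccal)

design  <- experimentDesign()                    # the default trial layout
table   <- generatePlotTable(design, seed = 1)   # 1,536 plots, 6 nutrients
spectra <- generateSpectra(table, spectralModel(design), seed = 2)
spectra
#> class: SpectraExperiment
#> dim: 288 1536
#> assays(1): reflectance
#> rowData names(1): wavelength
#> colData names(13): plot_id genotype_id ... Fe Zn

## wet-chemistry quality of the synthetic trial: repeatability of N in
## Halle 2015
hal15 <- table[table$environment == "HAL15", ]
vc <- varianceComponents(hal15$N, hal15$genotype_id, R = 4)
vc
#> VarianceComponents: Vg = 3.086, Vr = 1.092 (R = 4, 48 genotypes)
repeatability(vc)
#> [1] 0.9187073

## how well does a 40% calibration set predict N in Halle 2015?
res <- runValidationScheme(spectra, "N", "pls",
                           compositionDesign("within_environment", "HAL15"),
                           fraction = 0.4, rounds = 20, baseSeed = 10)
meanR2(res)
#> [1] 0.9411021
head(res[, c("round", "nCal", "r2", "calRange")], 3)
#>   round nCal        r2 calRange
#> 1     1  154 0.9401236 11.01300
#> 2     2  154 0.9490234 10.26145
#> 3     3  154 0.9497134 10.57179
```

Each round draws 154 calibration samples (40% of the 384 Halle-2015
plots, stratified 1:1 over the N treatments), fits a 20-component PLS
model, and predicts the remaining 230 plots; `r2` is the squared Pearson
correlation between predicted and true N concentrations and `calRange`
the span of N values the calibration set happened to cover. The mean R²
of 0.94 says nitrogen is predicted almost as well as the generative
ceiling allows; mineral traits land near 0.45 at this size, and the gap
between the two is the central practical message: how far a calibration
can go depends on the trait's spectral signal, not only on sample count.

A full experiment grid (all traits, models, fractions, compositions,
with summary tables, transferability matrices and a manifest) runs from
a YAML config via `runExperiment()`; `inst/scripts/speccal.R` exposes
the same steps as shell subcommands (`simulate`, `reflect`, `segment`,
`evaluate`, `summarize`).

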