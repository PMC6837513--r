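---
title: "Designing calibration models for hyperspectral grain-nutrient prediction"
author: "speccal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing calibration models for hyperspectral grain-nutrient prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speccal)
```

## The problem

Hyperspectral imaging (HSI) can score grain quality traits in minutes, but
only through a calibration model that links the measured near-infrared
reflectance spectrum of a grain sample to a reference value obtained by
wet chemistry. The design of that calibration — which regression model,
how many reference samples, and from which field environments they are
drawn — largely determines the prediction quality, and reference samples
are the expensive part (combustion analysis and ICP-OES per sample).

speccal implements the full workflow for studying these design choices on
a multi-environment barley trial: 48 genotypes grown at two locations
(DUN, HAL) in two years (2015, 2016) under two nitrogen treatments with
four replicates, with six grain nutrients (N, P, K, Mg, Fe, Zn) as
targets and 288-band reflectance spectra (970–2500 nm) as inputs. Because
raw spectral cubes of such trials are rarely public, the package ships a
synthetic data generator that emulates the statistical structure of this
design end to end, down to raw camera cubes, so that every pipeline stage
is testable.

## Pipeline overview

1. **Reflectance correction** (`correctReflectance`): raw intensities are
   converted per pixel and band as
   $R_\lambda = (I_\lambda - I^{DC}_\lambda) / (I^{W}_\lambda - I^{DC}_\lambda)$,
   with the dark-current spectrum $I^{DC}$ from a closed-shutter
   measurement and the white-reference spectrum $I^{W}$ averaged over the
   pixels of a co-imaged reflectance panel (`extractWhiteReference`).
   Values are clipped to $[0, 1.1]$ and the clip count is recorded; the
   upper margin tolerates mild specular highlights. The panel's nominal
   95% reflectance can be folded in via `spectralonReflectance`, but the
   default applies the plain ratio formula.
2. **Segmentation** (`fitNeuralGas`, `trainPixelClassifier`,
   `segmentCube`): pixel spectra are clustered into material groups with
   a Neural Gas, clusters are labelled grain/background, an RBF network
   is trained on the labelled pixels, and the trained classifier is
   applied to all cubes. Grain-pixel spectra are then averaged per sample
   (`averageForegroundSpectrum`) into the regression input row.
3. **Regression** (`fitPLS`, `fitRBFRegressor`, `fitMLP`): three
   back-ends map an average spectrum to a nutrient concentration.
4. **Evaluation** (`runValidationScheme`, `transferabilityMatrix`,
   `costBenefit`, `fitLogCurve`): resampling over calibration fractions
   (5–80% plus leave-one-out), composition designs and environments.
5. **Statistics** (`varianceComponents`, `repeatability`,
   `compareGroups`, `flignerKilleen`): the supporting inference layer.

## The synthetic study and its calibration

`experimentDesign()` fixes the trial layout and a per-trait variance
structure; `generatePlotTable()` draws nutrient values as grand mean +
environment main effect + genotype effect + genotype-by-environment
effect + plot residual. The nitrogen treatment is carried only as a
stratification label: the trial this design emulates found no treatment
effect on grain nutrient concentrations, and calibration draws are
stratified 1:1 over it.

The generator's defaults are calibrated once, to the summary statistics
such a trial reports, and then frozen:

* **Repeatability.** Within-environment repeatability is
  $rep = V_g / (V_g + V_r / R)$ with $R = 4$ replicates. Given a target
  of 0.93 and a per-trait total within-environment CV, the constructor
  splits the implied variance into genotypic and residual parts (a fifth
  of the genotypic part is assigned to genotype-by-environment
  interaction). Estimated mean repeatability over 6 traits x 4
  environments lands in 0.92–0.93 (estimation adds slight downward
  noise).
* **Coefficients of variation.** Trait means (N 20, P 4.5, K 5.5,
  Mg 1.3 g/kg; Fe 45, Zn 35 mg/kg) and CVs (6.3% for Mg up to 23% for
  Fe) are typical for barley grain. Per-environment mean factors spread
  the CVs: iron is depressed in DUN16 so its CV rises above 23% (the
  factor 0.78 leaves margin for the ~10% sampling noise that 48 genotype
  draws put on a CV), and magnesium is elevated in HAL15 so its CV sits
  near 6%.
* **Spectra.** `spectralModel()` builds a smooth grain baseline with
  water-absorption features and one Gaussian absorption signature per
  trait. Sensitivities are scaled so one concentration standard
  deviation moves the spectrum by `signalAmp` reflectance units (0.045
  for N — protein N–H bonds are a strong, direct NIR signal — and
  ~0.011 for the minerals, which NIR senses only indirectly).
* **Proxy error.** The spectrum responds to `concentration + error`
  with per-trait error sd `proxyFrac * sd(conc)` (0.18 for N, 0.80 for
  minerals). This caps the asymptotically achievable prediction
  $R^2$ near $1/(1+\mathrm{frac}^2)$: ~0.97 for N, ~0.6 for minerals,
  reproducing the empirical ceiling where N predicts far better than
  minerals at every calibration size.
* **Structured interference.** Each sample adds random coefficients
  (sd 0.008) on 60 Gaussian basis spectra (widths 50–140 nm). The rank
  matters: interference of low rank is fully projected out by a
  calibration of ~150 samples and the learning curve then plateaus
  abruptly; at rank 60 the curve keeps rising gently through the larger
  sizes and is well described by $a + b\,\ln n$ (fit $R^2 \approx
  0.97$), with a per-sample gain beyond the 40% size of ~4e-4 — an
  order of magnitude below the 5→10% gain.
* **Environment effects.** Each location-year gets a smooth
  multiplicative scatter spectrum, an additive offset, per-trait
  sensitivity multipliers (±10%) and a signature wavelength shift of a
  few nm (moisture/matrix differences shift absorption bands). The
  shifts and multipliers are what break cross-environment transfer: a
  coefficient vector tuned to one environment's band positions misreads
  another's, while global scatter/offset alone would leave a
  correlation-based $R^2$ untouched.
* **Cubes.** `generateCube()` inverts the reflectance formula to raw
  intensities, placing a white-panel strip (rows 1–12), circular grains
  with log-normal per-pixel brightness jitter (sdlog 0.06), and a dark
  fleece background; sensor noise is added on the intensity scale.

What the generator does **not** emulate: pushbroom scanning geometry and
per-column illumination, 16-bit quantisation, grain-shape and packing
effects beyond brightness jitter, genetic family structure among the
genotypes, and any nonlinearity of the concentration-to-spectrum map.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and that the study's qualitative findings follow from this
statistical structure — not that the numerical values would be attained
on real images.

## Numerical choices

* **NIPALS PLS** (`fitPLS`): X is mean-centered, not variance-scaled
  (bands share units); y is centered; both are deflated per component.
  Inner tolerance 1e-10, at most 500 inner iterations (one pass suffices
  for a single response). Components are capped at
  `min(20, n - 1, n_bands)`, so 5% calibration sets (~19 samples) fit
  with 18 components and reproduce the small-set overfitting dip
  qualitatively. Prediction uses the equivalent coefficient vector
  $\beta = W(P'W)^{-1}q$.
* **RBF regressor** (`fitRBFRegressor`): 20 Gaussian kernels, centers
  from k-means, widths from nearest-center distances, output weights by
  ridge least squares (1e-6), then joint refinement of centers,
  log-widths and weights by Polak–Ribière conjugate gradient with Armijo
  backtracking. Stops after 1000 accepted epochs or when the MSE
  improvement drops below 1e-5; the per-epoch trace is stored and
  non-increasing by construction of the line search.
* **MLP** (`fitMLP`): 30 and 10 tanh units, linear output,
  Levenberg–Marquardt with the Jacobian assembled by backpropagation;
  damping ×10 on rejection, ÷10 on acceptance, initial 1e-3, abort above
  1e10. Weights start from a scaled-uniform (Nguyen–Widrow-style) range,
  so a seed fixes the whole trajectory. Note the Jacobian is n x
  n_weights; with 288 input bands the normal equations are ~9000², so
  full-band MLP fits are orders of magnitude slower than PLS — the same
  cost ranking (PLS ≪ RBF < MLP) the original workflow reports.
* **Evaluation**: calibration draws are stratified 1:1 by treatment
  within each contributing environment, ignoring genotype replication;
  an odd count alternates which treatment receives the extra sample
  between rounds. Round seeds are `baseSeed + round - 1`. $R^2$ is the
  squared Pearson correlation; zero-variance predictions yield a NaN
  sentinel that is excluded from means with a reported count (scoring
  such rounds 0 would conflate failure with anti-signal).
  Across-years/environments schemes are scored on the target
  environment's held-out samples. Leave-one-out pools the n held-out
  predictions into a single $R^2$ (per-fold values are undefined for
  single points); the scheme is reported as "99%" by convention.
* **Variance components**: method-of-moments from the one-way ANOVA
  table ($V_r = MS_W$, $V_g = (MS_B - MS_W)/\bar n$ with the
  unbalanced-corrected mean group size), negative $V_g$ truncated at 0
  and flagged. The estimator is transparent and closed-form; a REML fit
  would differ slightly on unbalanced data. $R$ stays fixed at 4 even
  when plots are missing, matching the formula as printed in the
  protocols this follows.
* **Model comparison**: per-round correlations $r = +\sqrt{R^2}$ (the
  sign is checked before squaring) are Fisher-z transformed, compared by
  one-way ANOVA, and letter-grouped via Tukey–Kramer adjusted p values
  (studentized range; harmonic handling of unequal group sizes) with the
  insert-and-absorb compact letter display.
* **Fligner–Killeen**: rank-based normal scores
  $a = \Phi^{-1}(1/2 + \mathrm{rank}/(2(N+1)))$ of $|x - \mathrm{median}|$,
  chi-squared with $k-1$ df. At 20 observations per group the
  chi-squared reference is conservative (empirical size ~0.03 at nominal
  0.05); the packaged type-I simulations use 30 per group, where the
  nominal level is attained.

## Design choices where the field is open

* **Neural Gas schedule**: 10,000 presentations, neighbourhood
  $\lambda: 10 \to 0.5$, step $\varepsilon: 0.5 \to 0.005$
  (Martinetz-style exponential decay). With $\lambda_{end} = 0.5$ a
  rank-1 neighbour pull of $e^{-2} \approx 0.14$ persists, so converged
  prototypes sit slightly inside their cluster centroids — inherent to
  Neural Gas, and harmless here because the classifier, not the
  prototypes, produces the final mask.
* **Cluster count**: the material groups are grain, table surface and
  white panel, but under log-normal pixel brightness jitter the grain
  material occupies two brightness modes. `trainSegmentation` therefore
  defaults to k = 4 (bright grain, dark grain, fleece, panel), which
  segments at pixel accuracy 1.00 across seeds where k = 3 occasionally
  merges bright grain pixels into the panel cluster (~0.96–0.98).
  `fitNeuralGas` itself defaults to k = 3.
* **Pixel subsampling**: clustering and classifier training use at most
  20,000 pixels per cube; the classifier is then applied to all pixels.
* **Transfer learning**: the second neural back-end is a plain trainable
  RBF regressor, tagged `rbf` in all outputs. The transfer-learning
  variant sometimes paired with this architecture has no published
  mechanism to re-implement, so nothing is labelled "transfer".
* **White reference**: the panel mean is global; a per-column variant
  (pushbroom optics) would be a straightforward extension but is not
  implemented.

## Problem sizes used by the packaged checks

The test suite and the acceptance script run the full pipeline at the
design's native size (1,536 plots, 288 bands). Validation schemes use
100 rounds for the within-environment learning curves and 20–50 rounds
for composition and transferability summaries; variance-component
recovery uses 200 simulated trials; the type-I simulation 1,000
replicates; segmentation checks three cubes of 60 x 80 pixels. A full
run of the acceptance script takes a couple of minutes on one CPU.

## Known limitations

* The generative model is linear in (proxy-noised) concentrations;
  nonlinear concentration-spectrum relationships, which would favour the
  neural back-ends, are out of scope.
* `varianceComponents` handles a single random factor (genotype within
  one environment); no across-environment heritability or mixed-model
  REML machinery is provided.
* Real-data mode expects plot tables and averaged spectra as CSV and raw
  cubes as ENVI BSQ float32; other interleaves and integer ENVI types
  are not read.
* The manual mask-correction step of interactive workflows is reduced to
  cluster-level selection (`labelClusters` with a manual map).
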