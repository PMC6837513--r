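## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

## Full-size default synthetic dataset (1536 plots, 288 bands).
defaultSpectraFixture <- function() {
  if (is.null(.fixtures$se)) {
    design <- experimentDesign()
    table <- generatePlotTable(design, seed = 11)
    .fixtures$design <- design
    .fixtures$table <- table
    .fixtures$se <- generateSpectra(table, spectralModel(design), seed = 12)
  }
  .fixtures$se
}

defaultTableFixture <- function() {
  defaultSpectraFixture()
  .fixtures$table
}

defaultDesignFixture <- function() {
  defaultSpectraFixture()
  .fixtures$design
}

## Tiny single-environment spectra with a purely linear, noise-free
## trait-band relationship; useful for exact regression contracts.
linearSpectraFixture <- function(n = 12, bands = 5, seed = 3) {
  X <- withr::with_seed(seed, matrix(runif(n * bands, 0.2, 0.6), n, bands))
  y <- 3 + 2 * X[, 2] - X[, 4]
  tab <- data.frame(plot_id = sprintf("P%03d", seq_len(n)),
                    genotype_id = sprintf("G%03d", seq_len(n)),
                    location = "DUN", year = 2015, environment = "DUN15",
                    treatment = rep(c("N+", "N0"), length.out = n),
                    replicate = 1, Y = y)
  SpectraExperiment(X, seq(1000, 1400, length.out = bands), tab,
                    samplesInRows = TRUE)
}

## A small synthetic cube plus ground truth, reflectance-corrected.
cubeFixture <- function(seed = 7, noise = TRUE) {
  design <- experimentDesign()
  model <- spectralModel(design)
  table <- generatePlotTable(design, seed = 21)[1, , drop = FALSE]
  se <- generateSpectra(table, model, seed = 22)
  spectrum <- spectraMatrix(se)[1, ]
  g <- generateCube(spectrum, model, seed = seed, noise = noise)
  list(model = model, spectrum = spectrum, cube = g$cube, mask = g$mask,
       reflectance = correctReflectance(g$cube))
}
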