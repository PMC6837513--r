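## Synthetic field-trial design and plot-table generation.
##
## The generator emulates a nested-association-mapping barley subset grown
## in four environments (two locations x two years) under two nitrogen
## treatments with four replicates. Per-trait variance components are, by
## default, derived from target coefficients of variation and a target
## within-environment repeatability, so the synthetic tables reproduce the
## summary statistics the downstream analysis assumes.

DEFAULT_TRAITS <- c("N", "P", "K", "Mg", "Fe", "Zn")

## Grand means (N, P, K, Mg in g/kg dry matter; Fe, Zn in mg/kg) and
## within-environment total CVs (percent) typical of barley grain.
DEFAULT_TRAIT_MEANS <- c(N = 20.0, P = 4.5, K = 5.5, Mg = 1.30,
                         Fe = 45, Zn = 35)
DEFAULT_TRAIT_CVS <- c(N = 11, P = 9.5, K = 8.5, Mg = 6.3,
                       Fe = 23, Zn = 14.5)

## Multiplicative environment mean factors (traits x DUN15, DUN16, HAL15,
## HAL16). Chosen so that per-environment CVs span roughly 6-25%: iron is
## depressed in Dundee-2016 (CV rises above 23%) and magnesium elevated in
## Halle-2015 (CV near 6%).
DEFAULT_ENV_FACTORS <- matrix(c(
  1.06, 0.94, 1.03, 0.97,   # N
  1.04, 0.97, 1.02, 0.97,   # P
  1.03, 0.98, 1.04, 0.95,   # K
  0.97, 0.99, 1.05, 0.99,   # Mg
  1.06, 0.78, 1.04, 1.05,   # Fe
  1.05, 0.95, 1.02, 0.98),  # Zn
  nrow = 6, byrow = TRUE, dimnames = list(DEFAULT_TRAITS, NULL))

#' Construct a multi-environment trial design
#'
#' Builds an [ExperimentDesign-class] describing the trial layout and the
#' per-trait variance structure used by [generatePlotTable()]. By default
#' the variance components are derived from target total within-environment
#' CVs and a target repeatability: writing `Vw` for the total
#' within-environment variance implied by the CV, the genotypic part
#' (genotype plus genotype-by-environment) is `Vw * rep' ` where
#' `rep' = repTarget / (repTarget + (1 - repTarget) * nReplicates)` is
#' inverted from `rep = Vg/(Vg + Vr/R)`, and `gxeFraction` of it is
#' assigned to the genotype-by-environment interaction.
#'
#' @param nGenotypes number of genotypes (default 48)
#' @param locations location labels (default `c("DUN", "HAL")`)
#' @param years trial years (default `c(2015, 2016)`)
#' @param treatments nitrogen treatment labels (default `c("N+", "N0")`);
#'   treatments are balanced 1:1 and have no effect on the nutrient values
#' @param nReplicates replicates per genotype x environment x treatment
#' @param nChecks number of check-cultivar entries added to the genotype
#'   set (default 0)
#' @param traits trait labels
#' @param traitMeans named grand means per trait
#' @param traitCVs named target total within-environment CVs (percent)
#' @param repTarget target within-environment repeatability used to split
#'   genotypic from residual variance (default 0.93)
#' @param gxeFraction fraction of the genotypic variance assigned to the
#'   genotype-by-environment interaction (default 0.2)
#' @param envFactors traits x environments matrix of multiplicative mean
#'   factors (environments ordered location-major, years within location)
#' @param traitVg,traitVge,traitVr optional explicit named variance
#'   components; when supplied they override the CV/repeatability
#'   derivation
#' @return an [ExperimentDesign-class]
#' @examples
#' d <- experimentDesign()
#' nPlots(d)   # 48 * 2 * 2 * 2 * 4 = 1536
#' @export
experimentDesign <- function(nGenotypes = 48, locations = c("DUN", "HAL"),
                             years = c(2015, 2016),
                             treatments = c("N+", "N0"),
                             nReplicates = 4, nChecks = 0,
                             traits = DEFAULT_TRAITS,
                             traitMeans = DEFAULT_TRAIT_MEANS,
                             traitCVs = DEFAULT_TRAIT_CVS,
                             repTarget = 0.93, gxeFraction = 0.2,
                             envFactors = NULL,
                             traitVg = NULL, traitVge = NULL,
                             traitVr = NULL) {
  if (nReplicates < 2) stop("nReplicates must be >= 2")
  if (length(traits) == 0) stop("trait list must not be empty")
  traitMeans <- traitMeans[traits]
  if (is.null(envFactors)) {
    ne <- length(locations) * length(years)
    envFactors <- if (identical(traits, DEFAULT_TRAITS) && ne == 4L)
      DEFAULT_ENV_FACTORS
    else matrix(1, length(traits), ne, dimnames = list(traits, NULL))
  }
  if (is.null(traitVg) || is.null(traitVr)) {
    cvs <- traitCVs[traits]
    Vw <- (cvs / 100 * traitMeans)^2
    ## invert rep = Vgeff / (Vgeff + Vr/R) given Vw = Vgeff + Vr
    ratio <- nReplicates * (1 / repTarget - 1)     # Vr / Vgeff
    Vgeff <- Vw / (1 + ratio)
    traitVr <- Vw - Vgeff
    traitVge <- gxeFraction * Vgeff
    traitVg <- (1 - gxeFraction) * Vgeff
  } else if (is.null(traitVge)) {
    traitVge <- setNames(rep(0, length(traits)), traits)
  }
  new("ExperimentDesign",
      nGenotypes = as.integer(nGenotypes), locations = locations,
      years = as.integer(years), treatments = treatments,
      nReplicates = as.integer(nReplicates), nChecks = as.integer(nChecks),
      traits = traits, traitMeans = traitMeans,
      traitVg = traitVg[traits], traitVge = traitVge[traits],
      traitVr = traitVr[traits], envFactors = envFactors)
}

#' Environment labels of a design
#'
#' One label per location-year combination, location-major (e.g. DUN15,
#' DUN16, HAL15, HAL16).
#' @param design an [ExperimentDesign-class]
#' @return character vector of environment labels
#' @export
environmentLabels <- function(design) {
  as.vector(t(outer(design@locations, substr(design@years, 3, 4), paste0)))
}

#' Total number of plots in a design
#' @param design an [ExperimentDesign-class]
#' @return integer plot count, including check entries
#' @export
nPlots <- function(design) {
  ne <- length(design@locations) * length(design@years)
  (design@nGenotypes + design@nChecks) * ne * length(design@treatments) *
    design@nReplicates
}

#' Trait labels of a design
#' @param design an [ExperimentDesign-class]
#' @return character vector
#' @export
designTraits <- function(design) design@traits

#' Variance components assumed by a design
#' @param design an [ExperimentDesign-class]
#' @return data.frame with one row per trait (mean, Vg, Vge, Vr)
#' @export
designVariances <- function(design) {
  data.frame(trait = design@traits, mean = unname(design@traitMeans),
             Vg = unname(design@traitVg), Vge = unname(design@traitVge),
             Vr = unname(design@traitVr))
}

#' Generate a synthetic plot table
#'
#' Draws one row per field plot with nutrient concentrations built from an
#' additive decomposition: grand mean + environment main effect + genotype
#' effect + genotype-by-environment effect + plot residual. Genotype and
#' interaction effects are zero-mean normal with the design's variances;
#' the environment main effect is the deterministic mean shift implied by
#' the design's `envFactors`. The nitrogen treatment is carried as a
#' stratification label but has no effect on the nutrient values.
#'
#' @param design an [ExperimentDesign-class]
#' @param seed integer seed; output is deterministic given the seed
#' @return data.frame with columns plot_id, genotype_id, location, year,
#'   environment, treatment, replicate and one column per trait
#' @examples
#' tab <- generatePlotTable(experimentDesign(), seed = 1)
#' nrow(tab)  # 1536
#' @export
generatePlotTable <- function(design, seed) {
  validObject(design)
  envs <- environmentLabels(design)
  nE <- length(envs)
  nG <- design@nGenotypes + design@nChecks
  genoIds <- c(sprintf("G%03d", seq_len(design@nGenotypes)),
               if (design@nChecks > 0) sprintf("CHK%02d",
                                               seq_len(design@nChecks)))
  grid <- expand.grid(replicate = seq_len(design@nReplicates),
                      treatment = design@treatments,
                      genotype_id = genoIds,
                      environment = envs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  envLoc <- rep(design@locations, each = length(design@years))
  envYear <- rep(design@years, times = length(design@locations))
  names(envLoc) <- names(envYear) <- envs
  n <- nrow(grid)
  tab <- data.frame(plot_id = sprintf("P%05d", seq_len(n)),
                    genotype_id = grid$genotype_id,
                    location = unname(envLoc[grid$environment]),
                    year = unname(envYear[grid$environment]),
                    environment = grid$environment,
                    treatment = grid$treatment,
                    replicate = grid$replicate,
                    stringsAsFactors = FALSE)
  gIdx <- match(grid$genotype_id, genoIds)
  eIdx <- match(grid$environment, envs)
  withr::with_seed(as.integer(seed), {
    for (ti in seq_along(design@traits)) {
      tr <- design@traits[ti]
      g <- rnorm(nG, 0, sqrt(design@traitVg[tr]))
      ge <- matrix(rnorm(nG * nE, 0, sqrt(design@traitVge[tr])), nG, nE)
      res <- rnorm(n, 0, sqrt(design@traitVr[tr]))
      envDelta <- design@traitMeans[tr] * (design@envFactors[ti, ] - 1)
      tab[[tr]] <- design@traitMeans[tr] + envDelta[eIdx] + g[gIdx] +
        ge[cbind(gIdx, eIdx)] + res
    }
  })
  tab
}

#' Write / read a plot table as CSV
#' @param table plot table data.frame
#' @param path file path
#' @return `readPlotTable` returns the plot table data.frame
#' @export
writePlotTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePlotTable
#' @export
readPlotTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
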