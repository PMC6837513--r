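## Statistical layer: variance components and repeatability, coefficient
## of variation, Fisher-z transformed model comparison (one-way ANOVA +
## Tukey-Kramer with compact letter display) and the Fligner-Killeen
## variance-homogeneity test.

#' Estimate variance components from replicated genotype values
#'
#' One-way random-effects ANOVA by the method of moments: the residual
#' variance is the within-genotype mean square and the genotype variance
#' `(MS_between - MS_within) / n0`, where `n0` is the unbalanced-corrected
#' average group size `(N - sum(n_i^2)/N) / (k - 1)`. A negative genotype
#' estimate is truncated at zero and flagged.
#'
#' @param values trait values, one per plot
#' @param genotypes genotype label per plot
#' @param R replicate count carried into the repeatability formula
#'   (default 4, the design's replicate number, irrespective of missing
#'   plots)
#' @return a [VarianceComponents-class]
#' @export
varianceComponents <- function(values, genotypes, R = 4) {
  keep <- !is.na(values)
  values <- values[keep]
  genotypes <- as.character(genotypes)[keep]
  k <- length(unique(genotypes))
  N <- length(values)
  if (k < 2) stop("need at least 2 genotypes")
  if (N <= k) stop("need replication (more values than genotypes)")
  groupMeans <- tapply(values, genotypes, mean)
  ni <- tapply(values, genotypes, length)
  grand <- mean(values)
  ssB <- sum(ni * (groupMeans - grand)^2)
  ssW <- sum((values - groupMeans[genotypes])^2)
  msB <- ssB / (k - 1)
  msW <- ssW / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  vg <- (msB - msW) / n0
  truncated <- vg < 0
  new("VarianceComponents", Vg = max(vg, 0), Vr = msW, R = R,
      nGenotypes = as.integer(k), truncated = truncated)
}

setMethod("repeatability", "VarianceComponents", function(x) {
  if (x@Vg == 0 && x@Vr == 0) {
    warning("both variance components are zero; repeatability undefined")
    return(NaN)
  }
  x@Vg / (x@Vg + x@Vr / x@R)
})

#' Coefficient of variation in percent
#'
#' `100 * sd / mean` with the sample standard deviation. Not
#' shift-invariant: adding a constant changes the CV.
#'
#' @param values numeric values with non-zero mean
#' @return CV in percent
#' @export
coefficientOfVariation <- function(values) {
  values <- values[!is.na(values)]
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * sd(values) / m
}

#' Fisher z transformation of a correlation coefficient
#'
#' `z = atanh(r)`, variance-stabilising transform applied to per-round
#' correlations before ANOVA. Values with `|r| >= 1` (perfect rounds) are
#' clamped to `1 - 1e-12` with a warning.
#'
#' @param r correlation coefficient(s)
#' @return transformed value(s)
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    warning("|r| >= 1 clamped before the Fisher z transform")
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  }
  atanh(r)
}

#' Compare groups of prediction correlations
#'
#' Fisher-z transforms each group's per-round correlation values, runs a
#' one-way ANOVA across the groups, computes Tukey-Kramer pairwise
#' adjusted p values (studentized range on the z scale) and assigns a
#' compact letter display by the insert-and-absorb algorithm, letters
#' ordered by descending group mean. Groups sharing a letter do not
#' differ at the chosen alpha.
#'
#' @param groups named list: group label -> per-round correlation values
#' @param alpha significance level for the letter display (default 0.05)
#' @param transform apply the Fisher z transform (default TRUE; set FALSE
#'   when the inputs are already on an unbounded scale)
#' @return list of class `speccalComparison`: group means (z and
#'   back-transformed), ANOVA F and p, pairwise adjusted p matrix and the
#'   letter display
#' @export
compareGroups <- function(groups, alpha = 0.05, transform = TRUE) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least 2 values")
  z <- if (transform) lapply(groups, fisherZ) else groups
  labels <- names(z)
  k <- length(z)
  ni <- vapply(z, length, integer(1))
  N <- sum(ni)
  means <- vapply(z, mean, numeric(1))
  grand <- sum(ni * means) / N
  ssB <- sum(ni * (means - grand)^2)
  ssW <- sum(vapply(z, function(g) sum((g - mean(g))^2), numeric(1)))
  dfB <- k - 1
  dfW <- N - k
  msW <- ssW / dfW
  Fstat <- (ssB / dfB) / msW
  pAnova <- pf(Fstat, dfB, dfW, lower.tail = FALSE)
  ## Tukey-Kramer adjusted p values
  pw <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(msW / 2 * (1 / ni[i] + 1 / ni[j]))
    q <- abs(means[i] - means[j]) / se
    pw[i, j] <- pw[j, i] <- ptukey(q, k, dfW, lower.tail = FALSE)
  }
  ord <- order(means, decreasing = TRUE)
  sigPairs <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    if (!is.na(pw[ord[i], ord[j]]) && pw[ord[i], ord[j]] < alpha)
      sigPairs <- c(sigPairs, list(labels[ord][c(i, j)]))
  letters <- compactLetters(labels[ord], sigPairs)
  structure(list(labels = labels, n = ni, zMeans = means,
                 means = tanh(means), F = Fstat, p = pAnova,
                 pairwise = pw, alpha = alpha,
                 letters = letters[labels]),
            class = "speccalComparison")
}

## Insert-and-absorb compact letter display. `ordered` lists group labels
## by descending mean; sigPairs are label pairs that differ significantly.
compactLetters <- function(ordered, sigPairs) {
  cols <- list(ordered)
  for (pair in sigPairs) {
    nxt <- list()
    for (col in cols) {
      if (all(pair %in% col))
        nxt <- c(nxt, list(setdiff(col, pair[1])),
                 list(setdiff(col, pair[2])))
      else nxt <- c(nxt, list(col))
    }
    ## absorb columns contained in another (including duplicates)
    keep <- rep(TRUE, length(nxt))
    for (u in seq_along(nxt)) for (v in seq_along(nxt)) {
      if (u == v || !keep[u] || !keep[v]) next
      if (all(nxt[[u]] %in% nxt[[v]]) &&
          (length(nxt[[u]]) < length(nxt[[v]]) || u > v))
        keep[u] <- FALSE
    }
    cols <- nxt[keep]
  }
  cols <- cols[order(vapply(cols, function(col)
    min(match(col, ordered)), numeric(1)))]
  out <- setNames(rep("", length(ordered)), ordered)
  for (ci in seq_along(cols))
    out[cols[[ci]]] <- paste0(out[cols[[ci]]], letters[ci])
  out
}

#' @export
print.speccalComparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA on Fisher-z values: F = %.4g, p = %.4g\n",
              x$F, x$p))
  df <- data.frame(group = x$labels, n = x$n, zMean = x$zMeans,
                   mean = x$means, letters = x$letters[x$labels])
  print(df, row.names = FALSE)
  invisible(x)
}

#' Fligner-Killeen test of variance homogeneity
#'
#' Rank-based test on the absolute deviations from the group medians:
#' deviations are ranked over all groups, transformed to normal scores
#' `a = qnorm(1/2 + rank / (2 (N + 1)))`, and the statistic
#' `sum n_i (abar_i - abar)^2 / V` is referred to a chi-squared
#' distribution with k - 1 degrees of freedom. When every value is
#' identical across all groups the statistic is 0 and p = 1 by
#' convention.
#'
#' @param groups list of numeric vectors (at least 2 groups of >= 2)
#' @return list with statistic, df and p
#' @export
flignerKilleen <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least 2 values")
  dev <- unlist(lapply(groups, function(g) abs(g - median(g))))
  sizes <- vapply(groups, length, integer(1))
  gid <- rep(seq_along(groups), sizes)
  N <- length(dev)
  a <- qnorm(0.5 + rank(dev) / (2 * (N + 1)))
  abar <- mean(a)
  v <- var(a)
  if (v == 0)
    return(list(statistic = 0, df = length(groups) - 1, p = 1))
  groupMeans <- tapply(a, gid, mean)
  stat <- sum(sizes * (groupMeans - abar)^2) / v
  df <- length(groups) - 1
  list(statistic = unname(stat), df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Write a comparison report to CSV and a plain-text letter table
#'
#' @param report a `speccalComparison` from [compareGroups()]
#' @param path CSV output path; a `.txt` letter table is written next to
#'   it
#' @return invisibly, the CSV path
#' @export
writeComparisonReport <- function(report, path) {
  df <- data.frame(group = report$labels, n = report$n,
                   zMean = report$zMeans, mean = report$means,
                   letters = report$letters[report$labels],
                   F = report$F, p = report$p)
  write.csv(df, path, row.names = FALSE)
  txt <- paste(sprintf("%-12s %s", report$labels,
                       report$letters[report$labels]), collapse = "\n")
  writeLines(txt, sub("\\.csv$", ".txt", path))
  invisible(path)
}
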