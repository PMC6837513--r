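test_that("variance components match hand-computed ANOVA", {
  ## 2 genotypes x 2 reps, groups (0,0) and (10,10):
  ## MS_within = 0, MS_between = 100, n0 = 2 -> Vg = 50
  vc <- varianceComponents(c(0, 0, 10, 10), c("a", "a", "b", "b"), R = 2)
  expect_equal(vc@Vg, 50)
  expect_equal(vc@Vr, 0)
  ## identical values: both components zero, repeatability undefined
  vc0 <- varianceComponents(rep(3, 6), rep(c("a", "b"), each = 3))
  expect_equal(vc0@Vg, 0)
  expect_equal(vc0@Vr, 0)
  expect_warning(r <- repeatability(vc0), "undefined")
  expect_true(is.nan(r))
  expect_error(varianceComponents(1:4, rep("a", 4)), "2 genotypes")
})

test_that("negative genotype estimates are truncated and flagged", {
  ## strong within-group spread, identical group means
  v <- c(0, 10, 5, 5)
  vc <- varianceComponents(v, c("a", "a", "b", "b"))
  expect_equal(vc@Vg, 0)
  expect_true(vc@truncated)
})

test_that("repeatability follows Vg / (Vg + Vr / R)", {
  mk <- function(vg, vr, R) new("VarianceComponents", Vg = vg, Vr = vr,
                                R = R, nGenotypes = 48L, truncated = FALSE)
  expect_equal(repeatability(mk(2, 0, 4)), 1)
  expect_equal(repeatability(mk(1, 1, 4)), 0.8)
  ## monotone: increasing in Vg and R, decreasing in Vr
  expect_gt(repeatability(mk(2, 1, 4)), repeatability(mk(1, 1, 4)))
  expect_gt(repeatability(mk(1, 1, 8)), repeatability(mk(1, 1, 4)))
  expect_lt(repeatability(mk(1, 2, 4)), repeatability(mk(1, 1, 4)))
})

test_that("the coefficient of variation is sd over mean in percent", {
  expect_equal(coefficientOfVariation(c(10, 10, 10)), 0)
  expect_equal(coefficientOfVariation(c(8, 12)), 100 * 2 * sqrt(2) / 10,
               tolerance = 1e-12)
  ## not shift-invariant
  expect_false(isTRUE(all.equal(coefficientOfVariation(c(8, 12)),
                                coefficientOfVariation(c(8, 12) + 100))))
  expect_error(coefficientOfVariation(c(-1, 1)), "zero mean")
})

test_that("the Fisher z transform behaves as atanh", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.5 * log(3), tolerance = 1e-12)
  expect_equal(fisherZ(-0.7), -fisherZ(0.7))
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(fisherZ(r)) > 0))
  expect_warning(z <- fisherZ(1), "clamped")
  expect_gt(z, 13)
})

test_that("group comparison matches the reference Tukey implementation", {
  g <- withr::with_seed(5, list(a = rnorm(10, 0.0, 0.3),
                                b = rnorm(12, 0.2, 0.3),
                                c = rnorm(9, 0.8, 0.3)))
  cmp <- compareGroups(g, transform = FALSE)
  df <- data.frame(v = unlist(g),
                   grp = rep(names(g), vapply(g, length, integer(1))))
  ref <- TukeyHSD(aov(v ~ grp, data = df))$grp
  expect_equal(cmp$pairwise["b", "a"], ref["b-a", "p adj"],
               tolerance = 1e-8)
  expect_equal(cmp$pairwise["c", "a"], ref["c-a", "p adj"],
               tolerance = 1e-8)
  expect_equal(cmp$pairwise["c", "b"], ref["c-b", "p adj"],
               tolerance = 1e-8)
})

test_that("the ANOVA F on two balanced groups is the squared t statistic", {
  g <- withr::with_seed(6, list(a = rnorm(15, 0, 1), b = rnorm(15, 0.5, 1)))
  cmp <- compareGroups(g, transform = FALSE)
  tt <- t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(cmp$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(cmp$p, tt$p.value, tolerance = 1e-10)
})

test_that("compact letters mark equal and distinct groups correctly", {
  gSame <- list(m1 = c(0.5, 0.6, 0.55), m2 = c(0.5, 0.6, 0.55))
  repSame <- compareGroups(gSame)
  expect_equal(unname(repSame$letters), c("a", "a"))
  gs <- withr::with_seed(7, list(a = rnorm(10, 0, 0.1),
                                 b = rnorm(10, 0, 0.1),
                                 c = rnorm(10, 5, 0.1)))
  repABC <- compareGroups(gs, transform = FALSE)
  expect_equal(repABC$letters[["a"]], repABC$letters[["b"]])
  expect_false(repABC$letters[["c"]] == repABC$letters[["a"]])
})

test_that("letters are a valid cover of the pairwise decisions", {
  for (seed in 1:5) {
    gs <- withr::with_seed(seed, {
      k <- sample(3:5, 1)
      means <- runif(k, 0, 1.5)
      setNames(lapply(means, function(m) rnorm(8, m, 0.3)),
               paste0("g", seq_len(k)))
    })
    cmp <- compareGroups(gs, transform = FALSE)
    expect_true(all(nchar(cmp$letters) >= 1))
    labs <- cmp$labels
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      if (i >= j) next
      share <- any(strsplit(cmp$letters[[labs[i]]], "")[[1]] %in%
                   strsplit(cmp$letters[[labs[j]]], "")[[1]])
      if (cmp$pairwise[labs[i], labs[j]] < cmp$alpha)
        expect_false(share)
      else expect_true(share)
    }
  }
})

test_that("Fligner-Killeen matches the reference implementation", {
  gs <- withr::with_seed(8, list(a = rnorm(12, 0, 1), b = rnorm(15, 0, 2),
                                 c = rnorm(10, 1, 1)))
  mine <- flignerKilleen(gs)
  ref <- fligner.test(unlist(gs),
                      factor(rep(names(gs),
                                 vapply(gs, length, integer(1)))))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
  ## scaled variances give a positive statistic
  pos <- flignerKilleen(list(c(1, 2, 3), c(10, 20, 30)))
  expect_gt(pos$statistic, 0)
  ## all-identical values: p = 1 by convention
  flat <- flignerKilleen(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(flat$p, 1)
  expect_equal(flat$statistic, 0)
})

test_that("comparison reports are written with letters attached", {
  g <- list(pls = c(0.8, 0.82, 0.81), mlp = c(0.5, 0.52, 0.49))
  cmp <- compareGroups(g)
  f <- tempfile(fileext = ".csv")
  writeComparisonReport(cmp, f)
  back <- read.csv(f)
  expect_equal(back$group, c("pls", "mlp"))
  expect_true(file.exists(sub("\\.csv$", ".txt", f)))
})
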