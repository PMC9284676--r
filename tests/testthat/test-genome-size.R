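test_that("independent contrasts match hand pruning on small trees", {
  t2 <- parseNewick("(A:1,B:1);")
  pc <- independentContrasts(t2, c(A = 3, B = 1))
  expect_equal(unname(pc$contrasts), 2 / sqrt(2), tolerance = 1e-9)
  t3 <- parseNewick("((A:1,B:1):1,C:2);")
  pc3 <- independentContrasts(t3, c(A = 2, B = 0, C = 1))
  expect_setequal(round(unname(pc3$contrasts), 5), c(1.41421, 0))
  # second contrast variance: augmented branch 1 + 0.5 plus C's branch 2
  expect_setequal(unname(pc3$variances), c(2, 3.5))
  const <- independentContrasts(t3, c(A = 7, B = 7, C = 7))
  expect_equal(unname(const$contrasts), c(0, 0))
})

test_that("contrasts are linear in the trait and reject bad inputs", {
  set.seed(21)
  tr <- ape::rtree(8)
  x <- setNames(rnorm(8), tr$tip.label)
  a <- independentContrasts(tr, x)$contrasts
  b <- independentContrasts(tr, 3 + 2 * x)$contrasts
  expect_equal(b, 2 * a, tolerance = 1e-12)
  poly <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_error(independentContrasts(poly, c(A = 1, B = 2, C = 3)), "polytom")
  zt <- ape::read.tree(text = "((A:0,B:1):1,C:2);")
  expect_error(independentContrasts(zt, c(A = 1, B = 2, C = 3)),
               "zero-length terminal")
})

test_that("contrasts agree with the reference implementation and GLS oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    tr <- ape::rtree(7)
    x <- setNames(rnorm(7), tr$tip.label)
    y <- setNames(rnorm(7), tr$tip.label)
    mine <- independentContrasts(tr, x)
    ref <- ape::pic(x[tr$tip.label], tr)
    expect_equal(sort(abs(unname(mine$contrasts))), sort(abs(unname(ref))),
                 tolerance = 1e-10)
    # correlation of contrasts (through origin) equals the GLS correlation
    cx <- independentContrasts(tr, x)$contrasts
    cy <- independentContrasts(tr, y)$contrasts
    r <- pearsonTest(cx, cy, center = FALSE)$r
    expect_equal(r, glsCorrelation(tr, x, y), tolerance = 1e-8)
  }
})

test_that("Pearson test matches hand computation and degenerate cases", {
  r <- pearsonTest(c(1, 2, 3), c(1, 2, 4))
  expect_equal(round(r$r, 4), 0.9820)
  expect_equal(round(r$r.squared, 4), 0.9643)
  expect_equal(pearsonTest(1:5, 1:5)$r, 1)
  expect_equal(pearsonTest(1:5, 1:5)$p.value, 0)
  expect_equal(pearsonTest(1:5, -(1:5))$r, -1)
  expect_error(pearsonTest(c(1, 1, 1), 1:3), "zero variance")
  # against the standard implementation
  set.seed(31)
  x <- rnorm(20); y <- x + rnorm(20)
  ct <- cor.test(x, y)
  mine <- pearsonTest(x, y)
  expect_equal(mine$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(mine$p.value, ct$p.value, tolerance = 1e-12)
})

test_that("repeat/genome-size correlation recovers planted relationships", {
  set.seed(41)
  tr <- simulateTree(10, 7)
  gsv <- setNames(runif(10, 2000, 5000), tr$tip.label)
  planted <- 0.9 * gsv + rnorm(10, 0, 30)
  other <- setNames(runif(10, 100, 200), tr$tip.label)
  am <- cbind(Planted = planted, Flat = other)
  gs <- GenomeSizeTable(sample = tr$tip.label, ploidy = 2,
                        c2_pg = 2 * mbpToPg(gsv))
  res <- repeatGsCorrelation(am, gs, tr)
  expect_gt(res$r.squared[res$family == "Planted"], 0.9)
  expect_true(all(res$testable))
  # constant family is reported as not testable
  am2 <- cbind(am, Const = rep(5, 10))
  res2 <- repeatGsCorrelation(am2, gs, tr)
  expect_false(res2$testable[res2$family == "Const"])
})

test_that("pairwise contribution matches hand computations", {
  a2 <- matrix(c(200, 100), 2, dimnames = list(c("a", "b"), "f"))
  gs2 <- c(a = 1100, b = 1000)
  expect_equal(pairwiseContribution(a2, gs2)$contributions$contribution_pct, 100)
  aConst <- matrix(c(50, 50), 2, dimnames = list(c("a", "b"), "f"))
  expect_equal(pairwiseContribution(aConst, gs2)$contributions$contribution_pct, 0)
  a3 <- matrix(c(10, 20, 40), 3, dimnames = list(c("a", "b", "c"), "f"))
  gs3 <- c(a = 100, b = 140, c = 200)
  r3 <- pairwiseContribution(a3, gs3)
  expect_equal(round(r3$contributions$contribution_pct, 2), 29.44)
  expect_identical(r3$nPairs, 3L)
  expect_equal(r3$contributions$min_mbp, 10)
  expect_equal(r3$contributions$max_mbp, 40)
  # near-equal genome sizes are excluded; all-excluded errors out
  gsEq <- c(a = 1000, b = 1000.5)
  expect_error(pairwiseContribution(a2, gsEq), "excluded")
})

test_that("contribution of summed amounts equals 100% minus unclassified share", {
  ds <- simulateRepeatome(simulationConfig(dataSeed = 5, treeSeed = 55,
                                           unclassifiedFraction = 0))
  gsr <- genomeSizeRecords(ds$genomeSizes)
  gsv <- setNames(gsr$cx1_mbp, gsr$sample)
  allrep <- cbind(All = rowSums(ds$amountsMbp))
  r <- pairwiseContribution(allrep, gsv)
  expect_equal(r$contributions$contribution_pct, 100, tolerance = 1e-9)
  ds5 <- simulateRepeatome(simulationConfig(dataSeed = 5, treeSeed = 55,
                                            unclassifiedFraction = 0.05))
  gsr5 <- genomeSizeRecords(ds5$genomeSizes)
  r5 <- pairwiseContribution(cbind(All = rowSums(ds5$amountsMbp)),
                             setNames(gsr5$cx1_mbp, gsr5$sample))
  expect_equal(r5$contributions$contribution_pct, 95, tolerance = 1e-9)
})
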