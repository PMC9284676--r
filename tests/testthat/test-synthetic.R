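test_that("Yule trees are ultrametric, unit depth, bifurcating, seeded", {
  t2 <- simulateTree(2, 1)
  expect_equal(unname(ape::node.depth.edgelength(t2)[1:2]), c(1, 1))
  t16 <- simulateTree(16, 5)
  expect_identical(t16$Nnode, 15L)      # 14 bifurcations + root
  expect_true(ape::is.binary(t16))
  expect_equal(unname(ape::node.depth.edgelength(t16)[1:16]), rep(1, 16),
               tolerance = 1e-9)
  expect_identical(serializeNewick(simulateTree(16, 5)),
                   serializeNewick(t16))
  expect_false(identical(serializeNewick(simulateTree(16, 6)),
                         serializeNewick(t16)))
  expect_error(simulateTree(1, 1), "at least 2")
})

test_that("Brownian traits obey the closed-form variance and seeding", {
  t2 <- parseNewick("(A:1,B:1);")
  expect_equal(unname(simulateBMTraits(t2, 0, rootValue = 3)), c(3, 3))
  set.seed(9)
  difs <- replicate(1000, {
    v <- simulateBMTraits(t2, 0.5)
    v["A"] - v["B"]
  })
  expect_equal(var(difs), 2 * 0.5, tolerance = 0.15)
  expect_identical(simulateBMTraits(t2, 1, seed = 4),
                   simulateBMTraits(t2, 1, seed = 4))
  expect_error(simulateBMTraits(t2, -1), ">= 0")
})

test_that("synthetic repeatome conserves genome-size composition exactly", {
  ds0 <- simulateRepeatome(simulationConfig(unclassifiedFraction = 0,
                                            treeSeed = 3, dataSeed = 4))
  gs <- genomeSizeRecords(ds0$genomeSizes)
  expect_equal(unname(rowSums(ds0$amountsMbp)),
               gs$cx1_mbp[match(rownames(ds0$amountsMbp), gs$sample)])
  # abundance percentages are amounts over 1Cx
  pct <- abundanceValues(ds0$abundance)
  expect_equal(unname(pct[, "CL01"]),
               unname(100 * ds0$amountsMbp[, "CL01"] /
                      gs$cx1_mbp[match(rownames(ds0$amountsMbp), gs$sample)]))
  expect_equal(unname(pct[, "Total"]), rep(100, nrow(pct)))
})

test_that("cluster truth labels follow the configured composition", {
  dsN <- simulateRepeatome(simulationConfig(nSignalClusters = 0,
    nNoiseClusters = 5, treeSeed = 3, dataSeed = 4))
  expect_true(all(dsN$clusterTruth == "noise"))
  ds <- simulateRepeatome(simulationConfig(treeSeed = 3, dataSeed = 4))
  expect_identical(sum(ds$clusterTruth == "signal"), 8L)
  expect_identical(sum(ds$clusterTruth == "noise"), 4L)
})

test_that("signal clusters carry tree structure that noise clusters lack", {
  ds <- simulateRepeatome(simulationConfig(treeSeed = 13, dataSeed = 14,
                                           bmSigma2 = 1))
  kSig <- vapply(names(ds$clusterTruth)[ds$clusterTruth == "signal"],
                 function(cl) blombergK(ds$tree, log(ds$amountsMbp[, cl])), 1)
  kNoise <- vapply(names(ds$clusterTruth)[ds$clusterTruth == "noise"],
                   function(cl) blombergK(ds$tree, log(ds$amountsMbp[, cl])), 1)
  expect_gt(mean(kSig), mean(kNoise))
})

test_that("synthetic generation is deterministic given the seeds", {
  a <- simulateRepeatome(simulationConfig(treeSeed = 21, dataSeed = 22))
  b <- simulateRepeatome(simulationConfig(treeSeed = 21, dataSeed = 22))
  expect_identical(a$amountsMbp, b$amountsMbp)
  expect_identical(a$hitGraph@edges, b$hitGraph@edges)
  expect_identical(serializeNewick(a$tree), serializeNewick(b$tree))
})

test_that("tandem cluster generator respects its contract", {
  c1 <- simulateTandemCluster(nRibotypes = 1, seed = 7)
  expect_identical(c1$truthType, 1L)
  expect_length(c1$ribotypes, 1)
  expect_true(all(nchar(c1$reads) == 100))
  c2 <- simulateTandemCluster(nRibotypes = 2, seed = 7)
  expect_length(c2$ribotypes, 2)
  # identical conserved gene segment, divergent spacer
  expect_identical(substr(c2$ribotypes[1], 1, 120), substr(c2$ribotypes[2], 1, 120))
  expect_false(substr(c2$ribotypes[1], 121, 300) == substr(c2$ribotypes[2], 121, 300))
  # determinism
  c1b <- simulateTandemCluster(nRibotypes = 1, seed = 7)
  expect_identical(c1$reads, c1b$reads)
  expect_identical(c1$graph@edges, c1b$graph@edges)
  expect_error(simulateTandemCluster(readLength = 400), "read length")
  expect_error(simulateTandemCluster(nRibotypes = 2, sharedGeneLength = 300),
               "shared gene")
})
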