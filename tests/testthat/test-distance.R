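test_that("observed/expected ratios match hand counts", {
  # 2 species x 2 reads, all 4 interspecies pairs are edges, no intra edges
  g <- makeHitGraph(c("A_1", "A_2", "B_1", "B_2"), c("A", "A", "B", "B"),
                    rbind(c("A_1", "B_1", 1), c("A_1", "B_2", 1),
                          c("A_2", "B_1", 1), c("A_2", "B_2", 1)))
  m <- similarityRatios(observedExpectedMatrix(g, "CL1"))
  expect_equal(m["A", "B"], 1.5)
  expect_equal(m["A", "A"], 0)
  expect_equal(m["B", "B"], 0)
  # complete graph: every ratio is exactly 1
  reads <- c("A_1", "A_2", "B_1", "B_2", "C_1")
  sp <- substr(reads, 1, 1)
  allp <- t(combn(reads, 2))
  gK <- makeHitGraph(reads, sp, cbind(allp, 1))
  mK <- similarityRatios(observedExpectedMatrix(gK, "CL1"))
  expect_equal(unname(mK[!is.na(mK)]), rep(1, sum(!is.na(mK))))
  # single-read species has an undefined (missing) diagonal ratio
  expect_true(is.na(mK["C", "C"]))
  # single-species cluster errors
  g1 <- makeHitGraph(c("A_1", "A_2"), c("A", "A"), rbind(c("A_1", "A_2", 1)))
  expect_error(observedExpectedMatrix(g1, "CL1"), "single species")
})

test_that("ratios average to 1 under a uniformly random, exchangeable graph", {
  # decay 0 and conservatism 1 make every node pair equally likely
  ds <- simulateRepeatome(simulationConfig(nSpecies = 4, readsPerSpecies = 50,
    nSignalClusters = 6, nNoiseClusters = 0, pIn = 0.3, conservatism = 1,
    decay = 0, treeSeed = 61, dataSeed = 62))
  inter <- unlist(lapply(clusterIDs(ds$hitGraph), function(cl) {
    m <- similarityRatios(observedExpectedMatrix(ds$hitGraph, cl))
    m[row(m) != col(m)]
  }))
  expect_equal(mean(inter), 1, tolerance = 0.1)
})

test_that("euclidean profile distance matches hand computation and is metric", {
  m <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  sim <- new("ClusterSimilarityMatrix", cluster = "x", ratios = m,
             readCounts = c(A = 2L, B = 2L))
  d <- distanceValues(euclideanProfileDistance(sim))
  expect_equal(d["A", "B"], sqrt(2))
  expect_equal(diag(d), c(A = 0, B = 0))
  # identical rows give zero distance
  m2 <- matrix(1, 2, 2, dimnames = dimnames(m))
  sim2 <- new("ClusterSimilarityMatrix", cluster = "x", ratios = m2,
              readCounts = c(A = 2L, B = 2L))
  expect_equal(max(distanceValues(euclideanProfileDistance(sim2))), 0)
  # triangle inequality on random symmetric profiles
  set.seed(71)
  for (rep in 1:20) {
    r <- matrix(runif(25), 5); r <- (r + t(r)) / 2
    dimnames(r) <- list(letters[1:5], letters[1:5])
    simr <- new("ClusterSimilarityMatrix", cluster = "r", ratios = r,
                readCounts = setNames(rep(2L, 5), letters[1:5]))
    dd <- distanceValues(euclideanProfileDistance(simr))
    for (i in 1:5) for (j in 1:5) for (k in 1:5)
      expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-12)
  }
})

test_that("inverse similarity distance inverts off-diagonals", {
  m <- matrix(c(1, 2, 4, 2, 1, 0.5, 4, 0.5, 1), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d <- distanceValues(inverseSimilarityDistance(
    new("ClusterSimilarityMatrix", cluster = "x", ratios = m,
        readCounts = c(A = 2L, B = 2L, C = 2L))))
  expect_equal(d["A", "B"], 0.5)
  expect_equal(d["A", "C"], 0.25)
  expect_equal(d["B", "C"], 2)
  expect_equal(unname(diag(d)), c(0, 0, 0))
  m0 <- m; m0["A", "B"] <- m0["B", "A"] <- 0
  expect_error(inverseSimilarityDistance(
    new("ClusterSimilarityMatrix", cluster = "x", ratios = m0,
        readCounts = c(A = 2L, B = 2L, C = 2L))), "positive")
})

test_that("both transforms are equivariant under species relabelling", {
  set.seed(72)
  r <- matrix(runif(16, 0.5, 2), 4); r <- (r + t(r)) / 2
  dimnames(r) <- list(LETTERS[1:4], LETTERS[1:4])
  sim <- new("ClusterSimilarityMatrix", cluster = "x", ratios = r,
             readCounts = setNames(rep(3L, 4), LETTERS[1:4]))
  perm <- c(3, 1, 4, 2)
  rp <- r[perm, perm]
  simP <- new("ClusterSimilarityMatrix", cluster = "x", ratios = rp,
              readCounts = setNames(rep(3L, 4), rownames(rp)))
  for (f in list(euclideanProfileDistance, inverseSimilarityDistance)) {
    d <- distanceValues(f(sim))
    dp <- distanceValues(f(simP))
    expect_equal(dp, d[perm, perm], tolerance = 1e-12)
  }
})

test_that("cluster filtering retains exactly the complete matrices", {
  mk <- function(cl, m) new("ClusterSimilarityMatrix", cluster = cl,
    ratios = m, readCounts = setNames(rep(2L, nrow(m)), rownames(m)))
  ok <- matrix(c(1, 2, 2, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  zero <- ok; zero["A", "B"] <- zero["B", "A"] <- 0
  flt <- filterCompleteClusters(list(mk("c1", ok), mk("c2", zero), mk("c3", ok)))
  expect_identical(sum(flt$report$retained), 2L)
  expect_identical(flt$report$reason[flt$report$cluster == "c2"],
                   "zero interspecies ratio")
  all_ok <- filterCompleteClusters(list(mk("c1", ok), mk("c3", ok)))
  expect_true(all(all_ok$report$retained))
  # missing species relative to the full set
  flt2 <- filterCompleteClusters(list(mk("c1", ok)), species = c("A", "B", "C"))
  expect_false(any(flt2$report$retained))
  expect_identical(flt2$report$reason, "missing species")
})

test_that("sparse synthetic graphs are partially discarded with reasons", {
  ds <- simulateRepeatome(simulationConfig(readsPerSpecies = 6,
    treeSeed = 81, dataSeed = 82))
  mats <- lapply(clusterIDs(ds$hitGraph), function(cl)
    observedExpectedMatrix(ds$hitGraph, cl))
  flt <- filterCompleteClusters(mats)
  expect_lte(sum(flt$report$retained), length(mats))
  expect_true(any(nzchar(flt$report$reason)))
})
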