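test_that("three-taxon NJ uses the three-point formulas", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 0.5, B = 1.5, C = 2.5))
  expect_error(neighborJoining(d[1:2, 1:2]), "at least 3")
  dn <- d; dn[1, 2] <- dn[2, 1] <- NaN
  expect_error(neighborJoining(dn), "NaN")
})

test_that("NJ recovers the generating tree exactly from an additive matrix", {
  t0 <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  tr <- neighborJoining(stats::cophenetic(t0))
  expect_identical(robinsonFoulds(tr, t0), 0L)
  # internal branch length 1.0 is reproduced
  ntip <- length(tr$tip.label)
  internal <- tr$edge[, 2] > ntip
  expect_equal(sum(tr$edge.length[internal]), 1)
  # patristic distances reproduce the input exactly
  expect_equal(stats::cophenetic(tr)[rownames(stats::cophenetic(t0)),
                                     colnames(stats::cophenetic(t0))],
               stats::cophenetic(t0), tolerance = 1e-12)
})

test_that("NJ is consistent on every 4- and 5-taxon shape", {
  skip_if_not_installed("phangorn")
  for (n in 4:5) {
    for (t0 in additiveCases(n, seed = n)) {
      tr <- neighborJoining(stats::cophenetic(t0))
      expect_identical(robinsonFoulds(tr, t0), 0L)
    }
  }
})

test_that("NJ topology agrees with the reference implementation", {
  set.seed(91)
  for (rep in 1:5) {
    t0 <- ape::rtree(6)
    d <- stats::cophenetic(t0)
    mine <- neighborJoining(d)
    ref <- ape::nj(d)
    expect_identical(robinsonFoulds(mine, ref), 0L)
  }
})

test_that("ultrametric matrices from random trees recover the topology", {
  for (seed in 1:5) {
    t0 <- simulateTree(5, seed)
    tr <- neighborJoining(stats::cophenetic(t0))
    expect_identical(robinsonFoulds(tr, t0), 0L)
  }
})

test_that("negative branch lengths are clamped with the deficit transferred", {
  # a non-additive matrix known to produce a negative NJ branch
  d <- matrix(c(0, 5, 9, 9, 5, 0, 8, 9, 9, 8, 0, 1, 9, 9, 1, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighborJoining(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("tree splits enumerate internal edges plus trivial splits", {
  q <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  ss <- treeSplits(q)
  nt <- splitList(ss)[isNontrivialSplit(ss)]
  expect_length(nt, 1)
  expect_setequal(nt[[1]], c("A", "B"))
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_length(splitList(treeSplits(star))[isNontrivialSplit(treeSplits(star))], 0)
  cat5 <- ape::read.tree(text = "((((A:1,B:1):1,C:1):1,D:1):1,E:1);")
  ssc <- treeSplits(cat5)
  expect_length(splitList(ssc)[isNontrivialSplit(ssc)], 2)  # n - 3
})

test_that("consensus network support, weights and thresholding are correct", {
  tAB <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tAC <- ape::read.tree(text = "((A:1,C:1):2,(B:1,D:1):2);")
  same <- consensusNetwork(list(tAB, tAB, tAB), threshold = 0.9)
  expect_setequal(nontrivialKeys(same), nontrivialKeys(tAB))
  expect_true(all(splitSupport(same) == 1))
  mix <- consensusNetwork(list(tAB, tAB, tAC), threshold = 0.25)
  nt <- isNontrivialSplit(mix)
  expect_identical(sum(nt), 2L)
  expect_setequal(round(splitSupport(mix)[nt], 3), c(0.667, 0.333))
  # the AB|CD split weight is the mean internal length over its two trees
  keyAB <- nontrivialKeys(tAB)
  wAB <- splitWeights(mix)[nt][match(keyAB, nontrivialKeys(mix))]
  expect_equal(unname(wAB), 2)  # edge appears as 1+1 in tAB (both sides)
  maj <- consensusNetwork(list(tAB, tAB, tAC), threshold = 0.5)
  expect_identical(sum(isNontrivialSplit(maj)), 1L)
  expect_setequal(nontrivialKeys(maj), nontrivialKeys(tAB))
  bad <- ape::read.tree(text = "((A:1,B:1):1,(C:1,E:1):1);")
  expect_error(consensusNetwork(list(tAB, bad)), "mismatched tip set.*[DE]")
})

test_that("Robinson-Foulds counts split symmetric differences", {
  tAB <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tAC <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_identical(robinsonFoulds(tAB, tAB), 0L)
  expect_identical(robinsonFoulds(tAB, tAC), 2L)
  skip_if_not_installed("phangorn")
  set.seed(101)
  for (rep in 1:5) {
    t1 <- ape::rtree(8); t2 <- ape::rtree(8)
    expect_equal(robinsonFoulds(t1, t2),
                 as.integer(phangorn::RF.dist(t1, t2)))
  }
  # one NNI move changes at most one split
  t1 <- ape::rtree(8)
  nni <- phangorn::rNNI(t1, 1)
  expect_lte(robinsonFoulds(t1, nni), 2L)
})
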