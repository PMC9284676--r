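test_that("connected component index is the largest-component share", {
  ring <- igraph::make_ring(10)
  igraph::E(ring)$weight <- 1
  expect_equal(connectedComponentIndex(ring), 1)
  two <- igraph::make_ring(7) + igraph::make_ring(3)
  igraph::E(two)$weight <- 1
  expect_equal(connectedComponentIndex(two), 0.7)
  expect_error(connectedComponentIndex(igraph::make_empty_graph(0)), "empty")
  # dense single-ribotype cluster graphs are near fully connected
  cl <- simulateTandemCluster(nRibotypes = 1, seed = 17)
  expect_gte(connectedComponentIndex(cl$graph), 0.95)
})

test_that("loop counting matches cycle rank on canonical shapes", {
  ring <- igraph::make_ring(10)
  igraph::E(ring)$weight <- 1
  r <- simplifyAndCountLoops(ring)
  expect_identical(r$beta, 1L)
  expect_identical(r$shapeType, 1L)
  theta <- igraph::graph_from_edgelist(
    rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 5), c(5, 3)),
    directed = FALSE)
  igraph::E(theta)$weight <- 1
  rt <- simplifyAndCountLoops(theta)
  expect_identical(rt$beta, 2L)
  expect_identical(rt$shapeType, 2L)
  # a tree prunes to nothing: flagged linear/ambiguous
  tree <- igraph::make_tree(7, 2, mode = "undirected")
  igraph::E(tree)$weight <- 1
  rl <- simplifyAndCountLoops(tree)
  expect_identical(rl$beta, 0L)
  expect_true(is.na(rl$shapeType))
  expect_identical(rl$shapeLabel, "linear/ambiguous")
})

test_that("cycle rank is invariant under edge subdivision", {
  set.seed(121)
  base <- igraph::sample_gnm(12, 18)
  igraph::E(base)$weight <- 10
  b0 <- simplifyAndCountLoops(base)$beta
  for (rep in 1:5) {
    g <- base
    for (s in 1:6) {   # subdivide a random edge: V+1, E+1, beta unchanged
      e <- sample(igraph::ecount(g), 1)
      ends <- igraph::ends(g, e)
      g <- igraph::delete_edges(g, e)
      g <- igraph::add_vertices(g, 1)
      v <- igraph::vcount(g)
      g <- igraph::add_edges(g, c(ends[1], v, v, ends[2]))
      igraph::E(g)$weight <- 10
    }
    expect_identical(simplifyAndCountLoops(g)$beta, b0)
  }
})

test_that("k-mer graph of an error-free circular monomer is one loop", {
  c1 <- simulateTandemCluster(nRibotypes = 1, seed = 31, buildHitGraph = FALSE)
  r <- classifyTandemCluster(c1$reads)
  expect_identical(r$beta, 1L)
  expect_identical(r$shapeType, 1L)
  expect_gte(r$kmerScore, 0.95)
  c2 <- simulateTandemCluster(nRibotypes = 2, seed = 31, buildHitGraph = FALSE)
  r2 <- classifyTandemCluster(c2$reads)
  expect_identical(r2$beta, 2L)
  expect_identical(r2$shapeType, 2L)
  # two equal-abundance ribotypes: score near the dominant cycle's share
  expect_lt(r2$kmerScore, 0.8)
  expect_gt(r2$kmerScore, 0.4)
})

test_that("random unrelated reads score near zero with a warning", {
  set.seed(41)
  rnd <- replicate(60, paste(sample(c("A", "C", "G", "T"), 100, TRUE),
                             collapse = ""))
  expect_warning(s <- kmerCycleScore(rnd), "no cycle")
  expect_lt(s, 0.3)
})

test_that("noise-free classification is perfect over seeded replicates", {
  hits <- 0L
  for (seed in 1:10) {
    t1 <- classifyTandemCluster(simulateTandemCluster(nRibotypes = 1,
      seed = seed, buildHitGraph = FALSE)$reads)
    t2 <- classifyTandemCluster(simulateTandemCluster(nRibotypes = 2,
      seed = seed + 500, buildHitGraph = FALSE)$reads)
    hits <- hits + (t1$shapeType == 1L) + (t2$shapeType == 2L)
  }
  expect_identical(hits, 20L)
})

test_that("tandem metrics table combines C, loops and genome proportion", {
  cl <- simulateTandemCluster(nRibotypes = 1, seed = 51)
  tm <- tandemClusterMetrics(cl$graph, cl$reads, nTotalReads = 500000)
  expect_identical(tm$n_reads, 150L)
  expect_equal(tm$genome_proportion, 100 * 150 / 500000)
  expect_identical(tm$shape_type, 1L)
  expect_gt(tm$C, 0.9)
})
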