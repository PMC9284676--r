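# Shared fixture builders for the test suite. Everything is constructed in
# code; no binary fixtures.

# A small HitGraph from explicit node/edge specs.
makeHitGraph <- function(reads, species, edges, cluster = "CL1") {
  nodes <- data.frame(read = reads, species = species, cluster = cluster,
                      stringsAsFactors = FALSE)
  e <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(e) <- c("from", "to", "weight")[seq_len(ncol(e))]
  if (!"weight" %in% names(e)) e$weight <- 1
  e$weight <- as.numeric(e$weight)
  HitGraph(nodes, e)
}

# Canonical sorted-key representation of the nontrivial splits of a tree or
# SplitSet, independent of side orientation.
nontrivialKeys <- function(x) {
  ss <- if (inherits(x, "phylo")) treeSplits(x) else x
  taxa <- sort(taxonLabels(ss))
  sides <- splitList(ss)[isNontrivialSplit(ss)]
  vapply(sides, function(s) {
    s <- sort(s)
    comp <- sort(setdiff(taxa, s))
    paste(min(paste(s, collapse = "+"), paste(comp, collapse = "+")),
          collapse = "")
  }, "")
}

# All unrooted topologies on n in {4, 5} taxa with random positive branch
# lengths (deterministic given seed).
additiveCases <- function(n, seed = 1) {
  stopifnot(requireNamespace("phangorn", quietly = TRUE))
  set.seed(seed)
  trees <- phangorn::allTrees(n, rooted = FALSE,
                              tip.label = LETTERS[seq_len(n)])
  lapply(trees, function(tr) {
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 2)
    tr
  })
}

# GLS correlation of two traits on a tree, straight from the covariance
# matrix (the independent oracle for PIC correlation).
glsCorrelation <- function(tree, x, y) {
  V <- ape::vcv.phylo(tree)
  x <- x[rownames(V)]; y <- y[rownames(V)]
  Vi <- solve(V)
  one <- rep(1, nrow(V))
  P <- Vi - (Vi %*% one %*% t(one) %*% Vi) / as.numeric(t(one) %*% Vi %*% one)
  as.numeric(t(x) %*% P %*% y) /
    sqrt(as.numeric(t(x) %*% P %*% x) * as.numeric(t(y) %*% P %*% y))
}
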