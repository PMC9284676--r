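#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: iteratively joins the pair (i, j) minimizing
#' Q_ij = (n - 2) d_ij - sum_k d_ik - sum_k d_jk, with the standard branch
#' length formulas. Ties are broken by the lowest (i, j) index pair in the
#' current matrix order. Negative branch lengths are clamped to zero and
#' the deficit transferred to the sibling branch so path lengths through
#' the new node are preserved.
#'
#' @param d a \linkS4class{DistanceMatrix} or labelled square symmetric
#'   numeric matrix (n >= 3, zero diagonal, no NaN)
#' @return an unrooted \code{phylo} tree with the matrix labels as tips
#' @export
neighborJoining <- function(d) {
  m <- if (is(d, "DistanceMatrix")) distanceValues(d) else d
  if (anyNA(m) || any(!is.finite(m))) stop("distance matrix has NaN/Inf entries")
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 taxa")
  if (max(abs(m - t(m))) > 1e-9) stop("matrix must be symmetric")
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("T", seq_len(n))
  ntip <- n
  # node bookkeeping: tips 1..ntip, internal nodes numbered from ntip+1
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  nodeId <- c(seq_len(ntip))
  newId <- ntip + 1L
  while (n > 3L) {
    rs <- rowSums(m)
    Q <- (n - 2) * m - outer(rs, rs, `+`)
    diag(Q) <- Inf
    # lowest index pair among minima
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    bi <- 0.5 * m[i, j] + (rs[i] - rs[j]) / (2 * (n - 2))
    bj <- m[i, j] - bi
    # clamp-and-transfer
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    u <- newId; newId <- newId + 1L
    edges <- rbind(edges, c(u, nodeId[i]), c(u, nodeId[j]))
    lens <- c(lens, bi, bj)
    du <- 0.5 * (m[i, ] + m[j, ] - m[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    m <- rbind(cbind(m[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    nodeId <- c(nodeId[keep], u)
    rownames(m) <- colnames(m) <- NULL
    n <- n - 1L
  }
  # final 3 nodes: star joined at one internal node (three-point formulas)
  u <- newId
  b1 <- (m[1, 2] + m[1, 3] - m[2, 3]) / 2
  b2 <- (m[1, 2] + m[2, 3] - m[1, 3]) / 2
  b3 <- (m[1, 3] + m[2, 3] - m[1, 2]) / 2
  b <- c(b1, b2, b3)
  for (k in 1:3) if (b[k] < 0) { b[-k] <- b[-k] + b[k] / 2; b[k] <- 0 }
  edges <- rbind(edges, c(u, nodeId[1]), c(u, nodeId[2]), c(u, nodeId[3]))
  lens <- c(lens, b)
  # renumber internal nodes into ape convention (tips 1..n, then internals)
  internal <- sort(unique(edges[, 1]))
  map <- integer(max(edges))
  map[seq_len(ntip)] <- seq_len(ntip)
  # root (last created) first, per ape convention root = ntip + 1
  ordInt <- rev(internal)
  map[ordInt] <- ntip + seq_along(ordInt)
  edges <- matrix(map[edges], ncol = 2)
  tr <- list(edge = edges, edge.length = lens, tip.label = labels,
             Nnode = length(internal))
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  tr
}

#' Splits of an unrooted tree
#'
#' One split per edge: nontrivial splits for internal edges (weight =
#' branch length) and trivial single-taxon splits for pendant edges.
#'
#' @param tree \code{phylo} tree (treated as unrooted)
#' @return a \linkS4class{SplitSet} with support 1 for every split
#' @export
treeSplits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  taxa <- tree$tip.label
  desc <- ape::prop.part(tree)  # tip sets per internal node
  splits <- list(); weights <- numeric(0)
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2]
    side <- if (child <= ntip) taxa[child]
      else taxa[desc[[child - ntip]]]
    if (length(side) %in% c(0L, ntip)) next
    splits <- c(splits, list(side))
    weights <- c(weights, if (is.null(tree$edge.length)) 1 else
      tree$edge.length[k])
  }
  SplitSet(taxa, splits, weights, support = rep(1, length(splits)))
}

#' Consensus split network over a set of trees
#'
#' Computes, over trees sharing one tip set, the support of every split
#' (fraction of trees containing it) and retains the nontrivial splits
#' with support strictly above the threshold, plus all trivial splits.
#' Split weights are the mean branch length over the trees containing the
#' split. The retained set may contain mutually incompatible splits (that
#' is what makes it a network rather than a tree).
#'
#' @param trees list of \code{phylo} trees with identical tip sets
#' @param threshold support threshold in [0, 1); default 0.25 (below
#'   majority rule, so conflicting signal is exposed)
#' @return a \linkS4class{SplitSet}
#' @export
consensusNetwork <- function(trees, threshold = 0.25) {
  if (!length(trees)) stop("need at least one tree")
  if (threshold < 0 || threshold >= 1) stop("threshold must be in [0, 1)")
  tips <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    ti <- sort(trees[[i]]$tip.label)
    if (!identical(ti, tips))
      stop("tree ", i, " has a mismatched tip set: ",
           paste(union(setdiff(ti, tips), setdiff(tips, ti)), collapse = ", "))
  }
  acc <- new.env(parent = emptyenv())
  ref <- tips[1]  # one reference taxon so sides compare across trees
  for (tr in trees) {
    ss <- treeSplits(tr)
    for (k in seq_along(ss@splits)) {
      side <- ss@splits[[k]]
      if (!(ref %in% side)) side <- setdiff(tips, side)
      key <- splitKey(side)
      cur <- acc[[key]]
      if (is.null(cur)) cur <- list(side = side, n = 0L, w = 0)
      cur$n <- cur$n + 1L
      cur$w <- cur$w + ss@weights[k]
      acc[[key]] <- cur
    }
  }
  m <- length(trees)
  keys <- ls(acc)
  splits <- list(); weights <- numeric(0); support <- numeric(0)
  ntip <- length(tips)
  for (key in keys) {
    cur <- acc[[key]]
    sz <- length(cur$side)
    trivial <- sz == 1L || sz == ntip - 1L
    supp <- cur$n / m
    if (trivial || supp > threshold) {
      splits <- c(splits, list(cur$side))
      weights <- c(weights, cur$w / cur$n)
      support <- c(support, supp)
    }
  }
  SplitSet(trees[[1]]$tip.label, splits, weights, support)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of nontrivial splits.
#' @param t1,t2 \code{phylo} trees over the same tip set
#' @return non-negative integer
#' @export
robinsonFoulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have mismatched tip sets")
  s1 <- treeSplits(t1); s2 <- treeSplits(t2)
  k1 <- vapply(s1@splits[isNontrivialSplit(s1)], splitKey, "")
  # canonicalize t2 splits against t1's taxon order
  nt2 <- s2@splits[isNontrivialSplit(s2)]
  taxa <- s1@taxa
  k2 <- vapply(nt2, function(s) {
    if (!(taxa[1] %in% s)) s <- setdiff(taxa, s)
    splitKey(s)
  }, "")
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Per-cluster NJ trees and the consensus network of a hitsort dataset
#'
#' Convenience wrapper: builds observed/expected matrices for every
#' cluster, filters clusters with incomplete information, applies the
#' chosen similarity-to-distance transform, runs neighbor-joining per
#' cluster, and returns the trees plus their consensus network.
#'
#' @param graph a \linkS4class{HitGraph}
#' @param transform \code{"euclidean"} or \code{"inverse"}
#' @param threshold consensus support threshold
#' @return list with \code{trees} (named list of \code{phylo}),
#'   \code{network} (\linkS4class{SplitSet}), \code{filterReport}
#' @export
repeatomeNetwork <- function(graph, transform = c("euclidean", "inverse"),
                             threshold = 0.25) {
  transform <- match.arg(transform)
  mats <- lapply(clusterIDs(graph), function(cl)
    tryCatch(observedExpectedMatrix(graph, cl), error = function(e) NULL))
  mats <- Filter(Negate(is.null), mats)
  flt <- filterCompleteClusters(mats)
  if (!length(flt$retained))
    stop("no cluster with complete similarity information")
  trees <- lapply(flt$retained, function(m) {
    d <- if (transform == "euclidean") euclideanProfileDistance(m)
      else inverseSimilarityDistance(m)
    neighborJoining(d)
  })
  names(trees) <- vapply(flt$retained, function(m) m@cluster, "")
  list(trees = trees,
       network = consensusNetwork(trees, threshold),
       filterReport = flt$report)
}
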