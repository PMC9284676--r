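#' Simulate a pure-birth (Yule) tree rescaled to unit depth
#'
#' Draws a Yule tree on \code{nTips} tips and rescales branch lengths so
#' that the root-to-tip depth is exactly 1. The result is ultrametric and
#' fully bifurcating, and deterministic for a given seed.
#'
#' @param nTips number of tips (>= 2)
#' @param seed integer RNG seed
#' @param tipPrefix prefix for tip labels (\code{S01}, \code{S02}, ...)
#' @return an \code{ape} \code{phylo} tree
#' @export
simulateTree <- function(nTips, seed, tipPrefix = "S") {
  if (nTips < 2) stop("need at least 2 tips")
  set.seed(as.integer(seed))
  tr <- ape::rphylo(nTips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("%s%02d", tipPrefix, seq_len(nTips))
  tr
}

#' Simulate Brownian-motion tip values on a tree
#'
#' Each branch receives an independent Normal(0, sigma2 x branch length)
#' increment; a tip's value is the root value plus the sum of increments
#' along its path. With \code{sigma2 = 0} every tip equals the root value.
#'
#' @param tree \code{phylo} tree with branch lengths >= 0
#' @param sigma2 Brownian-motion rate (>= 0)
#' @param rootValue trait value at the root
#' @param seed optional integer seed (omit to use the current RNG stream)
#' @return named numeric vector of tip values
#' @export
simulateBMTraits <- function(tree, sigma2, rootValue = 0, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ntip <- length(tree$tip.label)
  val <- numeric(ntip + tree$Nnode)
  val[ntip + 1L] <- rootValue
  inc <- stats::rnorm(nrow(tree$edge), 0, sqrt(sigma2 * tree$edge.length))
  # preorder so each parent's value exists before its children are visited
  tr <- ape::reorder.phylo(tree, "cladewise")
  ord <- match(paste(tr$edge[, 1], tr$edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  for (k in seq_len(nrow(tr$edge)))
    val[tr$edge[k, 2]] <- val[tr$edge[k, 1]] + inc[ord[k]]
  out <- val[seq_len(ntip)]
  names(out) <- tree$tip.label
  out
}
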