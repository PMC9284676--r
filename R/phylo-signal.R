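#' Brownian-motion phylogenetic covariance matrix
#'
#' V_ij is the shared root-to-MRCA path length of tips i and j; V_ii is the
#' tip depth. Requires a rooted tree (root the input at an outgroup or at
#' the midpoint first if necessary).
#'
#' @param tree rooted \code{phylo} tree with branch lengths
#' @return symmetric positive-definite matrix over the tips
#' @export
phyloCovariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  # a pure star is its own rooting (the hub); anything else must be rooted
  if (!ape::is.rooted(tree) && tree$Nnode > 1L)
    stop("tree must be rooted; root at an outgroup or midpoint first")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  ape::vcv.phylo(tree)
}

#' Set all branch lengths to one (cladogram mode)
#'
#' Signal tests are sometimes run on topology-only cladograms; this helper
#' replaces every branch length by 1.
#' @param tree \code{phylo} tree
#' @return \code{phylo} tree with unit branch lengths
#' @export
asCladogram <- function(tree) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

kStatistics <- function(V, x, Vi = solve(V)) {
  n <- length(x)
  vi1 <- rowSums(Vi)
  denom1 <- sum(vi1)
  ahat <- sum(vi1 * x) / denom1
  r <- x - ahat
  mse0 <- sum(r^2) / (n - 1)
  mse <- as.numeric(t(r) %*% Vi %*% r) / (n - 1)
  expected <- (sum(diag(V)) - n / denom1) / (n - 1)
  list(mse0 = mse0, mse = mse, K = (mse0 / mse) / expected)
}

#' Blomberg's K phylogenetic-signal statistic
#'
#' K compares the observed ratio of trait variance to phylogenetically
#' corrected variance against its Brownian-motion expectation on the tree:
#' K of about 1 means the trait is as structured as Brownian evolution on
#' the tree predicts, K near 0 means no phylogenetic signal, K > 1 means
#' stronger-than-Brownian signal. Invariant to affine trait transforms and
#' to uniform branch-length rescaling.
#'
#' @param tree rooted \code{phylo} tree with branch lengths
#' @param trait named numeric vector over all tips, non-constant
#' @return K (numeric scalar)
#' @export
blombergK <- function(tree, trait) {
  V <- phyloCovariance(tree)
  if (!all(rownames(V) %in% names(trait)))
    stop("trait must be defined on every tip")
  x <- trait[rownames(V)]
  if (length(unique(x)) == 1L) stop("K undefined for a constant trait")
  kStatistics(V, x)$K
}

#' Permutation test for phylogenetic signal
#'
#' Randomizes trait values over the tips. The test statistic is the
#' phylogenetically corrected mean squared error (smaller MSE = more
#' signal); the p-value uses the add-one rule
#' p = (1 + #\{permuted MSE <= observed\}) / (nPerm + 1), so the smallest
#' attainable p is 1 / (nPerm + 1).
#'
#' @param tree rooted \code{phylo} tree with branch lengths
#' @param trait named numeric vector over all tips
#' @param nPerm number of permutations (>= 99)
#' @param seed integer seed for the permutation stream
#' @return list with \code{K}, \code{p.value}, \code{mse},
#'   \code{n} (tips), \code{nPerm}, \code{seed}
#' @export
kPermutationTest <- function(tree, trait, nPerm = 999L, seed = 1L) {
  if (nPerm < 99L) stop("use at least 99 permutations")
  V <- phyloCovariance(tree)
  if (!all(rownames(V) %in% names(trait)))
    stop("trait must be defined on every tip")
  x <- trait[rownames(V)]
  if (length(unique(x)) == 1L) stop("K undefined for a constant trait")
  Vi <- solve(V)
  obs <- kStatistics(V, x, Vi)
  set.seed(as.integer(seed))
  hits <- 0L
  for (b in seq_len(nPerm)) {
    perm <- kStatistics(V, sample(x), Vi)
    if (perm$mse <= obs$mse) hits <- hits + 1L
  }
  list(K = obs$K, p.value = (1 + hits) / (nPerm + 1), mse = obs$mse,
       n = length(x), nPerm = as.integer(nPerm), seed = as.integer(seed))
}

#' Per-family phylogenetic signal of an abundance table
#'
#' Runs \code{\link{kPermutationTest}} for every repeat family on the
#' given tree, optionally in cladogram mode (all branch lengths one).
#'
#' @param x a \linkS4class{RepeatAbundanceTable}
#' @param tree rooted \code{phylo}; tips must be samples of \code{x}
#' @param nPerm permutations per family
#' @param seed base seed; family f uses seed + f - 1
#' @param cladogram use unit branch lengths
#' @param totalColumn total column to skip
#' @return data.frame with family, K, p.value, n
#' @export
abundanceSignal <- function(x, tree, nPerm = 999L, seed = 1L,
                            cladogram = FALSE, totalColumn = "Total") {
  if (cladogram) tree <- asCladogram(tree)
  v <- abundanceValues(x)
  fams <- setdiff(colnames(v), totalColumn)
  res <- lapply(seq_along(fams), function(fi) {
    f <- fams[fi]
    trait <- v[, f]
    names(trait) <- rownames(v)
    r <- tryCatch(kPermutationTest(tree, trait, nPerm, seed + fi - 1L),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(family = f, K = r$K, p.value = r$p.value, n = r$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
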